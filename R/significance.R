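## Feature quantification across PSMs, Mann-Whitney testing, metric
## computation, threshold filtering, and fragment-remainder echo correction.

## Per-PSM quantification context: theoretical masses plus the two stripped
## views of the spectrum (diagnostic/peptide-remainder stripping removes
## unshifted and fully shifted a/b/y ions; fragment-remainder stripping
## removes unshifted ions only).
psm_context <- function(peptide, var_mods, mass_shift, spectrum, tol_ppm) {
  th <- theoretical_peptide(peptide, var_mods)
  sd <- strip_spectrum(spectrum, th, mass_shift, tol_ppm, "diagnostic")
  sf <- strip_spectrum(spectrum, th, mass_shift, tol_ppm, "fragment_remainder")
  un_b <- unique(sf$matched$idx[sf$matched$series == "b"])
  un_y <- unique(sf$matched$idx[sf$matched$series == "y"])
  ## per-series fragment remainder offset tables, sorted for range lookup
  fr <- lapply(c(b = "b", y = "y"), function(series) {
    f <- th[[series]]
    m <- length(sf$mz)
    n <- length(f)
    if (!m || !n) {
      return(list(off = numeric(), int = numeric(), frag = integer()))
    }
    off <- as.vector(outer(sf$mz, f, `-`))
    o <- order(off)
    list(off = off[o],
         int = rep(sf$intensity, times = n)[o],
         frag = rep(seq_len(n), each = m)[o])
  })
  list(theo = th, peptide = peptide, P = th$P,
       diag_mz = sd$mz, diag_int = sd$intensity,
       frag_mz = sf$mz, frag_int = sf$intensity, fr = fr,
       n_unshifted = c(b = length(un_b), y = length(un_y)))
}

## Indices i with lo <= x[i] <= hi for sorted x.
range_idx <- function(x, lo, hi) {
  a <- findInterval(lo, x, left.open = TRUE) + 1L
  b <- findInterval(hi, x)
  if (a > b) integer() else seq.int(a, b)
}

build_contexts <- function(psms, idx, spectra, tol_ppm) {
  lapply(idx, function(i) {
    psm_context(psms$peptide[i], psms$var_mods[[i]], psms$mass_shift[i],
                spectra[[psms$spectrum_id[i]]], tol_ppm)
  })
}

q_diagnostic <- function(ctx, mass, spread) {
  sel <- range_idx(ctx$diag_mz, mass - spread, mass + spread)
  if (length(sel)) max(ctx$diag_int[sel]) else 0
}

q_peptide_remainder <- function(ctx, mass, spread) {
  tgt <- ctx$P + mass
  sel <- range_idx(ctx$diag_mz, tgt - spread, tgt + spread)
  if (length(sel)) max(ctx$diag_int[sel]) else 0
}

## Fragment remainder: a PSM carries the feature only if at least two series
## fragments have a peak at F_j + mass; the value is the mean intensity of
## the matched peaks (per-fragment maxima). Also returns the minimal shifted
## fragment index (for echo correction) and the per-PSM remainder propensity.
q_fragment_remainder <- function(ctx, mass, spread, series) {
  tab <- ctx$fr[[series]]
  sel <- range_idx(tab$off, mass - spread, mass + spread)
  if (length(sel) < 2L) return(c(value = 0, min_j = NA, propensity = NA))
  frag <- tab$frag[sel]
  matched <- unique(frag)
  if (length(matched) < 2L) return(c(value = 0, min_j = NA, propensity = NA))
  per_j <- vapply(split(tab$int[sel], frag), max, numeric(1))
  n_shift <- length(matched)
  n_unsh <- ctx$n_unshifted[[series]]
  c(value = mean(per_j), min_j = min(matched),
    propensity = 100 * n_shift / (n_shift + n_unsh))
}

## Quantify every candidate of one feature class across a list of contexts
## in a single pass per context (one batched findInterval per spectrum).
## Returns matrices (PSM x candidate): value, and for fragment remainders
## min_j and propensity.
quantify_class <- function(ctxs, cls, masses, spreads, series = NULL) {
  np <- length(ctxs)
  nc <- length(masses)
  val <- matrix(0, np, nc)
  is_frag <- !is.null(series)
  minj <- if (is_frag) matrix(NA_real_, np, nc)
  prop <- if (is_frag) matrix(NA_real_, np, nc)
  lo <- masses - spreads
  hi <- masses + spreads
  ks <- seq_len(nc)
  for (i in seq_len(np)) {
    ctx <- ctxs[[i]]
    if (!is_frag) {
      x <- ctx$diag_mz
      if (!length(x)) next
      off <- if (cls == "peptide_remainder") ctx$P else 0
      v <- findInterval(c(lo + off, hi + off), x)
      a <- v[ks] + 1L
      b <- v[nc + ks]
      for (k in which(b >= a)) val[i, k] <- max(ctx$diag_int[a[k]:b[k]])
    } else {
      tab <- ctx$fr[[series]]
      x <- tab$off
      if (length(x) < 2L) next
      v <- findInterval(c(lo, hi), x)
      a <- v[ks] + 1L
      b <- v[nc + ks]
      for (k in which(b >= a + 1L)) {
        sel <- a[k]:b[k]
        frag <- tab$frag[sel]
        ufrag <- unique(frag)
        if (length(ufrag) < 2L) next  # fewer than two shifted series ions
        ints <- tab$int[sel]
        per_j <- vapply(ufrag, function(u) max(ints[frag == u]), numeric(1))
        val[i, k] <- mean(per_j)
        minj[i, k] <- min(ufrag)
        ns <- length(ufrag)
        prop[i, k] <- 100 * ns / (ns + ctx$n_unshifted[[series]])
      }
    }
  }
  list(value = val, min_j = minj, propensity = prop)
}

#' Quantify a candidate feature across PSMs
#'
#' Produces one intensity per PSM, with missing features coded as zero:
#' for diagnostic ions, the most intense unannotated peak within the
#' tolerance window of the feature mass; for peptide remainders, the most
#' intense peak whose distance to the theoretical peptide mass lies within
#' the window; for fragment remainders, the mean intensity of series
#' fragments matched at `F_j + mass`, required at two or more positions.
#' The window half-width is [mass_spread()] of the feature mass.
#'
#' @param psms PSM data.frame (see [read_psm_table()]).
#' @param spectra preprocessed spectrum collection.
#' @param feature a list or one-row data.frame with `feature_class`
#'   (`"diagnostic"`, `"peptide_remainder"`, `"fragment_remainder_b"`,
#'   `"fragment_remainder_y"`) and `mass`.
#' @param tol_ppm MS/MS tolerance in ppm (default 20).
#' @param mass_x reference mass for the tolerance window (150 for diagnostic
#'   ions; for remainder classes pass the bin's average peptide or fragment
#'   mass).
#' @return numeric vector of intensities, one per PSM row.
#' @export
quantify_feature <- function(psms, spectra, feature, tol_ppm = 20,
                             mass_x = 150) {
  cls <- feature$feature_class
  spread <- mass_spread(feature$mass, mass_x, tol_ppm)
  ctxs <- build_contexts(psms, seq_len(nrow(psms)), spectra, tol_ppm)
  vapply(ctxs, function(ctx) {
    switch(cls,
      diagnostic = q_diagnostic(ctx, feature$mass, spread),
      peptide_remainder = q_peptide_remainder(ctx, feature$mass, spread),
      fragment_remainder_b =
        q_fragment_remainder(ctx, feature$mass, spread, "b")[["value"]],
      fragment_remainder_y =
        q_fragment_remainder(ctx, feature$mass, spread, "y")[["value"]],
      stop("unknown feature class '", cls, "'"))
  }, numeric(1))
}

#' Mann-Whitney U test with tie and continuity correction, plus AUC
#'
#' Computes the Mann-Whitney U statistic of `x` over `y` by midrank
#' assignment, a two-sided p-value from the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction, and the AUC effect
#' size `U / (|x| * |y|)` -- the probability that a value drawn from `x`
#' exceeds one drawn from `y` (ties counted half).
#'
#' @param x,y numeric vectors (each non-empty).
#' @return list with `u_stat`, `p_value`, `auc`. If every value is tied,
#'   `p_value = 1` and `auc = 0.5`.
#' @export
mann_whitney_auc <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  auc <- u / (nx * ny)
  n <- nx + ny
  tie <- table(c(x, y))
  tie_term <- sum(tie^3 - tie)
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(u_stat = u, p_value = 1, auc = 0.5))
  }
  dev <- u - nx * ny / 2
  z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
  list(u_stat = u, p_value = min(1, 2 * pnorm(-abs(z))), auc = auc)
}

#' Filter quantified features
#'
#' Applies the significance and abundance filters to a table of quantified
#' candidates. E-values are the Mann-Whitney p-values multiplied by the
#' number of candidates tested in the same feature class for the bin
#' (fragment remainder b and y candidates count as one class). A feature is
#' retained iff `e_value <= alpha`, `fold_change >= min_fold`, `percent_mod`
#' meets its class prevalence threshold, and -- for fragment remainders --
#' `propensity >= min_propensity`. A feature absent from every unmodified
#' PSM has infinite fold change and passes the fold filter.
#'
#' @param stats data.frame with one row per candidate and columns
#'   `feature_class`, `p_value`, `fold_change`, `percent_mod`, `propensity`
#'   (NA outside fragment remainders).
#' @param alpha E-value threshold (default 0.05).
#' @param min_fold minimum intensity fold change (default 3).
#' @param min_prev_diag,min_prev_peprem,min_prev_fragrem class prevalence
#'   thresholds in percent (defaults 25, 25, 15).
#' @param min_propensity minimum fragment-remainder ion propensity in
#'   percent (default 12.5).
#' @return `stats` with an `e_value` column added, restricted to the
#'   retained rows.
#' @export
filter_features <- function(stats, alpha = 0.05, min_fold = 3,
                            min_prev_diag = 25, min_prev_peprem = 25,
                            min_prev_fragrem = 15, min_propensity = 12.5) {
  if (!nrow(stats)) {
    stats$e_value <- numeric()
    return(stats)
  }
  is_frag <- grepl("^fragment_remainder", stats$feature_class)
  test_class <- ifelse(is_frag, "fragment_remainder", stats$feature_class)
  n_tests <- table(test_class)
  stats$e_value <- pmin(1, stats$p_value * as.numeric(n_tests[test_class]))
  min_prev <- ifelse(stats$feature_class == "diagnostic", min_prev_diag,
              ifelse(stats$feature_class == "peptide_remainder",
                     min_prev_peprem, min_prev_fragrem))
  keep <- stats$e_value <= alpha &
    stats$fold_change >= min_fold &
    stats$percent_mod >= min_prev &
    (!is_frag | (!is.na(stats$propensity) & stats$propensity >= min_propensity))
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correct fragment-remainder echoes
#'
#' A single experimental peak is differenced against every theoretical
#' fragment, so a true remainder mass also produces "echo" features offset
#' by the masses of residues adjacent to the matched site. For each retained
#' fragment-remainder feature, the matched site j is the minimal shifted
#' fragment index per feature-positive PSM (in series direction). If one
#' residue occupies series position j + 1 in more than half of those PSMs,
#' its mass is subtracted from the feature mass; otherwise, if one residue
#' occupies position j in more than half, its mass is added. At most one
#' adjustment is applied per feature (the j + 1 rule takes precedence).
#' Features are ranked by decreasing mean modified-PSM intensity, and all
#' features ranked below the first corrected one are removed as probable
#' noise.
#'
#' @param results data.frame of retained fragment-remainder features with at
#'   least `mass`, `ion_series`, `avg_int_mod`, and `bin_apex` columns.
#' @param sites list parallel to `results` rows; element k is a data.frame
#'   with columns `peptide` and `min_j` over the feature-positive modified
#'   PSMs of feature k.
#' @return `results` with corrected `mass`, recomputed `delta_mod_mass`,
#'   a logical `echo_corrected` column, and noise rows truncated.
#' @export
correct_fragment_echoes <- function(results, sites) {
  if (!nrow(results)) {
    results$echo_corrected <- logical()
    return(results)
  }
  ord <- order(-results$avg_int_mod)
  results <- results[ord, , drop = FALSE]
  sites <- sites[ord]
  results$echo_corrected <- FALSE
  for (k in seq_len(nrow(results))) {
    s <- sites[[k]]
    if (is.null(s) || !nrow(s)) next
    series <- results$ion_series[k]
    res_next <- residue_at_series_pos(s$peptide, series, s$min_j + 1L)
    res_at <- residue_at_series_pos(s$peptide, series, s$min_j)
    dominant <- function(res) {
      res <- res[!is.na(res)]
      if (!length(res)) return(NA_character_)
      tab <- table(res)
      top <- names(tab)[which.max(tab)]
      if (tab[top] > nrow(s) / 2) top else NA_character_
    }
    d1 <- dominant(res_next)
    if (!is.na(d1)) {
      results$mass[k] <- results$mass[k] - AA_MONO[[d1]]
      results$echo_corrected[k] <- TRUE
      next
    }
    d0 <- dominant(res_at)
    if (!is.na(d0)) {
      results$mass[k] <- results$mass[k] + AA_MONO[[d0]]
      results$echo_corrected[k] <- TRUE
    }
  }
  first_corr <- which(results$echo_corrected)[1]
  if (!is.na(first_corr)) {
    results <- results[seq_len(first_corr), , drop = FALSE]
  }
  if (!is.null(results$bin_apex)) {
    results$delta_mod_mass <- results$mass - results$bin_apex
  }
  rownames(results) <- NULL
  results
}
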