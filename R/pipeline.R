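## End-to-end orchestration: peak picking -> binning -> representatives ->
## per-PSM features -> pooled histograms -> candidates -> quantification ->
## testing/filtering -> echo correction.

#' Mining parameters
#'
#' Bundles all tunable parameters of the mining pipeline with their default
#' values.
#'
#' @param tol_ppm MS/MS matching tolerance in ppm.
#' @param top_n peaks retained per spectrum during preprocessing.
#' @param bin_width MS1 mass-shift histogram bin width (Da).
#' @param prominence_frac relative prominence for MS1 peak picking.
#' @param max_ms1_peaks maximum number of MS1 apexes.
#' @param assign_width PSM-to-bin assignment window (Da).
#' @param cap maximum representative PSMs per bin.
#' @param min_area minimum integrated histogram peak area (percent of base
#'   peak per spectrum).
#' @param descent_tol relative bin-to-bin increase tolerated during peak
#'   descent.
#' @param alpha feature E-value threshold.
#' @param min_fold minimum intensity fold change.
#' @param min_prev_diag,min_prev_peprem,min_prev_fragrem prevalence
#'   thresholds (percent of representative PSMs).
#' @param min_propensity minimum fragment-remainder ion propensity (percent).
#' @param min_representatives bins with fewer representatives are skipped.
#' @param seed integer seed controlling representative down-sampling.
#' @return a named list of parameters.
#' @export
mine_params <- function(tol_ppm = 20, top_n = 150, bin_width = 0.0002,
                        prominence_frac = 0.3, max_ms1_peaks = 500,
                        assign_width = 0.004, cap = 1000, min_area = 0.1,
                        descent_tol = 0.01, alpha = 0.05, min_fold = 3,
                        min_prev_diag = 25, min_prev_peprem = 25,
                        min_prev_fragrem = 15, min_propensity = 12.5,
                        min_representatives = 20, seed = 1L) {
  as.list(environment())
}

empty_features <- function() {
  data.frame(bin_apex = numeric(), feature_class = character(),
             ion_series = character(), mass = numeric(),
             delta_mod_mass = numeric(), percent_mod = numeric(),
             percent_unmod = numeric(), avg_int_mod = numeric(),
             avg_int_unmod = numeric(), fold_change = numeric(),
             propensity = numeric(), u_stat = numeric(), p_value = numeric(),
             e_value = numeric(), auc = numeric(), area = numeric(),
             echo_corrected = logical(), stringsAsFactors = FALSE)
}

## Pool one feature class over a list of contexts into (mass, intensity).
pooled_entries <- function(ctxs, class) {
  if (class == "diagnostic") {
    mass <- lapply(ctxs, `[[`, "diag_mz")
    int <- lapply(ctxs, `[[`, "diag_int")
  } else if (class == "peptide_remainder") {
    mass <- lapply(ctxs, function(c) c$diag_mz - c$P)
    int <- lapply(ctxs, `[[`, "diag_int")
  } else {
    series <- sub("fragment_remainder_", "", class)
    mass <- lapply(ctxs, function(c) c$fr[[series]]$off)
    int <- lapply(ctxs, function(c) c$fr[[series]]$int)
  }
  data.frame(mass = unlist(mass, use.names = FALSE),
             intensity = unlist(int, use.names = FALSE))
}

## Mine one non-zero mass-shift bin against the unmodified background.
evaluate_bin <- function(bin_apex, mod_ctx, unmod_ctx, params) {
  n_mod <- length(mod_ctx)
  n_unmod <- length(unmod_ctx)
  mass_x <- list(
    diagnostic = 150,
    peptide_remainder = mean(vapply(mod_ctx, `[[`, numeric(1), "P")),
    fragment_remainder_b =
      mean(unlist(lapply(mod_ctx, function(c) c$theo$b), use.names = FALSE)),
    fragment_remainder_y =
      mean(unlist(lapply(mod_ctx, function(c) c$theo$y), use.names = FALSE))
  )
  classes <- c("diagnostic", "peptide_remainder",
               "fragment_remainder_b", "fragment_remainder_y")

  stats <- list()
  sites <- list()
  for (cls in classes) {
    h <- pool_histogram(pooled_entries(mod_ctx, cls), cls, n_mod,
                        mass_x = mass_x[[cls]], bin_width = params$bin_width)
    h <- smooth_mass_dependent(h, params$tol_ppm)
    cand <- detect_and_integrate_peaks(h, params$tol_ppm, params$min_area,
                                       params$descent_tol)
    rm(h)
    if (!nrow(cand)) next
    is_frag <- grepl("^fragment_remainder", cls)
    series <- if (is_frag) sub("fragment_remainder_", "", cls) else NULL
    spreads <- mass_spread(cand$mass, mass_x[[cls]], params$tol_ppm)
    qm <- quantify_class(mod_ctx, cls, cand$mass, spreads, series)
    qu_all <- quantify_class(unmod_ctx, cls, cand$mass, spreads, series)$value
    peptides <- vapply(mod_ctx, `[[`, character(1), "peptide")
    for (ci in seq_len(nrow(cand))) {
      mass <- cand$mass[ci]
      x <- qm$value[, ci]
      qu <- qu_all[, ci]
      if (is_frag) {
        pos <- x > 0
        prop <- if (any(pos)) mean(qm$propensity[pos, ci]) else NA_real_
        site <- data.frame(
          peptide = peptides[pos],
          min_j = as.integer(qm$min_j[pos, ci]),
          stringsAsFactors = FALSE)
      } else {
        prop <- NA_real_
        site <- NULL
      }
      mw <- mann_whitney_auc(x, qu)
      avg_mod <- mean(x)
      avg_unmod <- mean(qu)
      row <- data.frame(
        bin_apex = bin_apex,
        feature_class = cls,
        ion_series = if (is_frag) series else "none",
        mass = mass,
        delta_mod_mass = if (is_frag) mass - bin_apex else NA_real_,
        percent_mod = 100 * mean(x > 0),
        percent_unmod = 100 * mean(qu > 0),
        avg_int_mod = avg_mod,
        avg_int_unmod = avg_unmod,
        fold_change = if (avg_unmod == 0) Inf else avg_mod / avg_unmod,
        propensity = prop,
        u_stat = mw$u_stat,
        p_value = mw$p_value,
        auc = mw$auc,
        area = cand$area[ci],
        stringsAsFactors = FALSE)
      stats[[length(stats) + 1L]] <- row
      sites[length(sites) + 1L] <- list(site)  # keeps NULL placeholders
    }
  }
  if (!length(stats)) return(empty_features())
  stats <- do.call(rbind, stats)
  keep_id <- seq_len(nrow(stats))
  stats$.id <- keep_id
  res <- filter_features(stats,
                         alpha = params$alpha, min_fold = params$min_fold,
                         min_prev_diag = params$min_prev_diag,
                         min_prev_peprem = params$min_prev_peprem,
                         min_prev_fragrem = params$min_prev_fragrem,
                         min_propensity = params$min_propensity)
  if (!nrow(res)) return(empty_features())
  is_frag <- grepl("^fragment_remainder", res$feature_class)
  frag <- res[is_frag, , drop = FALSE]
  other <- res[!is_frag, , drop = FALSE]
  if (nrow(frag)) {
    frag <- correct_fragment_echoes(frag, sites[frag$.id])
  } else {
    frag$echo_corrected <- logical()
  }
  other$echo_corrected <- rep(FALSE, nrow(other))
  out <- rbind(other, frag)
  out$.id <- NULL
  rownames(out) <- NULL
  out
}

#' Mine diagnostic features from spectra and PSMs
#'
#' Runs the full diagnostic feature mining pipeline: spectra are
#' preprocessed (base peak 100, top `top_n` peaks), MS1 mass-shift apexes
#' are picked and PSMs assigned to bins, representative PSMs are selected
#' per peptide ion, the three feature classes are pooled into histograms and
#' candidate peaks detected, and every candidate is quantified in the bin's
#' representative PSMs versus the unmodified (zero-bin) representatives and
#' filtered by Mann-Whitney E-value, fold change, prevalence and propensity,
#' with fragment-remainder echo correction. The zero bin itself is the
#' background and is never tested.
#'
#' @param spectra spectrum collection from [read_spectra()] (raw; they are
#'   preprocessed internally).
#' @param psms PSM data.frame from [read_psm_table()].
#' @param params parameter list from [mine_params()].
#' @return an object of class `mine_report`: a list with `summary` (per-bin
#'   apex, PSM and representative counts), `features` (validated feature
#'   table), `params`, `n_unassigned`, and `warnings`.
#' @export
mine_all <- function(spectra, psms, params = mine_params()) {
  warns <- character()
  spectra <- lapply(spectra, preprocess_spectrum, top_n = params$top_n)
  have <- psms$spectrum_id %in% names(spectra)
  if (!all(have)) {
    warns <- c(warns, sprintf("%d PSM(s) without a loaded spectrum dropped",
                              sum(!have)))
    warning(warns[length(warns)], call. = FALSE)
    psms <- psms[have, , drop = FALSE]
    rownames(psms) <- NULL
  }
  if (!nrow(psms)) stop("no PSMs with spectra to mine")

  apexes <- pick_mass_shift_peaks(psms$mass_shift, params$bin_width,
                                  params$prominence_frac, params$max_ms1_peaks)
  bins <- assign_psms(psms, apexes, params$assign_width)
  zero <- which(vapply(bins, `[[`, logical(1), "is_zero_bin"))
  if (!length(zero)) {
    stop("no zero (unmodified) mass-shift bin found: unmodified peptides ",
         "are required as the statistical background")
  }

  rep_idx <- lapply(bins, function(b) {
    select_representatives(psms, b$psm_idx, cap = params$cap,
                           seed = params$seed)
  })
  unmod_ctx <- build_contexts(psms, rep_idx[[zero]], spectra, params$tol_ppm)
  if (!length(unmod_ctx)) stop("zero bin has no representative PSMs")

  features <- list()
  skipped <- logical(length(bins))
  for (k in seq_along(bins)) {
    if (k == zero) next
    if (length(rep_idx[[k]]) < params$min_representatives) {
      skipped[k] <- TRUE
      warns <- c(warns, sprintf(
        "bin %.4f skipped: %d representative(s) < %d",
        bins[[k]]$apex, length(rep_idx[[k]]), params$min_representatives))
      next
    }
    mod_ctx <- build_contexts(psms, rep_idx[[k]], spectra, params$tol_ppm)
    features[[length(features) + 1L]] <-
      evaluate_bin(bins[[k]]$apex, mod_ctx, unmod_ctx, params)
  }
  features <- if (length(features)) do.call(rbind, features) else empty_features()
  rownames(features) <- NULL

  summary <- data.frame(
    apex = vapply(bins, `[[`, numeric(1), "apex"),
    n_psms = vapply(bins, function(b) length(b$psm_idx), integer(1)),
    n_representatives = vapply(rep_idx, length, integer(1)),
    is_zero_bin = vapply(bins, `[[`, logical(1), "is_zero_bin"),
    skipped = skipped
  )
  structure(list(summary = summary, features = features, params = params,
                 n_unassigned = attr(bins, "n_unassigned"),
                 warnings = warns),
            class = "mine_report")
}

#' @export
print.mine_report <- function(x, ...) {
  cat("Diagnostic feature mining report\n")
  cat(sprintf("  %d mass-shift bin(s), %d unassigned PSM(s)\n",
              nrow(x$summary), x$n_unassigned))
  cat(sprintf("  %d validated feature(s)\n", nrow(x$features)))
  if (nrow(x$features)) {
    print(x$features[, c("bin_apex", "feature_class", "ion_series", "mass",
                         "percent_mod", "fold_change", "e_value", "auc")],
          digits = 6)
  }
  invisible(x)
}

#' Write all report tables of a mining run
#'
#' Writes the mass-shift summary (`mass_shifts.tsv`) and the feature report
#' (`features.tsv`) into a directory, plus a `run_log.txt` with parameters
#' and warnings.
#'
#' @param report a `mine_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mass_shift_summary(report, file.path(dir, "mass_shifts.tsv"))
  write_feature_report(report, file.path(dir, "features.tsv"))
  par <- vapply(report$params, function(p) paste(format(p), collapse = ","),
                character(1))
  writeLines(c(paste0(names(par), " = ", par), report$warnings),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
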