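## Theoretical peptide/fragment masses, ion stripping, and the per-PSM
## feature primitives: unannotated-ion vectors, peptide remainder vectors,
## and fragment remainder matrices.

#' Theoretical peptide and fragment masses
#'
#' Computes the singly protonated theoretical peptide mass P (`M+H`, Da) and
#' the charge-1 a-, b- and y-ion series for a peptide with optional variable
#' modifications. The observed MS1 mass shift is deliberately excluded:
#' remainder masses are defined against the unshifted theoretical masses.
#'
#' Invariants: `b[j] + y[n + 1 - j] = P + proton` and `a[j] = b[j] - CO`,
#' with `n = nchar(peptide) - 1`.
#'
#' @param peptide amino-acid sequence (standard 20 letters).
#' @param var_mods variable modifications: a data.frame with columns `pos`
#'   (`"1"`..`"n"`, `"N-term"`, `"C-term"`) and `delta` (Da), as produced by
#'   [parse_mod_string()]; `NULL` for none.
#' @return an object of class `theoretical_peptide`: a list with `peptide`,
#'   `n` (series length), `P`, and numeric vectors `a`, `b`, `y`.
#' @export
theoretical_peptide <- function(peptide, var_mods = NULL) {
  aa <- strsplit(peptide, "")[[1]]
  if (!length(aa)) stop("empty peptide sequence")
  bad <- setdiff(aa, names(AA_MONO))
  if (length(bad)) stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  res <- unname(AA_MONO[aa])
  len <- length(aa)
  nterm <- cterm <- 0
  if (!is.null(var_mods) && nrow(var_mods)) {
    for (i in seq_len(nrow(var_mods))) {
      p <- var_mods$pos[i]
      d <- var_mods$delta[i]
      if (p == "N-term") {
        nterm <- nterm + d
      } else if (p == "C-term") {
        cterm <- cterm + d
      } else {
        pi <- as.integer(p)
        if (is.na(pi) || pi < 1L || pi > len) {
          stop("modification position '", p, "' outside peptide '", peptide, "'")
        }
        res[pi] <- res[pi] + d
      }
    }
  }
  n <- len - 1L
  proton <- MASS_CONST[["proton"]]
  water <- MASS_CONST[["water"]]
  b <- proton + nterm + cumsum(res)[seq_len(n)]
  y <- proton + water + cterm + cumsum(rev(res))[seq_len(n)]
  structure(list(peptide = peptide, n = n,
                 P = proton + water + nterm + cterm + sum(res),
                 a = b - MASS_CONST[["co"]], b = unname(b), y = unname(y)),
            class = "theoretical_peptide")
}

## Nearest-neighbour ppm matching of observed masses against a sorted-or-not
## reference vector. Returns the index of the matched reference mass, or NA.
match_masses_ppm <- function(mz, ref, tol_ppm) {
  if (!length(ref) || !length(mz)) return(rep(NA_integer_, length(mz)))
  o <- order(ref)
  rs <- ref[o]
  i <- findInterval(mz, rs)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(rs))
  pick <- ifelse(abs(mz - rs[lo]) <= abs(mz - rs[hi]), lo, hi)
  ok <- abs(mz - rs[pick]) <= ppm_tol(rs[pick], tol_ppm)
  ifelse(ok, o[pick], NA_integer_)
}

#' Strip annotated backbone ions from a spectrum
#'
#' Removes peaks matching theoretical a-, b- and y-ions from a preprocessed
#' spectrum before feature calculation. In `diagnostic` and
#' `peptide_remainder` modes both the unshifted series masses and the fully
#' shifted masses (series mass + `mass_shift`) are stripped, so that backbone
#' fragments carrying the modification are not mistaken for diagnostic ions.
#' In `fragment_remainder` mode only unshifted series ions are stripped,
#' leaving shifted fragments available as remainder-mass evidence.
#'
#' @param s preprocessed spectrum.
#' @param t [theoretical_peptide()] of the PSM.
#' @param mass_shift the PSM's observed MS1 mass shift (Da).
#' @param tol_ppm matching tolerance in ppm (default 20), applied as
#'   `|obs - theo| <= tol_ppm * theo / 1e6`.
#' @param mode one of `"diagnostic"`, `"peptide_remainder"`,
#'   `"fragment_remainder"`.
#' @return a list with `mz`, `intensity` (the unannotated ions U), `matched`
#'   (list with parallel vectors `series`, `idx`, `kind`
#'   (`"unshifted"`/`"shifted"`), `mz`, `intensity` for removed peaks),
#'   `P`, `mode` and `mass_shift`.
#' @export
strip_spectrum <- function(s, t, mass_shift, tol_ppm = 20,
                           mode = c("diagnostic", "peptide_remainder",
                                    "fragment_remainder")) {
  mode <- match.arg(mode)
  n <- t$n
  theo <- c(t$a, t$b, t$y)
  series <- rep(c("a", "b", "y"), each = n)
  idx <- rep(seq_len(n), times = 3L)
  kind <- rep("unshifted", 3L * n)
  if (mode != "fragment_remainder") {
    theo <- c(theo, theo + mass_shift)
    series <- c(series, series)
    idx <- c(idx, idx)
    kind <- c(kind, rep("shifted", 3L * n))
  }
  hit <- match_masses_ppm(s$mz, theo, tol_ppm)
  rm <- !is.na(hit)
  mi <- hit[rm]
  list(mz = s$mz[!rm], intensity = s$intensity[!rm],
       matched = list(series = series[mi], idx = idx[mi], kind = kind[mi],
                      mz = s$mz[rm], intensity = s$intensity[rm]),
       P = t$P, mode = mode, mass_shift = mass_shift)
}

#' Peptide remainder vector
#'
#' For every unannotated ion remaining after stripping, the candidate peptide
#' remainder mass is its distance to the theoretical unshifted peptide mass:
#' `mz_i - P`, carrying the ion's intensity.
#'
#' @param ss stripped spectrum from [strip_spectrum()] in
#'   `peptide_remainder` mode.
#' @param t the PSM's [theoretical_peptide()].
#' @return data.frame with columns `mass` (remainder, Da) and `intensity`.
#' @export
peptide_remainder_vector <- function(ss, t) {
  data.frame(mass = ss$mz - t$P, intensity = ss$intensity)
}

#' Fragment remainder matrix
#'
#' Pairwise distances between every remaining ion and every theoretical
#' fragment of one series: entry (i, j) is `(mz_i - F_j, int_i)`. b and y
#' series are processed independently.
#'
#' @param ss stripped spectrum from [strip_spectrum()] in
#'   `fragment_remainder` mode.
#' @param t the PSM's [theoretical_peptide()].
#' @param series `"b"` or `"y"`.
#' @return data.frame with columns `offset` (Da), `intensity`, `peak` (ion
#'   index i) and `frag` (fragment index j); `nrow = m * n`.
#' @export
fragment_remainder_matrix <- function(ss, t, series = c("b", "y")) {
  series <- match.arg(series)
  f <- t[[series]]
  m <- length(ss$mz)
  n <- length(f)
  data.frame(
    offset = as.vector(outer(ss$mz, f, `-`)),
    intensity = rep(ss$intensity, times = n),
    peak = rep(seq_len(m), times = n),
    frag = rep(seq_len(n), each = m)
  )
}

## Residue letter at series position p: for b ions position p is the p-th
## residue from the N terminus; for y ions it is the p-th from the C terminus.
residue_at_series_pos <- function(peptide, series, p) {
  len <- nchar(peptide)
  i <- if (series == "b") p else len - p + 1L
  ifelse(i >= 1L & i <= len, substr(rep(peptide, length.out = length(i)), i, i), NA_character_)
}
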