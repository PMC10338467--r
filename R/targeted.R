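## Targeted extraction of user-specified ions, rank correlation between
## ions, and precision/AUC-versus-intensity discrimination summaries.

#' Extract an ion intensity matrix
#'
#' Quantifies user-specified ions across all PSMs on the raw (preprocessed
#' but unstripped) spectra: each cell is the maximum intensity of any peak
#' within ppm tolerance of the requested m/z, or 0 if absent. Extraction is
#' deliberately performed without backbone-ion stripping so that neutral
#' losses that co-occur under normal fragmentation are not forced into
#' anticorrelation.
#'
#' @param psms PSM data.frame.
#' @param spectra preprocessed spectrum collection.
#' @param ions numeric vector of ion m/z values; ions closer than their
#'   mutual tolerance are rejected.
#' @param tol_ppm tolerance in ppm (default 20).
#' @param labels optional logical vector (one per PSM) flagging modified
#'   rows; defaults to `abs(mass_shift) > 0.002`.
#' @return a list of class `ion_matrix` with `intensities` (PSMs x ions
#'   matrix, columns named by m/z), `labels`, and `ions`.
#' @export
extract_ion_matrix <- function(psms, spectra, ions, tol_ppm = 20,
                               labels = NULL) {
  if (!length(ions)) stop("no ions requested")
  ions <- as.numeric(ions)
  if (length(ions) > 1L) {
    s <- sort(ions)
    gap <- diff(s)
    lim <- ppm_tol(s[-1], tol_ppm) + ppm_tol(s[-length(s)], tol_ppm)
    if (any(gap <= lim)) {
      stop("requested ions cannot be resolved at ", tol_ppm, " ppm: ",
           paste(sprintf("%.4f", s[c(which(gap <= lim)[1],
                                     which(gap <= lim)[1] + 1L)]),
                 collapse = " / "))
    }
  }
  if (is.null(labels)) labels <- abs(psms$mass_shift) > 0.002
  tol <- ppm_tol(ions, tol_ppm)
  m <- matrix(0, nrow = nrow(psms), ncol = length(ions),
              dimnames = list(psms$spectrum_id, sprintf("%.4f", ions)))
  for (i in seq_len(nrow(psms))) {
    sp <- spectra[[psms$spectrum_id[i]]]
    if (is.null(sp)) next
    for (j in seq_along(ions)) {
      sel <- abs(sp$mz - ions[j]) <= tol[j]
      if (any(sel)) m[i, j] <- max(sp$intensity[sel])
    }
  }
  structure(list(intensities = m, labels = labels, ions = ions),
            class = "ion_matrix")
}

#' Spearman correlation between extracted ions
#'
#' Pairwise Spearman rank correlation between ion columns over PSM rows
#' (zeros included, midranks for ties). Columns with zero variance yield
#' `NA` against other columns; the diagonal is 1.
#'
#' @param m an `ion_matrix` from [extract_ion_matrix()].
#' @param subset optional row filter (logical or integer indices).
#' @return symmetric correlation matrix.
#' @export
spearman_correlation <- function(m, subset = NULL) {
  x <- m$intensities
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  if (nrow(x) < 2L) stop("need at least two rows to correlate")
  rho <- suppressWarnings(cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Precision and AUC of ions versus intensity
#'
#' For each ion, computes the precision curve: the probability that a
#' spectrum is modified given that the ion is present at an intensity within
#' each band, banded by deciles of the ion's nonzero intensities. Also
#' computes a single AUC per ion from [mann_whitney_auc()] between modified
#' and unmodified intensity vectors (zeros included): the probability that
#' the ion is more intense in a random modified than a random unmodified
#' PSM.
#'
#' @param m an `ion_matrix` with both labels present.
#' @return list with `curves` (data.frame: `ion`, `band`, `x_lo`, `x_hi`,
#'   `precision`, `n`) and `auc` (data.frame: `ion`, `auc`).
#' @export
discrimination_curves <- function(m) {
  lab <- m$labels
  if (length(unique(lab)) < 2L) {
    stop("both modified and unmodified PSMs are required")
  }
  x <- m$intensities
  curves <- list()
  aucs <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    aucs[j] <- mann_whitney_auc(v[lab], v[!lab])$auc
    nz <- v[v > 0]
    if (!length(nz)) next
    br <- unique(quantile(nz, probs = seq(0, 1, by = 0.1), names = FALSE))
    if (length(br) < 2L) br <- c(br, br + .Machine$double.eps)
    band <- cut(v[v > 0], breaks = br, include.lowest = TRUE, labels = FALSE)
    lab_nz <- lab[v > 0]
    for (b in sort(unique(band))) {
      sel <- band == b
      curves[[length(curves) + 1L]] <- data.frame(
        ion = m$ions[j], band = b,
        x_lo = br[b], x_hi = br[b + 1L],
        precision = mean(lab_nz[sel]), n = sum(sel))
    }
  }
  list(curves = if (length(curves)) do.call(rbind, curves) else
         data.frame(ion = numeric(), band = integer(), x_lo = numeric(),
                    x_hi = numeric(), precision = numeric(), n = integer()),
       auc = data.frame(ion = m$ions, auc = aucs))
}
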