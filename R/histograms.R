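## Pooled candidate-feature histograms: 0.2 mDa binning, mass-dependent
## rolling-mean smoothing, and peak detection/integration.

#' Mass-dependent smoothing half-width
#'
#' The half-width (in Da) over which a histogram entry of mass `mass` is
#' spread: `tol_ppm * (mass + mass_x) / 1e6`. `mass_x` is the average
#' reference mass the entries were computed against (mean theoretical peptide
#' or fragment mass for remainder classes, 150 Da for diagnostic ions), so
#' that the ppm uncertainty of a remainder reflects the mass of the ions it
#' was derived from, not the remainder itself.
#'
#' @param mass entry mass in Da (may be a vector).
#' @param mass_x reference mass in Da.
#' @param tol_ppm MS/MS tolerance in ppm.
#' @return half-width(s) in Da.
#' @export
mass_spread <- function(mass, mass_x, tol_ppm = 20) {
  tol_ppm * (mass + mass_x) / 1e6
}

#' Pool per-PSM features into a histogram
#'
#' Accumulates candidate feature masses from the representative PSMs of one
#' mass-shift bin into a fixed-width histogram. Each entry adds
#' `intensity / n_spectra` to its bin (half-open bins), so bin weights are in
#' units of percent-of-base-peak per spectrum. For remainder classes the left
#' tail is truncated at -250 Da.
#'
#' @param features data.frame with columns `mass` and `intensity`, pooled
#'   over all representative PSMs.
#' @param feature_class one of `"diagnostic"`, `"peptide_remainder"`,
#'   `"fragment_remainder_b"`, `"fragment_remainder_y"`.
#' @param n_spectra number of contributing representative PSMs (> 0).
#' @param mass_x average reference mass (defaults to 150 for the diagnostic
#'   class; required for remainder classes).
#' @param bin_width bin width in Da (default 0.0002).
#' @param lo,hi histogram bounds in Da; defaults: `lo = -250` for remainder
#'   classes and 0 for diagnostic ions, `hi` = just above the largest
#'   observed mass.
#' @return an object of class `feature_histogram`: a list with `feature_class`,
#'   `bin_width`, `lo`, `nbins`, `weights`, `n_spectra`, `mass_x`, `smoothed`.
#' @export
pool_histogram <- function(features, feature_class, n_spectra,
                           mass_x = NULL, bin_width = 0.0002,
                           lo = NULL, hi = NULL) {
  feature_class <- match.arg(feature_class,
                             c("diagnostic", "peptide_remainder",
                               "fragment_remainder_b", "fragment_remainder_y"))
  if (n_spectra <= 0L) stop("n_spectra must be positive")
  if (is.null(mass_x)) {
    if (feature_class == "diagnostic") mass_x <- 150
    else stop("mass_x is required for remainder feature classes")
  }
  if (is.null(lo)) lo <- if (feature_class == "diagnostic") 0 else -250
  mass <- features$mass
  int <- features$intensity
  keep <- mass >= lo
  mass <- mass[keep]
  int <- int[keep]
  if (is.null(hi)) hi <- if (length(mass)) max(mass) + 10 * bin_width else lo + bin_width
  keep <- mass < hi
  mass <- mass[keep]
  int <- int[keep]
  nbins <- as.integer(ceiling((hi - lo) / bin_width))
  w <- numeric(nbins)
  if (length(mass)) {
    idx <- pmin(floor((mass - lo) / bin_width) + 1L, nbins)
    acc <- rowsum(int / n_spectra, idx)
    w[as.integer(rownames(acc))] <- acc[, 1]
  }
  structure(list(feature_class = feature_class, bin_width = bin_width,
                 lo = lo, nbins = nbins, weights = w, n_spectra = n_spectra,
                 mass_x = mass_x, smoothed = FALSE),
            class = "feature_histogram")
}

bin_centers <- function(h, idx = seq_len(h$nbins)) {
  h$lo + (idx - 0.5) * h$bin_width
}

#' Smooth a feature histogram mass-dependently
#'
#' Applies the rolling-mean smoothing whose spread grows with ion mass: each
#' bin's weight is redistributed uniformly over the window of half-width
#' [mass_spread()] centred on it (`floor(spread / bin_width)` bins per side).
#' Weight falling beyond the histogram bounds is absorbed by the edge bins,
#' so the total weight is conserved exactly.
#'
#' @param h a `feature_histogram` from [pool_histogram()].
#' @param tol_ppm MS/MS tolerance in ppm (default 20).
#' @return the smoothed `feature_histogram` (`smoothed = TRUE`).
#' @export
smooth_mass_dependent <- function(h, tol_ppm = 20) {
  stopifnot(inherits(h, "feature_histogram"))
  nz <- which(h$weights > 0)
  if (!length(nz)) {
    h$smoothed <- TRUE
    return(h)
  }
  spread <- mass_spread(bin_centers(h, nz), h$mass_x, tol_ppm)
  k <- as.integer(pmax(floor(spread / h$bin_width), 0))
  h$raw <- h$weights
  h$weights <- boxcar_scatter(h$nbins, nz, h$weights[nz], k)
  h$smoothed <- TRUE
  h$tol_ppm <- tol_ppm
  h
}

#' Detect and integrate candidate feature peaks
#'
#' Apexes are local maxima of the smoothed histogram found by descending each
#' side of a maximum until a zero bin is reached or the next bin increases by
#' more than `descent_tol` (relative); maxima inside the descent path of a
#' larger peak are shoulders and are not reported. Each apex is integrated by
#' summing bins within the MS/MS tolerance ([mass_spread()] at the apex),
#' without regard for adjacent peak boundaries. Candidates with integrated
#' area below `min_area` are dropped; of any two candidates that cannot be
#' resolved under the tolerance (closer than the larger of their spreads),
#' the lower-area one is removed. The reported mass is the weight-weighted
#' centroid within the integration window.
#'
#' @param h a smoothed `feature_histogram`.
#' @param tol_ppm MS/MS tolerance in ppm (default 20).
#' @param min_area minimum integrated area, in percent-of-base-peak per
#'   spectrum (default 0.1).
#' @param descent_tol relative bin-to-bin increase tolerated during descent
#'   (default 0.01).
#' @return data.frame with columns `mass` (centroid), `apex` (apex bin
#'   centre), `area` and `spread`, sorted by decreasing area.
#' @export
detect_and_integrate_peaks <- function(h, tol_ppm = 20, min_area = 0.1,
                                       descent_tol = 0.01) {
  stopifnot(inherits(h, "feature_histogram"), isTRUE(h$smoothed))
  empty <- data.frame(mass = numeric(), apex = numeric(),
                      area = numeric(), spread = numeric())
  w <- h$weights
  ap <- descend_apexes(w, descent_tol)
  if (!length(ap)) return(empty)
  centers <- bin_centers(h, ap)
  spread <- mass_spread(centers, h$mass_x, tol_ppm)
  k <- as.integer(pmax(floor(spread / h$bin_width), 0))
  loi <- pmax(ap - k, 1L)
  hii <- pmin(ap + k, h$nbins)
  cs <- c(0, cumsum(w))
  area <- cs[hii + 1L] - cs[loi]
  ## centroid over the unsmoothed histogram inside the integration window:
  ## smoothing flattens narrow peaks into plateaus whose argmax is noisy,
  ## while the raw entries keep the sub-bin mass information
  wr <- if (is.null(h$raw)) w else h$raw
  csr <- c(0, cumsum(wr))
  raw_area <- csr[hii + 1L] - csr[loi]
  csm <- c(0, cumsum(wr * bin_centers(h)))
  centroid <- ifelse(raw_area > 0, (csm[hii + 1L] - csm[loi]) / raw_area,
                     bin_centers(h, ap))
  keep <- area > min_area
  if (!any(keep)) return(empty)
  out <- data.frame(mass = centroid[keep], apex = centers[keep],
                    area = area[keep], spread = spread[keep])
  out <- out[order(-out$area, out$apex), , drop = FALSE]
  ## redundancy removal: greedy from the most intense
  sel <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    kept <- which(sel)
    if (!length(kept) ||
        all(abs(out$apex[i] - out$apex[kept]) >
            pmax(out$spread[i], out$spread[kept]))) {
      sel[i] <- TRUE
    }
  }
  out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}
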