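## MS1 mass-shift peak picking, PSM-to-bin assignment, and representative
## PSM selection.

#' Pick MS1 mass-shift peaks
#'
#' Builds a histogram of observed precursor mass shifts at `bin_width`
#' resolution, smooths it with a 5-point discrete normal kernel (sigma = one
#' bin, renormalised to sum 1; weight falling outside the histogram is folded
#' back into the edge bins so total count is conserved), and reports local
#' maxima whose topographic prominence is at least `prominence_frac` times
#' their height. Each surviving apex is scored by signal-to-noise: PSM count
#' within +/-0.002 Da of the apex minus the counts in the two flanking
#' 0.01 Da windows. The `max_peaks` highest-SNR apexes are returned, sorted
#' by absolute mass.
#'
#' @param mass_shifts numeric vector of observed MS1 mass shifts (Da), or a
#'   PSM data.frame with a `mass_shift` column.
#' @param bin_width histogram bin width in Da (default 0.0002).
#' @param prominence_frac minimum prominence relative to apex height
#'   (default 0.3).
#' @param max_peaks maximum number of apexes reported (default 500).
#' @return numeric vector of apex masses (bin centres), sorted by `abs()`.
#' @export
pick_mass_shift_peaks <- function(mass_shifts, bin_width = 0.0002,
                                  prominence_frac = 0.3, max_peaks = 500) {
  if (is.data.frame(mass_shifts)) mass_shifts <- mass_shifts$mass_shift
  if (!length(mass_shifts)) stop("no mass shifts supplied")

  pad <- 100L  # empty bins on each side so the kernel and SNR windows fit
  lo <- floor(min(mass_shifts) / bin_width) * bin_width - pad * bin_width
  idx <- floor((mass_shifts - lo) / bin_width) + 1L
  nbins <- max(idx) + pad
  counts <- numeric(nbins)
  tab <- table(idx)
  counts[as.integer(names(tab))] <- as.numeric(tab)

  sm <- smooth_counts_5pt(counts)

  cand <- plateau_maxima(sm)
  if (!length(cand)) return(numeric())
  keep <- vapply(cand, function(i) {
    prominence_ok(sm, i, prominence_frac)
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(numeric())

  centers <- lo + (cand - 0.5) * bin_width
  cs <- c(0, cumsum(counts))
  win_count <- function(a, b) {
    # raw PSM count with shift in [a, b)
    ia <- pmin(pmax(floor((a - lo) / bin_width) + 1L, 1L), nbins + 1L)
    ib <- pmin(pmax(floor((b - lo) / bin_width) + 1L, 1L), nbins + 1L)
    cs[ib] - cs[ia]
  }
  sig <- win_count(centers - 0.002, centers + 0.002)
  noise <- win_count(centers - 0.012, centers - 0.002) +
    win_count(centers + 0.002, centers + 0.012)
  snr <- sig - noise
  ord <- order(-snr, abs(centers))
  top <- head(ord, max_peaks)
  apexes <- centers[top]
  apexes[order(abs(apexes))]
}

## 5-point discrete normal smoothing (sigma = 1 bin, renormalised); edge
## bins absorb kernel overflow so the total count is conserved.
smooth_counts_5pt <- function(counts) {
  nbins <- length(counts)
  kw <- dnorm(-2:2)
  kw <- kw / sum(kw)
  nz <- which(counts > 0)
  sm <- numeric(nbins)
  for (o in -2:2) {
    dst <- pmin(pmax(nz + o, 1L), nbins)
    part <- rowsum(counts[nz] * kw[o + 3L], dst)
    ii <- as.integer(rownames(part))
    sm[ii] <- sm[ii] + part[, 1]
  }
  sm
}

## Indices of local maxima; runs of equal values ("plateaus") yield a single
## candidate at the plateau centre.
plateau_maxima <- function(w) {
  n <- length(w)
  if (n == 0L) return(integer())
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  leftv <- c(-Inf, r$values[-k])
  rightv <- c(r$values[-1], -Inf)
  is_max <- r$values > 0 & r$values >= leftv & r$values >= rightv
  as.integer(floor((starts[is_max] + ends[is_max]) / 2))
}

## Decide whether the local maximum at bin i has topographic prominence of at
## least frac * height. Walks outward on each side until either a strictly
## higher bin is found (the key col is the running minimum along the path) or
## the running minimum already guarantees the prominence criterion.
prominence_ok <- function(w, i, frac) {
  h <- w[i]
  thr <- (1 - frac) * h  # key col must be <= thr
  side_ok <- function(step) {
    j <- i + step
    runmin <- h
    while (j >= 1L && j <= length(w)) {
      v <- w[j]
      if (v > h) return(runmin <= thr)
      if (v < runmin) {
        runmin <- v
        if (runmin <= thr) return(TRUE)
      }
      j <- j + step
    }
    TRUE  # no higher ground on this side: side imposes no key col
  }
  side_ok(-1L) && side_ok(1L)
}

#' Assign PSMs to mass-shift bins
#'
#' Each PSM is assigned to the nearest apex if its mass shift lies within
#' `assign_width` of it, otherwise it is left unassigned. The bin whose apex
#' is nearest zero and within +/-0.002 Da of zero is flagged as the zero
#' (unmodified background) bin.
#'
#' @param psms PSM data.frame with a `mass_shift` column.
#' @param apexes apex masses from [pick_mass_shift_peaks()].
#' @param assign_width maximum |mass_shift - apex| for assignment (Da).
#' @return a list of bins; each bin is a list with `apex`, `psm_idx` (row
#'   indices into `psms`), and `is_zero_bin`. The attribute `n_unassigned`
#'   carries the count of unassigned PSMs.
#' @export
assign_psms <- function(psms, apexes, assign_width = 0.004) {
  stopifnot(length(apexes) >= 1)
  ax <- sort(apexes)
  i <- findInterval(psms$mass_shift, ax)
  loi <- pmax(i, 1L)
  hii <- pmin(i + 1L, length(ax))
  nearest <- ifelse(abs(psms$mass_shift - ax[loi]) <= abs(psms$mass_shift - ax[hii]),
                    loi, hii)
  dist <- abs(psms$mass_shift - ax[nearest])
  nearest[dist > assign_width] <- NA_integer_
  zero_cand <- which(abs(ax) <= 0.002)
  zero_idx <- if (length(zero_cand)) zero_cand[which.min(abs(ax[zero_cand]))] else NA_integer_
  bins <- lapply(seq_along(ax), function(k) {
    list(apex = ax[k],
         psm_idx = which(!is.na(nearest) & nearest == k),
         is_zero_bin = !is.na(zero_idx) && k == zero_idx)
  })
  attr(bins, "n_unassigned") <- sum(is.na(nearest))
  bins
}

#' Select representative PSMs for a bin
#'
#' PSMs are grouped by peptide ion (sequence, modification state, precursor
#' charge) and the lowest-E-value PSM of each group is kept, with ties broken
#' by the lexicographically smallest spectrum id. If more than `cap` peptide
#' ions remain, a uniform random sample of `cap` representatives is drawn
#' using `seed` (the caller's RNG stream is left untouched).
#'
#' @param psms PSM data.frame.
#' @param idx row indices belonging to the bin (default: all rows).
#' @param cap maximum number of representatives (default 1000).
#' @param seed integer seed for the down-sampling step.
#' @return integer vector of selected row indices into `psms`.
#' @export
select_representatives <- function(psms, idx = seq_len(nrow(psms)),
                                   cap = 1000, seed = 1L) {
  if (!length(idx)) return(integer())
  sub <- psms[idx, , drop = FALSE]
  key <- paste(sub$peptide, sub$mods, sub$charge, sep = "\r")
  ord <- order(key, sub$evalue, sub$spectrum_id)
  first <- ord[!duplicated(key[ord])]
  reps <- idx[first]
  if (length(reps) > cap) {
    reps <- with_seed(seed, sample(reps, cap))
  }
  sort(reps)
}
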