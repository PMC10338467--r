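## Synthetic open-search data generator: tryptic-like peptides, spectra with
## b/y ladders, planted diagnostic features, noise, optional co-fragmentation
## contamination, and shuffled-mass-shift decoys.

#' Simulation configuration
#'
#' Describes an open-search-like dataset with planted diagnostic features.
#' The defaults emulate a labile modification of +226.0594 Da carrying one
#' diagnostic ion, one peptide remainder mass and one y-series fragment
#' remainder mass: backbone fragments spanning the modified residue either
#' retain the planted remainder (with the configured per-fragment retention
#' probability) or lose the modification completely; fully shifted fragments
#' are not produced.
#'
#' @param n_mod,n_unmod numbers of modified and unmodified PSMs.
#' @param mass_shifts data.frame with columns `shift` (Da) and `weight`
#'   (sampling weight across modified PSMs).
#' @param diagnostic_ions data.frame with columns `shift`, `mz`,
#'   `prevalence` (per-spectrum Bernoulli probability) and `intensity`
#'   (mean, percent of base peak).
#' @param peptide_remainders data.frame with columns `shift`, `mass`,
#'   `prevalence`, `intensity`; peaks are planted at `P + mass`.
#' @param fragment_remainders data.frame with columns `shift`, `mass`,
#'   `series` (`"b"`/`"y"`), `retention` (per-fragment probability),
#'   `intensity`, and optional `adjacent_residue` (force this residue next
#'   to the modification site, reproducing a deterministic echo; `NA` =
#'   random neighbours).
#' @param noise_peaks number of uniform random noise peaks per spectrum.
#' @param noise_mz_range,noise_intensity_range noise peak ranges.
#' @param ladder_prob per-fragment probability that a backbone ion is
#'   observed.
#' @param ladder_intensity_range uniform intensity range of backbone ions.
#' @param peptide_length_range tryptic-like peptide length range (peptides
#'   end in K/R).
#' @param contamination probability that a spectrum also receives the signal
#'   peaks of a second, modified peptide (co-fragmentation).
#' @param contaminant_scale intensity scale of contaminant peaks.
#' @param mz_jitter_ppm Gaussian m/z error (ppm, 1 s.d.) applied to every
#'   peak.
#' @param shift_jitter Gaussian error (Da, 1 s.d.) on the observed MS1 mass
#'   shift.
#' @param log_intensity_sd log10 s.d. of planted-feature intensity jitter.
#' @param seed integer seed; identical configs produce byte-identical
#'   outputs.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_mod = 400, n_unmod = 400,
                       mass_shifts = data.frame(shift = 226.0594, weight = 1),
                       diagnostic_ions = data.frame(
                         shift = 226.0594, mz = 241.0626,
                         prevalence = 0.6, intensity = 30),
                       peptide_remainders = data.frame(
                         shift = 226.0594, mass = 94.0168,
                         prevalence = 0.5, intensity = 25),
                       fragment_remainders = data.frame(
                         shift = 226.0594, mass = 94.0168, series = "y",
                         retention = 0.3, intensity = 20,
                         adjacent_residue = NA_character_),
                       noise_peaks = 30, noise_mz_range = c(100, 1500),
                       noise_intensity_range = c(0.5, 8),
                       ladder_prob = 0.7,
                       ladder_intensity_range = c(20, 100),
                       peptide_length_range = c(7, 20),
                       contamination = 0, contaminant_scale = 0.3,
                       mz_jitter_ppm = 5, shift_jitter = 5e-4,
                       log_intensity_sd = 0.3, seed = 42) {
  cfg <- as.list(environment())
  if (is.null(cfg$fragment_remainders$adjacent_residue) &&
      nrow(cfg$fragment_remainders)) {
    cfg$fragment_remainders$adjacent_residue <- NA_character_
  }
  probs <- c(cfg$diagnostic_ions$prevalence, cfg$peptide_remainders$prevalence,
             cfg$fragment_remainders$retention, cfg$ladder_prob,
             cfg$contamination)
  if (any(probs < 0 | probs > 1)) stop("prevalences/probabilities must lie in [0, 1]")
  ints <- c(cfg$diagnostic_ions$intensity, cfg$peptide_remainders$intensity,
            cfg$fragment_remainders$intensity)
  if (any(ints <= 0)) stop("planted intensities must be positive")
  if (cfg$n_mod > 0 && nrow(cfg$mass_shifts) == 0) {
    stop("modified PSMs requested but no mass shifts configured")
  }
  if (cfg$peptide_length_range[1] < 6) {
    stop("peptide_length_range must start at 6 or more")
  }
  ## per (shift, series) the retention probabilities must be a sub-distribution
  if (nrow(cfg$fragment_remainders)) {
    key <- paste(cfg$fragment_remainders$shift, cfg$fragment_remainders$series)
    tot <- tapply(cfg$fragment_remainders$retention, key, sum)
    if (any(tot > 1)) stop("fragment remainder retention probabilities exceed 1")
  }
  structure(cfg, class = "sim_config")
}

ln_intensity <- function(mean_int, n, sd_log10) {
  10^(log10(mean_int) + rnorm(n, 0, sd_log10))
}

## Signal peaks (backbone ladder + planted features) of one precursor.
sim_signal_peaks <- function(cfg, peptide, mod_pos, shift) {
  th <- theoretical_peptide(peptide)
  len <- nchar(peptide)
  mz <- numeric(0)
  int <- numeric(0)
  for (series in c("b", "y")) {
    f <- th[[series]]
    nfrag <- length(f)
    present <- which(runif(nfrag) < cfg$ladder_prob)
    if (!length(present)) next
    spans <- if (is.na(mod_pos)) rep(FALSE, length(present)) else if (series == "b") {
      present >= mod_pos
    } else {
      present >= (len - mod_pos + 1L)
    }
    rows <- cfg$fragment_remainders[
      cfg$fragment_remainders$shift == shift &
        cfg$fragment_remainders$series == series, , drop = FALSE]
    for (t in seq_along(present)) {
      j <- present[t]
      placed <- FALSE
      if (spans[t] && nrow(rows)) {
        u <- runif(1)
        cum <- 0
        for (r in seq_len(nrow(rows))) {
          cum <- cum + rows$retention[r]
          if (u < cum) {
            mz <- c(mz, f[j] + rows$mass[r])
            int <- c(int, ln_intensity(rows$intensity[r], 1, cfg$log_intensity_sd))
            placed <- TRUE
            break
          }
        }
      }
      if (!placed) {
        ## the labile modification is lost completely during fragmentation:
        ## spanning fragments appear at their unshifted mass
        mz <- c(mz, f[j])
        int <- c(int, runif(1, cfg$ladder_intensity_range[1],
                            cfg$ladder_intensity_range[2]))
      }
    }
  }
  if (!is.na(mod_pos)) {
    di <- cfg$diagnostic_ions[cfg$diagnostic_ions$shift == shift, , drop = FALSE]
    if (nrow(di)) {
      hit <- runif(nrow(di)) < di$prevalence
      if (any(hit)) {
        mz <- c(mz, di$mz[hit])
        int <- c(int, ln_intensity(di$intensity[hit], sum(hit),
                                   cfg$log_intensity_sd))
      }
    }
    pr <- cfg$peptide_remainders[cfg$peptide_remainders$shift == shift, , drop = FALSE]
    if (nrow(pr)) {
      hit <- runif(nrow(pr)) < pr$prevalence
      if (any(hit)) {
        mz <- c(mz, th$P + pr$mass[hit])
        int <- c(int, ln_intensity(pr$intensity[hit], sum(hit),
                                   cfg$log_intensity_sd))
      }
    }
  }
  list(mz = mz, int = int)
}

#' Generate a synthetic open-search dataset
#'
#' Builds random tryptic-like peptides, assigns planted mass shifts by
#' weight, and simulates one MS/MS spectrum per PSM: a partially observed
#' b/y ladder (fragments spanning the modification site either retain a
#' planted remainder mass or lose the modification completely), planted
#' diagnostic ions and peptide remainder peaks, uniform noise peaks, and
#' optional contaminant signal from a co-fragmented modified peptide. All
#' peak m/z values carry Gaussian ppm error; observed MS1 shifts carry
#' Gaussian Da error; E-values are log-uniform.
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; if given, writes `spectra.mgf`,
#'   `psms.tsv` and `truth.tsv` there.
#' @return list with `spectra` (named spectrum list), `psms` (PSM
#'   data.frame), `truth` (planted feature table), and `config`.
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  res <- with_seed(cfg$seed, {
    n <- cfg$n_mod + cfg$n_unmod
    if (n == 0L) stop("empty simulation")
    is_mod <- rep(c(TRUE, FALSE), c(cfg$n_mod, cfg$n_unmod))
    lens <- sample(seq(cfg$peptide_length_range[1], cfg$peptide_length_range[2]),
                   n, replace = TRUE)
    aa <- names(AA_MONO)
    seen <- new.env(parent = emptyenv())
    peptides <- character(n)
    for (i in seq_len(n)) {
      repeat {
        p <- paste0(paste(sample(aa, lens[i] - 1L, replace = TRUE), collapse = ""),
                    sample(c("K", "R"), 1))
        if (is.null(seen[[p]])) {
          assign(p, TRUE, envir = seen)
          peptides[i] <- p
          break
        }
      }
    }
    shift_true <- numeric(n)
    mod_pos <- rep(NA_integer_, n)
    if (cfg$n_mod > 0) {
      si <- sample(seq_len(nrow(cfg$mass_shifts)), cfg$n_mod, replace = TRUE,
                   prob = cfg$mass_shifts$weight)
      shift_true[is_mod] <- cfg$mass_shifts$shift[si]
      mod_pos[is_mod] <- vapply(lens[is_mod], function(l) {
        sample(seq.int(3L, l - 2L), 1)
      }, integer(1))
      ## force adjacent residues where a deterministic echo is requested
      fr <- cfg$fragment_remainders
      if (nrow(fr)) {
        for (r in which(!is.na(fr$adjacent_residue))) {
          tgt <- which(is_mod & shift_true == fr$shift[r])
          at <- if (fr$series[r] == "y") mod_pos[tgt] - 1L else mod_pos[tgt] + 1L
          for (t in seq_along(tgt)) {
            substr(peptides[tgt[t]], at[t], at[t]) <- fr$adjacent_residue[r]
          }
        }
      }
    }

    spectra <- vector("list", n)
    ids <- sprintf("sim.%05d", seq_len(n))
    mod_idx <- which(is_mod)
    for (i in seq_len(n)) {
      sig <- sim_signal_peaks(cfg, peptides[i], mod_pos[i], shift_true[i])
      mz <- c(sig$mz, runif(cfg$noise_peaks, cfg$noise_mz_range[1],
                            cfg$noise_mz_range[2]))
      int <- c(sig$int, runif(cfg$noise_peaks, cfg$noise_intensity_range[1],
                              cfg$noise_intensity_range[2]))
      if (cfg$contamination > 0 && length(mod_idx) &&
          runif(1) < cfg$contamination) {
        d <- mod_idx[sample.int(length(mod_idx), 1)]
        dsig <- sim_signal_peaks(cfg, peptides[d], mod_pos[d], shift_true[d])
        mz <- c(mz, dsig$mz)
        int <- c(int, dsig$int * cfg$contaminant_scale)
      }
      mz <- mz * (1 + rnorm(length(mz), 0, cfg$mz_jitter_ppm) * 1e-6)
      spectra[[i]] <- new_spectrum(ids[i], mz, int)
    }
    names(spectra) <- ids

    psms <- data.frame(
      spectrum_id = ids,
      peptide = peptides,
      mods = "",
      charge = sample(2:3, n, replace = TRUE),
      mass_shift = shift_true + rnorm(n, 0, cfg$shift_jitter),
      evalue = 10^runif(n, -5, -1),
      stringsAsFactors = FALSE
    )
    psms$var_mods <- rep(list(data.frame(pos = character(), delta = numeric(),
                                         stringsAsFactors = FALSE)), n)

    truth <- rbind(
      if (nrow(cfg$diagnostic_ions)) data.frame(
        shift = cfg$diagnostic_ions$shift, feature_class = "diagnostic",
        series = NA_character_, mass = cfg$diagnostic_ions$mz,
        prevalence = cfg$diagnostic_ions$prevalence,
        stringsAsFactors = FALSE),
      if (nrow(cfg$peptide_remainders)) data.frame(
        shift = cfg$peptide_remainders$shift,
        feature_class = "peptide_remainder", series = NA_character_,
        mass = cfg$peptide_remainders$mass,
        prevalence = cfg$peptide_remainders$prevalence,
        stringsAsFactors = FALSE),
      if (nrow(cfg$fragment_remainders)) data.frame(
        shift = cfg$fragment_remainders$shift,
        feature_class = "fragment_remainder",
        series = cfg$fragment_remainders$series,
        mass = cfg$fragment_remainders$mass,
        prevalence = cfg$fragment_remainders$retention,
        stringsAsFactors = FALSE)
    )
    if (is.null(truth)) {
      truth <- data.frame(shift = numeric(), feature_class = character(),
                          series = character(), mass = numeric(),
                          prevalence = numeric(), stringsAsFactors = FALSE)
    }

    ## feasibility: warn if a planted diagnostic ion collides with backbone
    ## ions of many peptides
    if (nrow(cfg$diagnostic_ions) && any(is_mod)) {
      check <- peptides[is_mod][seq_len(min(100, sum(is_mod)))]
      for (r in seq_len(nrow(cfg$diagnostic_ions))) {
        ion <- cfg$diagnostic_ions$mz[r]
        coll <- mean(vapply(check, function(p) {
          th <- theoretical_peptide(p)
          any(abs(c(th$b, th$y) - ion) <= ppm_tol(ion, 20))
        }, logical(1)))
        if (coll > 0.1) {
          warning(sprintf(
            "planted diagnostic ion %.4f collides with backbone ions of %.0f%% of peptides",
            ion, 100 * coll), call. = FALSE)
        }
      }
    }
    list(spectra = spectra, psms = psms, truth = truth, config = cfg)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(res$spectra, file.path(out_dir, "spectra.mgf"))
    write_psm_table(res$psms, file.path(out_dir, "psms.tsv"))
    write.table(res$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}

#' Shuffle mass shifts across PSMs
#'
#' Builds a decoy PSM table by uniformly permuting the observed MS1 mass
#' shifts across all PSMs; every other column is untouched, so the multiset
#' of shifts (and all spectra) is preserved while the shift-to-spectrum
#' association is destroyed. Mining the shuffled table against the same
#' spectra estimates the miner's false discovery behaviour.
#'
#' @param psms PSM data.frame (>= 2 rows).
#' @param seed integer seed for the permutation.
#' @return the permuted PSM data.frame.
#' @export
shuffle_mass_shifts <- function(psms, seed = 1L) {
  if (nrow(psms) < 2L) stop("need at least two PSMs to shuffle")
  perm <- with_seed(seed, sample.int(nrow(psms)))
  psms$mass_shift <- psms$mass_shift[perm]
  psms
}
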