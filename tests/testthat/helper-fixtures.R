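# Small in-code fixtures shared across tests.

toy_spectrum <- function(id, mz, intensity) {
  o <- order(mz)
  list(spectrum_id = id, mz = mz[o], intensity = intensity[o])
}

make_psms <- function(spectrum_id, peptide, mass_shift, evalue = 1e-3,
                      charge = 2L, mods = "") {
  n <- max(lengths(list(spectrum_id, peptide, mass_shift, evalue, charge)))
  df <- data.frame(
    spectrum_id = rep_len(spectrum_id, n),
    peptide = rep_len(peptide, n),
    mods = rep_len(mods, n),
    charge = rep_len(as.integer(charge), n),
    mass_shift = rep_len(mass_shift, n),
    evalue = rep_len(evalue, n),
    stringsAsFactors = FALSE
  )
  df$var_mods <- lapply(df$mods, parse_mod_string)
  df
}

# Full mzML header row set required by mzR's writer.
mzml_header <- function(n_peaks, base_mz, base_int, precursor_mz) {
  k <- length(n_peaks)
  data.frame(
    seqNum = seq_len(k), acquisitionNum = seq_len(k), msLevel = 2L,
    polarity = 1L, peaksCount = as.integer(n_peaks),
    totIonCurrent = base_int, retentionTime = seq_len(k),
    basePeakMZ = base_mz, basePeakIntensity = base_int,
    collisionEnergy = 25, ionisationEnergy = 0,
    lowMZ = 0, highMZ = 2000,
    precursorScanNum = 0L, precursorMZ = precursor_mz,
    precursorCharge = 1L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(k)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_
  )
}
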