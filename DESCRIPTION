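Package: diagmine
Title: Mining Diagnostic Spectral Features of Peptide Modifications
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Discovers spectral features diagnostic of peptide modifications
    from open-search proteomics results. Peptide-spectrum matches are grouped
    by observed precursor (MS1) mass shift, and three classes of candidate
    features are mined from the MS/MS spectra of each shift: diagnostic ions,
    peptide remainder masses, and b-/y-ion fragment remainder masses.
    Candidates are validated against the unmodified-peptide background with a
    tie- and continuity-corrected Mann-Whitney U test plus fold-change,
    prevalence and ion-propensity filters, including correction of
    sequence-dependent "echo" artifacts among fragment remainder masses.
    The package also provides targeted extraction of user-specified ions with
    rank-correlation and precision/AUC summaries, and a synthetic open-search
    data generator (spectra, PSM tables, and shuffled-mass-shift decoys) for
    end-to-end validation of the miner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
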