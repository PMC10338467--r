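---
title: "Mining diagnostic spectral features of peptide modifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining diagnostic spectral features of peptide modifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diagmine)
```

## The problem

Open and mass-offset database searches identify modified peptides only
through a precursor-level mass shift: the MS1 delta mass between the observed
precursor and the unmodified sequence. The MS/MS spectra of those peptides,
however, carry much richer evidence of the modification — oxonium- and
immonium-like ions produced by the modification itself, intact peptide ions
that have lost part of the modification, and backbone fragments that retain a
portion of it. When these signals are known they can be fed back into search
engines to improve the recovery and localisation of modified peptides; for
most modifications, and for most combinations of instrument settings, they
are not known.

`diagmine` mines them automatically. Given MS/MS spectra (MGF or mzML,
assumed decharged and deisotoped so all fragments are singly charged) and an
open-search PSM table, it discovers, for every MS1 mass shift, three classes
of diagnostic features:

* **diagnostic ions** — unannotated spectrum peaks at a fixed m/z,
  independent of the peptide (e.g. an adenine ion at 136.0618 for
  ADP-ribosylation);
* **peptide remainder masses** — offsets `mz - P` between spectrum peaks and
  the theoretical unshifted singly protonated peptide mass `P` (the Y-ions of
  glycoproteomics; a remainder of 0 is the complete loss of the
  modification);
* **fragment remainder masses** — offsets `mz - F_j` between spectrum peaks
  and theoretical unshifted b- or y-ions `F_j`, i.e. the part of the
  modification retained on backbone fragments.

Every candidate is validated statistically against unmodified peptides, so
features that merely reflect dataset-wide background (solvent ions, common
neutral losses, immonium ions of unmodified residues) are rejected.

## The procedure

**Binning by mass shift.** Observed MS1 mass shifts are histogrammed at
0.0002 Da, smoothed with a 5-point discrete normal kernel (sigma = one bin,
renormalised; edge bins absorb overflow so the PSM count is conserved), and
local maxima with topographic prominence of at least 0.3 times their height
are kept. Each apex is scored by signal-to-noise — the PSM count within
±0.002 Da minus the counts in the two flanking 0.01 Da windows — and the 500
best apexes are retained. PSMs are assigned to the nearest apex within
0.004 Da (the same half-width used for the apex count, chosen for internal
consistency; it spans eight standard deviations of typical open-search
delta-mass error). The bin nearest zero and within ±0.002 Da of zero is the
*zero bin*: unmodified peptides, used as the statistical background and never
itself tested.

**Representative PSMs.** Within a bin, PSMs are grouped by peptide ion
(sequence, modification state, precursor charge) and the lowest-E-value PSM
per group is kept, at most 1000 per bin (uniformly sampled under the run
seed). This prevents abundant peptides from dominating the pooled evidence.

**Per-PSM feature vectors.** Spectra are normalised to base peak 100 and cut
to the 150 most intense peaks (ties broken toward lower m/z). For the
diagnostic-ion and peptide-remainder calculations, peaks matching theoretical
a/b/y ions *or* their fully shifted counterparts (series mass + delta mass)
are stripped at 20 ppm, so that backbone fragments carrying the modification
are not mistaken for diagnostic ions. For fragment remainders only unshifted
a/b/y ions are stripped, leaving shifted fragments available as evidence; b
and y series are then differenced independently against every remaining peak,
giving an m-by-n offset matrix per series.

**Recurring features.** Each class pools its per-PSM values into a 0.2 mDa
histogram (weight = intensity / number of representative PSMs, so bins are in
percent-of-base-peak per spectrum). Remainder histograms are truncated at
−250 Da — more negative offsets would require losing multiple residues. The
histogram is smoothed by a rolling mean whose half-width grows with mass,
`tol * (mass_i + mass_x) / 1e6`: `mass_x` is the mean peptide (or fragment)
mass of the bin, because the ppm uncertainty of a remainder is governed by
the mass of the ions it was computed from, not by the remainder itself; for
diagnostic ions `mass_x = 150`. Peaks are found by descending from local
maxima until a zero bin or a >1% bin-to-bin rise, integrated over the
tolerance window around the apex (ignoring neighbouring peak boundaries), and
kept if their area exceeds 0.1% of base peak per spectrum. Of two peaks
closer than the larger of their tolerance windows, the weaker is dropped.
The reported mass is the intensity centroid of the *unsmoothed* histogram
inside the integration window: the rolling mean flattens a narrow peak into a
plateau whose argmax carries little information, while the raw entries retain
sub-bin accuracy (empirically well under a millidalton at the default
simulation scale).

**Validation.** Every candidate is quantified in each representative PSM of
the bin and of the zero bin, absent features coded as zero: diagnostic ions
and peptide remainders take the most intense peak in the tolerance window;
fragment remainders require peaks at `F_j + mass` for **at least two** series
positions (offsets arise from m-by-n differencing and single matches are
noise) and take the mean of the matched peak intensities. The two intensity
lists are compared with a two-sided Mann-Whitney U test (midranks,
tie-corrected variance, 0.5 continuity correction); the AUC effect size
`U/(n1*n2)` is reported as the probability that a modified PSM shows the
feature more intensely than an unmodified one. P-values are multiplied by the
number of candidates tested in the same class for the bin (fragment
remainders of both series count as one class, since they are one feature
type) to give E-values. A feature is reported when its E-value is at most
0.05, its mean-intensity fold change (modified over unmodified, zeros
included; infinite when absent from the background) is at least 3, it occurs
in at least 25% of modified representative PSMs (15% for fragment
remainders), and — fragment remainders only — at least 12.5% of the
identified ions of its series carry the shift.

**Echo correction.** Because one experimental peak is differenced against
every theoretical fragment, a true fragment remainder also produces "echo"
features offset by the masses of residues adjacent to the matched site. For
each retained fragment remainder, the matched site j is the minimal shifted
fragment index per feature-positive PSM; if a single residue occupies series
position j+1 in more than half of those PSMs its mass is subtracted (this
rule takes precedence), else if one residue occupies position j its mass is
added; at most one adjustment is made. Since the residues adjacent to true
sites are pseudo-random, any fragment remainder weaker than the first
corrected one is treated as noise: results are ranked by mean modified-PSM
intensity and truncated after the first corrected mass.

## Targeted extraction

`extract_ion_matrix()` quantifies user-specified ions across all PSMs on raw
(unstripped) spectra — stripping would force neutral losses that naturally
co-occur into anticorrelation. `spearman_correlation()` gives the rank
correlation between ions over PSMs (base-peak normalisation makes
relationships between ions nonlinear, so rank correlation is the appropriate
choice), and `discrimination_curves()` summarises each ion's ability to
separate modified from unmodified spectra: a precision curve (probability of
"modified" given the ion is present at an intensity within each decile band
of its nonzero intensities — the banding is a package choice, as any finite
sample needs one) and a Mann-Whitney AUC over the zero-included intensity
vectors.

## The synthetic data generator

No public dataset is small enough, or carries known-enough truth, to test a
feature miner end to end at desk scale, so `sim_config()` /
`generate_dataset()` simulate open-search output with planted truth:

* random tryptic-like peptides (length 7–20, C-terminal K/R, otherwise
  uniform residues), one spectrum per PSM;
* a partially observed b/y ladder (each fragment present with probability
  0.7, uniform intensity 20–100% of base peak);
* a *labile* modification model: fragments spanning the modification site
  either retain a planted remainder mass (per-fragment retention
  probability) or lose the modification completely and appear unshifted;
  fully shifted fragments are not simulated, matching the behaviour of
  labile modifications such as nucleoside crosslinks and glycans for which
  remainder mining matters most;
* planted diagnostic ions and peptide remainder peaks by per-spectrum
  Bernoulli prevalence, with log-normal intensity jitter (sigma = 0.3 in
  log10, so zero-inflation in quantified intensities comes only from
  absence);
* 30 uniform noise peaks per spectrum (m/z 100–1500, intensity 0.5–8% of
  base peak), Gaussian 5 ppm m/z error on every peak, Gaussian 5e-4 Da error
  on the observed mass shift, log-uniform E-values, and optional
  co-fragmentation contamination (off by default);
* `shuffle_mass_shifts()` permutes the delta-mass column for decoy runs.

The default configuration — 400 modified PSMs at +226.0594 Da with a
diagnostic ion at 241.0626 m/z (prevalence 0.6, mean intensity 30), a
peptide remainder of +94.0168 Da (prevalence 0.5, intensity 25) and a
y-series fragment remainder of +94.0168 Da (retention 0.3, intensity 20),
against 400 unmodified PSMs — is the package's reference condition: it
emulates a nucleoside-analog crosslink whose intact mass splits into a
ribose-like and a base-like part. The test suite runs the full miner on this
condition across ten seeds (all three features must be recovered within
±0.01 Da and nothing farther than 0.05 Da from a planted mass may appear)
and on twenty decoy permutations (at least 19 of 20 must yield zero
features). The generator's `adjacent_residue` option pins the residue next
to the modification site, producing a deterministic echo: with a planted
y-series remainder of 151.0383 Da, glycine fixed before the site and
retention 0.9 (so the minimal matched fragment is usually the first spanning
one), the miner must report 94.0168 Da with the corrected flag set and
truncate everything ranked below it.

What the simulation does **not** model — isotope envelopes, multiply charged
fragments, chimeric charge states, retention time, intensity correlation
between fragments of one ladder, realistic peptide mass distributions —
bounds what a passing suite shows: the statistics and bookkeeping of the
miner are correct under the stated noise model, not that real spectra obey
that model.

## Numerical choices and edge cases

* Monoisotopic masses throughout; proton 1.00727646688 Da, water
  18.0105646863 Da, CO 27.99491462 Da. Matching tolerance is symmetric ppm
  on the theoretical mass, default 20 ppm.
* All smoothing operations conserve mass exactly (difference-array scatter
  with edge absorption); the test suite asserts conservation to 1e-9
  relative.
* Runs of equal histogram bins are one local maximum, at the run centre.
* The MS1 prominence threshold 0.3 is relative to apex height
  (dimensionless), making peak picking invariant to dataset size.
* Ties everywhere are broken deterministically (lower m/z at the top-150
  cutoff, lexicographically smallest spectrum id among equal E-values), and
  all sampling (representative cap, generator, shuffling) is seeded, so a
  run is reproducible end to end.
* A fold change over a background mean of exactly zero is reported as
  infinite and passes the fold filter; the Mann-Whitney test is unaffected.
* With every intensity tied the test degenerates gracefully (p = 1,
  AUC = 0.5).
* Intensities are not re-normalised after ion stripping; stripped-peak
  intensities simply leave the vector.
* Bins with fewer than 20 representative PSMs are skipped with a warning —
  rank statistics on a handful of spectra are not meaningful.

## Known limitations

* c/z ions, internal fragments and multiply charged fragments are out of
  scope; spectra must be decharged/deisotoped upstream.
* Spectra are matched to PSMs by exact spectrum id; no fuzzy scan matching.
* E-values control multiplicity per class and bin only; no correction is
  applied across mass-shift bins.
* The echo corrector applies at most one residue adjustment; remainders that
  are echoes across two or more residues are truncated by the ranking rule
  rather than corrected.
* The normal approximation to the Mann-Whitney null is used at every sample
  size; the suite verifies agreement with the exact permutation distribution
  within 0.05 for 8+8 samples, and bins are required to have at least 20
  representatives, where the approximation is comfortably adequate.

## A minimal session

```{r example, eval = FALSE}
library(diagmine)

ds <- generate_dataset(sim_config(seed = 7))
report <- mine_all(ds$spectra, ds$psms, mine_params(seed = 11))
report$features[, c("bin_apex", "feature_class", "mass",
                    "percent_mod", "fold_change", "e_value", "auc")]

## decoy: destroy the shift-spectrum association, expect nothing
decoy <- shuffle_mass_shifts(ds$psms, seed = 99)
nrow(mine_all(ds$spectra, decoy, mine_params(seed = 11))$features)
```
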