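test_that("Mann-Whitney AUC and p-value behave on the canonical cases", {
  r <- mann_whitney_auc(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$auc, 0)
  expect_equal(perm_pvalue(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_lt(abs(r$p_value - 0.1), 0.05)

  tied <- mann_whitney_auc(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$p_value, 1)
})

test_that("AUC equals the brute-force pairwise win fraction", {
  set.seed(61)
  for (r in 1:200) {
    x <- sample(0:3, sample(1:7, 1), replace = TRUE)
    y <- sample(0:3, sample(1:7, 1), replace = TRUE)
    expect_equal(mann_whitney_auc(x, y)$auc, brute_auc(x, y),
                 tolerance = 1e-12)
  }
})

test_that("AUC symmetry and rank invariance hold", {
  set.seed(62)
  for (r in 1:25) {
    x <- rnorm(sample(2:10, 1))
    y <- c(rnorm(sample(2:10, 1)), sample(x, 1))  # force an occasional tie
    a <- mann_whitney_auc(x, y)
    b <- mann_whitney_auc(y, x)
    expect_equal(a$auc + b$auc, 1, tolerance = 1e-12)
    shifted <- mann_whitney_auc(x + 7.5, y + 7.5)
    expect_equal(shifted$auc, a$auc, tolerance = 1e-12)
    expect_equal(shifted$p_value, a$p_value, tolerance = 1e-12)
    expect_equal(shifted$u_stat, a$u_stat, tolerance = 1e-12)
  }
})

test_that("the corrected normal approximation agrees with wilcox.test", {
  set.seed(63)
  for (r in 1:20) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    ours <- mann_whitney_auc(x, y)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(unname(ours$u_stat), unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("feature quantification codes missing features as zero", {
  pep <- "PEPTIDEK"
  t <- theoretical_peptide(pep)
  psms <- make_psms(c("s1", "s2"), pep, 226.0594)
  spectra <- list(
    s1 = toy_spectrum("s1", c(300.0, 500.0), c(42, 10)),
    s2 = toy_spectrum("s2", c(310.0, 510.0), c(30, 10))
  )
  v <- quantify_feature(psms, spectra,
                        list(feature_class = "diagnostic", mass = 300.0))
  expect_equal(v, c(42, 0))
})

test_that("fragment remainders require at least two shifted series ions", {
  pep <- "PEPTIDEK"
  t <- theoretical_peptide(pep)
  psms <- make_psms(c("one", "two"), pep, 226.0594)
  spectra <- list(
    one = toy_spectrum("one", t$y[2] + 50.0, 40),                  # 1 shifted ion
    two = toy_spectrum("two", c(t$y[2] + 50.0, t$y[4] + 50.0), c(40, 20))
  )
  v <- quantify_feature(psms, spectra,
                        list(feature_class = "fragment_remainder_y", mass = 50.0),
                        mass_x = mean(t$y))
  expect_equal(v, c(0, 30))  # mean of the two matched peak intensities
})

test_that("feature filtering applies E-value, fold, prevalence and propensity rules", {
  base <- data.frame(
    feature_class = c("diagnostic", "diagnostic", "peptide_remainder",
                      "fragment_remainder_y", "fragment_remainder_y"),
    p_value = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6),
    fold_change = c(2.9, 10, 10, 10, 10),
    percent_mod = c(90, 10, 60, 20, 20),
    propensity = c(NA, NA, NA, 14, 10),
    stringsAsFactors = FALSE
  )
  out <- filter_features(base)
  # row 1: fold 2.9 < 3 removed; row 2: prevalence 10 < 25 removed;
  # row 4: fragment remainder at 20% prevalence / 14% propensity retained;
  # row 5: propensity 10 < 12.5 removed
  expect_equal(out$feature_class, c("peptide_remainder", "fragment_remainder_y"))
  expect_equal(out$propensity[2], 14)
  # E-value multiplies by the class test count (fragment b+y share a class)
  expect_equal(out$e_value, c(1e-6 * 1, 1e-6 * 2), tolerance = 1e-15)
  expect_true(all(out$e_value >= out$p_value))
})

test_that("feature filtering is monotone in its thresholds", {
  set.seed(71)
  stats <- data.frame(
    feature_class = sample(c("diagnostic", "peptide_remainder",
                             "fragment_remainder_b"), 60, replace = TRUE),
    p_value = runif(60, 0, 0.2),
    fold_change = runif(60, 0, 10),
    percent_mod = runif(60, 0, 100),
    stringsAsFactors = FALSE
  )
  stats$propensity <- ifelse(grepl("fragment", stats$feature_class),
                             runif(60, 0, 40), NA)
  loose <- filter_features(stats, alpha = 0.1, min_fold = 2,
                           min_prev_diag = 10, min_prev_peprem = 10,
                           min_prev_fragrem = 5, min_propensity = 5)
  tight <- filter_features(stats, alpha = 0.05, min_fold = 3,
                           min_prev_diag = 25, min_prev_peprem = 25,
                           min_prev_fragrem = 15, min_propensity = 12.5)
  key <- function(d) paste(d$feature_class, d$p_value, d$fold_change)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("echo correction subtracts the dominant adjacent residue", {
  # glycine follows the matched site in 60% of feature-positive PSMs
  peps <- c(rep("AAAGAAAK", 6), "AAAVAAAK", "AAASAAAK", "AAATAAAK", "AAAHAAAK")
  sites <- list(data.frame(peptide = peps, min_j = 3L))  # b series: j+1 = 4
  res <- data.frame(bin_apex = 226.0594, feature_class = "fragment_remainder_b",
                    ion_series = "b", mass = 151.03830, avg_int_mod = 20,
                    stringsAsFactors = FALSE)
  out <- correct_fragment_echoes(res, sites)
  expect_true(out$echo_corrected)
  expect_equal(out$mass, 94.01684, tolerance = 1e-5)
  expect_equal(out$delta_mod_mass, 94.01684 - 226.0594, tolerance = 1e-5)

  # no residue above 50% at j or j+1: mass unchanged, flag unset
  peps2 <- c("AAVGAAAK", "AASVAAAK", "AATSAAAK", "AAHTAAAK", "AAGHAAAK")
  out2 <- correct_fragment_echoes(res, list(data.frame(peptide = peps2,
                                                       min_j = 3L)))
  expect_false(out2$echo_corrected)
  expect_equal(out2$mass, 151.03830)
})

test_that("echo correction adds the residue at the matched site when dominant", {
  # y series, min_j = 5 on length-8 peptides: residue at series position 5
  # is peptide[4] (fixed G); position 6 is peptide[3] (all different)
  peps <- sprintf("AA%sGAAAK", c("V", "S", "T", "H", "L", "M", "F", "W", "Y", "N"))
  sites <- list(data.frame(peptide = peps, min_j = 5L))
  res <- data.frame(bin_apex = 94.0168, feature_class = "fragment_remainder_y",
                    ion_series = "y", mass = 37.0, avg_int_mod = 5,
                    stringsAsFactors = FALSE)
  out <- correct_fragment_echoes(res, sites)
  expect_true(out$echo_corrected)
  expect_equal(out$mass, 37.0 + AA_MONO[["G"]], tolerance = 1e-9)
})

test_that("features below the first corrected mass are truncated", {
  res <- data.frame(
    bin_apex = 226.0594,
    feature_class = "fragment_remainder_b", ion_series = "b",
    mass = c(100, 151.0383, 80, 60),
    avg_int_mod = c(40, 30, 20, 10),
    stringsAsFactors = FALSE)
  mixed <- c("AVLVAAAK", "ASMSAAAK", "ATFTAAAK", "AHWHAAAK")  # nothing dominant
  sites <- list(
    data.frame(peptide = mixed, min_j = 2L),
    data.frame(peptide = rep("AAAGAAAK", 4), min_j = 3L),  # G at j+1 -> corrected
    data.frame(peptide = mixed, min_j = 2L),
    data.frame(peptide = mixed, min_j = 2L))
  out <- correct_fragment_echoes(res, sites)
  expect_equal(nrow(out), 2)
  expect_equal(out$mass[1], 100)
  expect_equal(out$echo_corrected, c(FALSE, TRUE))
})
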