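test_that("MGF write/read round trip preserves peak lists", {
  sp <- list(
    a = toy_spectrum("a", c(100.123456, 250.5, 900.000001), c(10, 100, 55.5)),
    b = toy_spectrum("b", c(150.2, 300.4), c(1.25, 80))
  )
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, f)
  rd <- read_spectra(f, "mgf")
  expect_named(rd, c("a", "b"))
  expect_equal(length(rd$a$mz), 3)
  for (id in names(sp)) {
    expect_lt(max(abs(rd[[id]]$mz - sp[[id]]$mz)), 1e-6)
    expect_lt(max(abs(rd[[id]]$intensity - sp[[id]]$intensity)), 1e-6)
  }
})

test_that("MGF reader skips empty scans and rejects duplicates and junk", {
  f <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=ok", "100.0 10", "END IONS",
               "BEGIN IONS", "TITLE=empty", "END IONS"), f)
  expect_warning(sp <- read_mgf(f), "empty.*skipped|skipped")
  expect_named(sp, "ok")

  writeLines(c("BEGIN IONS", "TITLE=x", "100.0 10", "END IONS",
               "BEGIN IONS", "TITLE=x", "200.0 10", "END IONS"), f)
  expect_error(read_mgf(f), "duplicate")

  writeLines(c("BEGIN IONS", "TITLE=bad", "100.0 ten", "END IONS"), f)
  expect_error(read_mgf(f), "bad")
})

test_that("mzML and MGF readers return identical peak lists for the same scans", {
  skip_if_not_installed("mzR")
  mz1 <- c(100.1002, 200.2005, 300.3008)
  it1 <- c(10, 50, 100)
  mz2 <- c(150.55, 250.55)
  it2 <- c(30, 60)
  mgf <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(s1 = toy_spectrum("s1", mz1, it1),
                 s2 = toy_spectrum("s2", mz2, it2)), mgf)
  ml <- withr::local_tempfile(fileext = ".mzML")
  hd <- mzml_header(c(3L, 2L), c(300.3008, 250.55), c(100, 60), c(500, 600))
  mzR::writeMSData(list(cbind(mz = mz1, intensity = it1),
                        cbind(mz = mz2, intensity = it2)), ml, header = hd)
  a <- read_spectra(mgf, "mgf")
  expect_warning(b <- read_spectra(ml, "mzml"), "decharged")
  expect_length(b, 2)
  for (k in 1:2) {
    expect_lt(max(abs(a[[k]]$mz - b[[k]]$mz)), 1e-6)
    expect_lt(max(abs(a[[k]]$intensity - b[[k]]$intensity)), 1e-6)
  }
})

test_that("preprocessing rescales to base peak 100 and keeps the top peaks", {
  s <- toy_spectrum("s", c(100, 200, 300), c(5, 10, 20))
  p <- preprocess_spectrum(s)
  expect_equal(p$intensity, c(25, 50, 100))

  set.seed(1)
  big <- toy_spectrum("big", sort(runif(200, 100, 1500)), runif(200, 1, 90))
  p <- preprocess_spectrum(big, top_n = 150)
  expect_length(p$mz, 150)
  expect_equal(max(p$intensity), 100)
  expect_false(is.unsorted(p$mz))
  # the 50 dropped peaks are the least intense ones
  cutoff <- sort(big$intensity, decreasing = TRUE)[150]
  expect_true(all(p$intensity >= 100 * cutoff / max(big$intensity) - 1e-9))

  small <- preprocess_spectrum(toy_spectrum("t", c(1, 2, 3), c(1, 2, 3)), 150)
  expect_length(small$mz, 3)
  expect_error(preprocess_spectrum(list(mz = numeric(), intensity = numeric())),
               "empty")
})

test_that("preprocessing breaks intensity ties at the cutoff by lower m/z and is idempotent", {
  s <- toy_spectrum("s", c(100, 200, 300, 400), c(50, 10, 10, 100))
  p <- preprocess_spectrum(s, top_n = 3)
  expect_equal(p$mz, c(100, 200, 400))  # tie at 10: keep lower m/z
  expect_equal(preprocess_spectrum(p, top_n = 3), p)
  # idempotence on a generic spectrum
  set.seed(2)
  g <- toy_spectrum("g", sort(runif(60, 100, 900)), runif(60, 1, 80))
  p1 <- preprocess_spectrum(g, 40)
  expect_equal(preprocess_spectrum(p1, 40), p1)
})

test_that("PSM tables parse, including modification strings and flags", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Spectrum\tPeptide\tAssigned Modifications\tCharge\tDelta Mass\tExpectation",
    "sc1\tPEPTIDEK\t3S(79.9663)\t2\t226.0594\t0.001",
    "sc2\tAGAGAGKR\tN-term(42.0106), 2G(14.0157)\t3\t-0.0002\t0.05"), f)
  psms <- read_psm_table(f)
  expect_equal(nrow(psms), 2)
  expect_equal(psms$mass_shift, c(226.0594, -0.0002))
  expect_equal(psms$var_mods[[1]]$pos, "3")
  expect_equal(psms$var_mods[[1]]$delta, 79.9663)
  expect_equal(psms$var_mods[[2]]$pos, c("N-term", "2"))
  expect_warning(
    flagged <- read_psm_table(f, spectra = list(sc1 = toy_spectrum("sc1", 1, 1))),
    "no loaded spectrum")
  expect_equal(flagged$in_spectra, c(TRUE, FALSE))
})

test_that("PSM tables with missing columns or malformed modifications error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Spectrum\tPeptide\tAssigned Modifications\tCharge\tDelta Mass",
               "sc1\tPEPTIDEK\t\t2\t226.0594"), f)
  expect_error(read_psm_table(f), "Expectation")
  writeLines(c(
    "Spectrum\tPeptide\tAssigned Modifications\tCharge\tDelta Mass\tExpectation",
    "sc1\tPEPTIDEK\tnot-a-mod\t2\t226.0594\t0.001"), f)
  expect_error(read_psm_table(f), "row 1")
})

test_that("feature reports carry the standard column set", {
  fe <- data.frame(bin_apex = 226.0594, feature_class = "fragment_remainder_y",
                   ion_series = "y", mass = 94.0168, delta_mod_mass = -132.0426,
                   percent_mod = 36, percent_unmod = 0.2, avg_int_mod = 9.7,
                   avg_int_unmod = 0.01, fold_change = 970, propensity = 25.1,
                   u_stat = 1, p_value = 1e-10, e_value = 3e-10, auc = 0.68,
                   area = 12, echo_corrected = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_report(fe, f)
  rd <- read.delim(f, check.names = FALSE)
  expect_true(all(c("peak apex", "ion type", "mass", "remainder propensity",
                    "delta mod mass", "percent PSMs (mod)",
                    "percent PSMs (unmod)", "avg intensity (mod)",
                    "avg intensity (unmod)", "intensity fold change",
                    "E-value", "AUC") %in% names(rd)))
  expect_equal(rd$`ion type`, "y")
})
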