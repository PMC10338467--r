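test_that("theoretical peptide and fragment masses match independent summation", {
  t <- theoretical_peptide("PEPTIDE")
  expect_equal(t$P, 800.36722, tolerance = 1e-7)
  expect_equal(t$P, oracle_peptide_mass("PEPTIDE"), tolerance = 1e-5)
  expect_equal(t$b[2], 227.10263, tolerance = 1e-7)
  expect_equal(t$y[1], 148.06043, tolerance = 1e-7)

  t2 <- theoretical_peptide("AG")
  expect_equal(t2$b[1], 72.04439, tolerance = 1e-7)
  expect_equal(t2$y[1], 76.03930, tolerance = 1e-7)
  expect_equal(t2$b[1] + t2$y[1], t2$P + MASS_CONST[["proton"]],
               tolerance = 1e-9)
})

test_that("b/y complementarity and the a-ion offset hold for random peptides", {
  set.seed(11)
  for (rep in 1:10) {
    pep <- paste(sample(names(AA_MONO), sample(6:15, 1), replace = TRUE),
                 collapse = "")
    t <- theoretical_peptide(pep)
    n <- t$n
    expect_equal(t$b + rev(t$y), rep(t$P + MASS_CONST[["proton"]], n),
                 tolerance = 1e-9)
    expect_equal(t$a, t$b - MASS_CONST[["co"]], tolerance = 1e-12)
    expect_equal(t$P, oracle_peptide_mass(pep), tolerance = 1e-4)
  }
  expect_error(theoretical_peptide("PEPTIDEZ"), "unknown residue")
})

test_that("variable modifications shift only the series that span them", {
  base <- theoretical_peptide("PEPTIDE")
  mod <- theoretical_peptide("PEPTIDE",
                             data.frame(pos = "1", delta = 79.9663))
  expect_equal(mod$P, base$P + 79.9663, tolerance = 1e-9)
  expect_equal(mod$b, base$b + 79.9663, tolerance = 1e-9)
  expect_equal(mod$y, base$y, tolerance = 1e-12)  # y1..y6 exclude residue 1
  nt <- theoretical_peptide("PEPTIDE",
                            data.frame(pos = "N-term", delta = 42.0106))
  expect_equal(nt$b, base$b + 42.0106, tolerance = 1e-9)
  expect_equal(nt$y, base$y, tolerance = 1e-12)
})

test_that("stripping removes matched and shifted backbone ions by mode", {
  t <- theoretical_peptide("PEPTIDE")
  shift <- 94.0168
  s <- toy_spectrum("s", c(227.10263, t$b[2] + shift, 400.0), c(50, 40, 100))
  d <- strip_spectrum(s, t, shift, mode = "diagnostic")
  expect_equal(d$mz, 400.0)           # b2 and shifted b2 both stripped
  expect_setequal(d$matched$kind, c("unshifted", "shifted"))
  f <- strip_spectrum(s, t, shift, mode = "fragment_remainder")
  expect_setequal(round(f$mz, 4), round(c(t$b[2] + shift, 400.0), 4))
  expect_true(all(f$matched$kind == "unshifted"))
})

test_that("stripping is idempotent", {
  set.seed(3)
  t <- theoretical_peptide("PEPTIDEK")
  mz <- sort(c(t$b, t$y, runif(20, 100, 900)))
  s <- toy_spectrum("s", mz, runif(length(mz), 1, 100))
  for (mode in c("diagnostic", "fragment_remainder")) {
    s1 <- strip_spectrum(s, t, 94.0168, mode = mode)
    s2 <- strip_spectrum(list(mz = s1$mz, intensity = s1$intensity), t,
                         94.0168, mode = mode)
    expect_length(s2$matched$mz, 0)
    expect_equal(s2$mz, s1$mz)
  }
})

test_that("peptide remainder vectors are distances to the theoretical peptide mass", {
  t <- theoretical_peptide("PEPTIDE")
  s <- toy_spectrum("s", c(500.1234, t$P, t$P + 94.0168), c(30, 10, 25))
  ss <- strip_spectrum(s, t, 226.0594, mode = "peptide_remainder")
  v <- peptide_remainder_vector(ss, t)
  expect_equal(nrow(v), length(ss$mz))
  expect_equal(v$mass[1], 500.1234 - 800.36722, tolerance = 1e-5)
  expect_equal(v$mass[2], 0, tolerance = 1e-9)           # complete loss
  expect_equal(v$mass[3], 94.0168, tolerance = 1e-9)
})

test_that("fragment remainder matrices have m x n entries and the echo structure", {
  pep <- "GASPVTIR"  # 8 residues -> n = 7
  t <- theoretical_peptide(pep)
  s <- toy_spectrum("s", c(150.0, t$y[3] + 203.0794, 700.1, 1100.2),
                    c(5, 40, 10, 20))
  ss <- strip_spectrum(s, t, 365.1322, mode = "fragment_remainder")
  expect_length(ss$mz, 4)
  W <- fragment_remainder_matrix(ss, t, "y")
  expect_equal(nrow(W), 4 * 7)
  hit <- W[W$peak == 2 & W$frag == 3, ]
  expect_equal(hit$offset, 203.0794, tolerance = 1e-9)
  # identity offset: a peak exactly at F_j gives offset 0 in column j
  s0 <- list(mz = t$b[4], intensity = 1)
  W0 <- fragment_remainder_matrix(s0, t, "b")
  expect_equal(W0$offset[W0$frag == 4], 0, tolerance = 1e-12)
  # echo structure: offsets in adjacent b columns differ by the intervening
  # residue mass
  res <- AA_MONO[strsplit(pep, "")[[1]]]
  Wb <- fragment_remainder_matrix(ss, t, "b")
  for (j in 1:6) {
    d <- Wb$offset[Wb$frag == j] - Wb$offset[Wb$frag == j + 1]
    expect_equal(d, rep(unname(res[j + 1]), 4), tolerance = 1e-9)
  }
})
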