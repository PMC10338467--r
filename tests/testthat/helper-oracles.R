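# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# AUC by exhaustive pairwise comparison (wins + half ties).
brute_auc <- function(x, y) {
  wins <- 0
  for (xi in x) for (yj in y) {
    wins <- wins + (xi > yj) + 0.5 * (xi == yj)
  }
  wins / (length(x) * length(y))
}

# Exact two-sided permutation p-value of the Mann-Whitney U statistic:
# enumerate every reassignment of the pooled values into groups of the
# observed sizes and compare rank sums.
perm_pvalue <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  u_of <- function(sel) sum(r[sel]) - nx * (nx + 1) / 2
  obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, u_of)
  p_lo <- mean(us <= obs)
  p_hi <- mean(us >= obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Peak-descent apex scan written independently with plain loops: every bin
# is tested as an apex candidate (runs of equal bins count once, at the run
# centre); candidates are processed in decreasing height and absorb their
# descent paths.
oracle_apexes <- function(w, descent_tol = 0.01) {
  n <- length(w)
  cand <- integer()
  i <- 1L
  while (i <= n) {
    if (w[i] <= 0) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && w[j + 1] == w[i]) j <- j + 1L
    left <- if (i > 1) w[i - 1] else 0
    right <- if (j < n) w[j + 1] else 0
    if (w[i] >= left && w[i] >= right) {
      cand <- c(cand, floor((i + j - 2) / 2) + 1L)
    }
    i <- j + 1L
  }
  cand <- cand[order(-w[cand], cand)]
  claimed <- rep(FALSE, n)
  apex <- integer()
  for (c in cand) {
    if (claimed[c]) next
    apex <- c(apex, c)
    claimed[c] <- TRUE
    j <- c
    while (j > 1 && w[j - 1] > 0 && w[j - 1] <= w[j] * (1 + descent_tol)) {
      j <- j - 1
      claimed[j] <- TRUE
    }
    j <- c
    while (j < n && w[j + 1] > 0 && w[j + 1] <= w[j] * (1 + descent_tol)) {
      j <- j + 1
      claimed[j] <- TRUE
    }
  }
  sort(apex)
}

# Independent monoisotopic summation for theoretical masses (own constants,
# typed in from standard tables).
oracle_peptide_mass <- function(peptide) {
  tab <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
           V = 99.06841, T = 101.04768, C = 103.00918, L = 113.08406,
           I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
           K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
           F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  sum(tab[strsplit(peptide, "")[[1]]]) + 18.010565 + 1.007276
}
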