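# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Spearman rho by direct rank computation (average ranks; the 1 - 6*sum(d^2)
# shortcut is only valid without ties, so use Pearson on ranks in general).
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# untied shortcut, for the worked example where no ties occur
oracle_spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force mass sum from the same printed atomic masses, independent of
# parse_formula / monoisotopic_mass internals
oracle_mass <- function(nC = 0, nH = 0, nN = 0, nO = 0) {
  nC * 12 + nH * 1.00782503 + nN * 14.00307401 + nO * 15.99491462
}

# random CHNO formula string + its count vector, for property tests
random_formula <- function() {
  n <- c(C = sample(1:30, 1), H = sample(1:40, 1),
         N = sample(0:3, 1), O = sample(0:8, 1))
  n <- n[n > 0]
  list(
    text = paste0(names(n), n, collapse = ""),
    counts = n
  )
}
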