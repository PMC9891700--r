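# Independent oracles: written from the textbook raw-sum formulas (a
# different algebraic path than the package's centered-sum implementation)
# or by brute-force enumeration. They must stay independent of the code
# under test.

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

oracle_pooled_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- (sum(x^2) - sum(x)^2 / n1) / (n1 - 1)
  v2 <- (sum(y^2) - sum(y)^2 / n2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

oracle_welch_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v1 <- (sum(x^2) - sum(x)^2 / n1) / (n1 - 1)
  v2 <- (sum(y^2) - sum(y)^2 / n2) / (n2 - 1)
  (mean(x) - mean(y)) / sqrt(v1 / n1 + v2 / n2)
}

# All permutations of 1..n (n! x n matrix), n small.
all_permutations <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

# Exhaustive two-sided permutation p-value for a correlation coefficient:
# the proportion of orderings of y whose |r| reaches the observed |r|.
perm_pvalue_exhaustive <- function(x, y, coef = oracle_pearson) {
  perms <- all_permutations(length(y))
  r_obs <- abs(coef(x, y))
  r_perm <- abs(apply(perms, 1L, function(p) coef(x, y[p])))
  mean(r_perm >= r_obs - 1e-12)
}

# Relative error, floored to absolute error at unit scale so that
# coefficients near zero (|r| << 1) are not judged on meaningless digits.
rel_err <- function(a, b) {
  ifelse(a == b, 0, abs(a - b) / pmax(abs(a), abs(b), 1))
}
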