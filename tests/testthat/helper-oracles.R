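# Independent oracles used to freeze expected values. These deliberately use
# naive O(n^2) enumeration or textbook formulas, never the package's own
# rank-based code paths.

# Brute-force concordance AUC: all case/control pairs, ties count 1/2.
brute_auc <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls) {
    s <- s + (x > y) + 0.5 * (x == y)
  }
  s / (length(cases) * length(controls))
}

# Brute-force Cliff's delta from the full dominance matrix.
brute_cliff <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    gt <- gt + (xi > yj)
    lt <- lt + (xi < yj)
  }
  (gt - lt) / (length(x) * length(y))
}

# Closed-form Wilson interval straight from the textbook formula.
brute_wilson <- function(x, n, z = qnorm(0.975)) {
  p <- x / n
  c((p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n),
    (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
      (1 + z^2 / n))
}

# Step-up BH by exhaustive minimisation over k (definitional form).
brute_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    min(1, min(vapply(which(r >= r[i]), function(j) m * p[j] / r[j],
                      numeric(1))))
  }, numeric(1))
}

# Newton-Raphson logistic MLE, hand-rolled (independent of glm/glmnet).
nr_logistic <- function(X, y, tol = 1e-10, maxit = 100) {
  X <- cbind(1, as.matrix(X))
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    step <- solve(crossprod(X, X * w), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  unname(beta)
}

# Two-group permutation test on the difference of means.
perm_test_p <- function(a, b, n_perm = 1e5) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), na)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Random positive molar profile over the full 24-analyte panel, summing
# to 100.
random_profile <- function(panel = default_panel()) {
  v <- stats::runif(nrow(panel), 0.05, 10)
  v <- v / sum(v) * 100
  names(v) <- panel$name
  v
}

# Small wide concentration cohort used by I/O tests.
tiny_cohort <- function() {
  data.frame(
    sample_id = c("s1", "s2", "s3"),
    group = c("Control", "Control", "AS"),
    `C18:0` = c(284.48, 142.24, 568.96),
    `C18:1n-9` = c(282.46, 141.23, NA),
    `C20:5n-3` = c(30.245, 60.49, 15.12),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
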