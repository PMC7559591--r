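# Independent oracles used to check the package's primitives.

# Cox-de Boor recursion, written directly from the recurrence
oracle_bspline <- function(x, knots, degree) {
  n_basis <- length(knots) - degree - 1L
  B <- sapply(seq_len(length(knots) - 1L), function(i) {
    lo <- knots[i]; hi <- knots[i + 1L]
    v <- as.numeric(x >= lo & x < hi)
    # close the last non-empty interval on the right
    if (hi == max(knots)) v[x == hi] <- 1
    v
  })
  if (is.null(dim(B))) B <- matrix(B, nrow = length(x))
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(x), ncol(B) - 1L)
    for (i in seq_len(ncol(Bn))) {
      d1 <- knots[i + d] - knots[i]
      d2 <- knots[i + d + 1L] - knots[i + 1L]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * B[, i] else 0
      t2 <- if (d2 > 0) (knots[i + d + 1L] - x) / d2 * B[, i + 1L] else 0
      Bn[, i] <- t1 + t2
    }
    B <- Bn
  }
  B[, seq_len(n_basis), drop = FALSE]
}

# row-wise Kronecker product by explicit double loop
oracle_kron_rows <- function(A, P) {
  out <- matrix(NA_real_, nrow(A), ncol(A) * ncol(P))
  for (r in seq_len(nrow(A))) {
    col <- 0L
    for (a in seq_len(ncol(A))) for (b in seq_len(ncol(P))) {
      col <- col + 1L
      out[r, col] <- A[r, a] * P[r, b]
    }
  }
  out
}

# brute-force Lexis cohort labelling: cells share a cohort iff ageing one
# age group forward corresponds to moving M periods later (same value of
# j - M i); consecutive cohorts are born one period apart, so ranks run over
# the full integer range oldest (large i, small j) to youngest -- including
# cohorts that fall between observed diagonals when M > 1
oracle_cohort_grid <- function(I, J, M) {
  v <- outer(seq_len(I), seq_len(J), function(i, j) j - M * i)
  lv <- seq(min(v), max(v))
  matrix(match(as.vector(v), lv), I, J)
}

# small random registry table
random_table <- function(seed, J = 4, I = 3, width = 5, rate = 2e-4) {
  set.seed(seed)
  N <- matrix(stats::runif(J * I, 1e4, 2e5), J, I)
  Y <- matrix(stats::rpois(J * I, as.vector(N) * rate), J, I)
  registry_table(2000L + seq_len(J) - 1L, 20L + (seq_len(I) - 1L) * width,
                 Y, N, age_width = width)
}

# registry table drawn from the Bayesian APC generative model with known
# precisions (rw2 age/period/cohort + iid overdispersion, Poisson counts)
gen_bapc_table <- function(seed, I = 5, J = 12, M = 1,
                           tau = c(age = 2, period = 50, cohort = 50,
                                   iid = 200),
                           mu0 = -7, N0 = 2e5) {
  set.seed(seed)
  lex <- lexis_spec(I, J, M)
  rw2_draw <- function(n, tau) {
    x <- cumsum(cumsum(c(0, 0, stats::rnorm(n - 2, 0, 1 / sqrt(tau)))))
    x - mean(x)
  }
  alpha <- rw2_draw(I, tau[["age"]])
  beta <- rw2_draw(J, tau[["period"]])
  gamma <- rw2_draw(lex$K, tau[["cohort"]])
  eta <- matrix(0, J, I)
  for (j in seq_len(J)) for (i in seq_len(I))
    eta[j, i] <- mu0 + alpha[i] + beta[j] + gamma[cohort_index(lex, i, j)] +
      stats::rnorm(1, 0, 1 / sqrt(tau[["iid"]]))
  N <- matrix(N0, J, I)
  Y <- matrix(stats::rpois(I * J, as.vector(N * exp(eta))), J, I)
  registry_table(2000L + seq_len(J) - 1L, 20L + seq_len(I) - 1L, Y, N,
                 age_width = M)
}
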