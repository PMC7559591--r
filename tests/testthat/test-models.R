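test_that("constant projections scale rates or carry counts forward", {
  tab <- registry_table(2000:2002, 20L, matrix(c(6L, 8L, 10L), 3, 1),
                        matrix(100, 3, 1))
  pr <- project_constant(tab, "rate", future_N = matrix(200, 1, 1))
  expect_equal(pr$cells$mean, 20)
  expect_equal(pr$cells$sd, 0)
  expect_equal(pr$cells$lo, pr$cells$hi)
  pc <- project_constant(tab, "count", future_N = matrix(999, 1, 1))
  expect_equal(pc$cells$mean, 10)

  # multi-age table: per-age outputs equal per-age scalar computation
  tab3 <- random_table(31)
  futN <- tab3$population[nrow(tab3$population), , drop = FALSE] * 1.3
  pr3 <- project_constant(tab3, "rate", futN)
  last <- nrow(tab3$incidence)
  for (i in seq_along(tab3$age_lower))
    expect_equal(pr3$cells$mean[i],
                 tab3$incidence[last, i] / tab3$population[last, i] *
                   futN[1, i])
})

test_that("Poisson intercept-only MLE is the pooled rate; NB approaches it", {
  tab <- random_table(32)
  fp <- fit_glm(tab, "intercept", family = "poisson")
  expect_equal(exp(unname(fp$coef[1])), sum(tab$incidence) / sum(tab$population),
               tolerance = 1e-7)
  fn <- fit_glm(tab, "intercept", family = "nb")
  expect_equal(exp(unname(fn$coef[1])), sum(tab$incidence) / sum(tab$population),
               tolerance = 1e-3)
  expect_true(fn$converged)
})

test_that("age-period GLM recovers simulated coefficients within 3 SE", {
  set.seed(33)
  I <- 10; J <- 12
  years <- 2000:(2000 + J - 1); ages <- seq(20, by = 5, length.out = I)
  mids <- ages + 2
  a_c <- rep(mids - mean(mids), times = J)
  p_c <- rep(years - mean(years), each = I)
  N <- matrix(5e5, J, I)
  beta <- c(-8, 0.05, 0, 0)
  eta <- beta[1] + beta[2] * a_c + beta[3] * p_c + beta[4] * a_c * p_c
  # eta is in cell (year-major) order: reshape back to years x ages
  Y <- matrix(rpois(I * J, 5e5 * exp(eta)), J, I, byrow = TRUE)
  tab <- registry_table(years, ages, Y, N)
  fit <- fit_glm(tab, "age_period", family = "nb")
  # standard errors from the Fisher information of the refitted model
  X <- cbind(1, a_c, p_c, a_c * p_c)
  mu <- 5e5 * exp(eta)
  se <- sqrt(diag(solve(t(X) %*% (X * mu))))
  expect_true(all(abs(unname(fit$coef) - beta) <= 3 * se))
  expect_true(fit$converged)
})

test_that("degree-0 saturated age spline reproduces per-age mean rates", {
  tab <- random_table(34, J = 6, I = 5)
  fit <- fit_gam_age_spline(tab, n_basis = 5, degree = 0, family = "poisson",
                            include_period = FALSE)
  futN <- matrix(colMeans(tab$population), 1)
  proj <- project(fit, futN, horizon = 1)
  per_age_rate <- colSums(tab$incidence) / colSums(tab$population)
  expect_equal(proj$cells$mean, per_age_rate * futN[1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("age spline fit tracks a flat age truth and rejects degenerate input", {
  set.seed(35)
  J <- 10; I <- 12
  N <- matrix(2e6, J, I)   # large counts so sampling noise is well under 5%
  Y <- matrix(rpois(J * I, 2e6 * 4e-4), J, I)
  tab <- registry_table(2001:2010, seq(20, by = 5, length.out = I), Y, N)
  fit <- fit_gam_age_spline(tab)
  proj <- project(fit, N[1:2, ], horizon = 2)
  expect_true(all(abs(proj$cells$mean / (2e6 * 4e-4) - 1) < 0.05))
  one_age <- registry_table(2001:2010, 20L, Y[, 1, drop = FALSE],
                            N[, 1, drop = FALSE])
  expect_error(fit_gam_age_spline(one_age), "at least 2 age groups")
  expect_error(fit_gam_age_spline(tab, n_basis = 40), "exceeds")
})

test_that("saturated ML design reproduces observed counts as fitted means", {
  # 2 ages x 2 years: the age-period interaction design is saturated
  tab <- registry_table(2000:2001, c(20L, 25L),
                        matrix(c(30L, 40L, 50L, 45L), 2, 2),
                        matrix(1e4, 2, 2))
  fit <- fit_glm(tab, "age_period", family = "poisson")
  cells <- tab$incidence
  X <- incproj:::glm_design(incproj:::unroll_cells(tab), "age_period",
                            fit$center)
  mu <- exp(drop(X %*% fit$coef) + log(as.vector(t(tab$population))))
  expect_equal(mu, as.vector(t(cells)), tolerance = 1e-6)
})

test_that("doubling the population doubles predictive mean counts", {
  tab <- random_table(36, J = 8, I = 4)
  tab2 <- registry_table(tab$years, tab$age_lower, tab$incidence,
                         2 * tab$population, age_width = tab$age_width)
  futN <- tab$population[8, , drop = FALSE]
  for (terms in c("intercept", "age_period")) {
    f1 <- fit_glm(tab, terms)
    p1 <- project(f1, futN, 1)
    p2 <- project(f1, 2 * futN, 1)
    expect_equal(p2$cells$mean, 2 * p1$cells$mean, tolerance = 1e-10)
  }
  # rates are invariant when both training N and future N double
  fa <- fit_glm(tab, "intercept", family = "poisson")
  fb <- fit_glm(tab2, "intercept", family = "poisson")
  expect_equal(exp(unname(fb$coef[1])), exp(unname(fa$coef[1])) / 2,
               tolerance = 1e-8)
})

test_that("tensor z-model: single-basis margins multiply, tight prior collapses to intercept", {
  # 1 basis function per margin (degree 0): Z has one column equal to the
  # product of the two marginal (constant) M-spline columns
  A <- mspline_basis(c(1, 2), 1, 0, span = c(0.5, 2.5))
  P <- mspline_basis(c(10, 20), 1, 0, span = c(5, 25))
  Z <- tensor_product_rows(A, P)
  expect_identical(ncol(Z$values), 1L)
  expect_equal(Z$values[, 1], A$values[, 1] * P$values[, 1])

  tab <- gen_bapc_table(401, I = 5, J = 8)
  fit <- fit_tensor_z(tab, horizon = 1, prior = c(1e8, 1), seed = 2,
                      mcmc = list(n_iter = 800, burnin = 200))
  futN <- tab$population[8, , drop = FALSE]
  proj <- project(fit, futN, 1, n_samples = 1500, seed = 3)
  pooled <- sum(tab$incidence) / sum(tab$population)
  expect_true(all(abs(proj$cells$mean / (pooled * futN[1, ]) - 1) < 0.15))
})

test_that("BAPC on constant-rate data shrinks to the pooled rate", {
  set.seed(37)
  J <- 8; I <- 5
  N <- matrix(5e5, J, I)
  Y <- matrix(rpois(J * I, 5e5 * 3e-4), J, I)
  tab <- registry_table(2000:2007, 20:24, Y, N, age_width = 1)
  fit <- fit_bapc(tab, seed = 7, mcmc = list(n_iter = 1200, burnin = 400))
  proj <- project(fit, N[1:2, ], 2, n_samples = 1500, seed = 8)
  pooled <- sum(Y) / sum(N)
  expect_true(all(abs(proj$cells$mean / (pooled * 5e5) - 1) < 0.1))
})

test_that("BAPC reproduces a linear drift in eta despite non-identified effects", {
  set.seed(38)
  J <- 10; I <- 5
  drift <- 0.04
  years <- 2000:(2000 + J - 1)
  eta_true <- outer(drift * (seq_len(J) - mean(seq_len(J))), rep(0, I), `+`) - 7
  N <- matrix(3e5, J, I)
  Y <- matrix(rpois(J * I, as.vector(N * exp(eta_true))), J, I)
  tab <- registry_table(years, 20:24, Y, N, age_width = 1)
  fit <- fit_bapc(tab, seed = 9, mcmc = list(n_iter = 1500, burnin = 500))
  eta_hat <- matrix(colMeans(fit$pa$eta_draws) - log(as.vector(t(N))), J, I,
                    byrow = TRUE)
  eta_sd <- matrix(apply(fit$pa$eta_draws, 2, sd), J, I, byrow = TRUE)
  expect_gt(mean(abs(eta_hat - eta_true) <= 3 * eta_sd), 0.9)
  # fitted drift across periods close to truth
  fitted_drift <- mean(diff(rowMeans(eta_hat)))
  expect_lt(abs(fitted_drift - drift), 0.01)
})

test_that("BAPC predictor is invariant under the linear effect reallocation", {
  I <- 4; J <- 5; M <- 2
  lex <- lexis_spec(I, J, M)
  mu <- -7
  alpha <- rnorm(I); beta <- rnorm(J); gamma <- rnorm(lex$K)
  eta <- function(mu, a, b, g) outer(seq_len(I), seq_len(J), function(i, j)
    mu + a[i] + b[j] + g[cohort_index(lex, i, j)])
  base <- eta(mu, alpha, beta, gamma)
  delta <- 0.3
  shifted <- eta(mu - delta * M * I,
                 alpha + delta * M * seq_len(I),
                 beta - delta * seq_len(J),
                 gamma + delta * seq_len(lex$K))
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("rw2 extrapolation variance grows with horizon", {
  set.seed(39)
  last2 <- matrix(rep(c(0, 0.1), each = 500), 500, 2)
  tau <- rep(25, 500)
  ext <- incproj:::rw2_extend(last2, tau, steps = 6)
  v <- apply(ext, 2, var)
  expect_true(all(diff(v) > 0))
})
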