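make_constant_table <- function(J = 40, I = 3, count = 25L, N = 1e5) {
  registry_table(1975L + seq_len(J) - 1L, seq(20, by = 5, length.out = I),
                 matrix(count, J, I), matrix(N, J, I))
}

test_that("rolling windows follow the L-years-ending-at-T-minus-n rule", {
  tab <- make_constant_table(J = 42)  # 1975..2016 -> use target 2014
  d <- evaluation_design(observation_length = 15, horizons = c(2, 5, 20),
                         target_year = 2014)
  w <- make_windows(tab, d)
  expect_length(w, 3)
  expect_identical(w[[1]]$train_years, 1998:2012)
  expect_identical(w[[1]]$target_year, 2014)
  expect_identical(w[[3]]$train_years, 1980:1994)
  # a table too short for a horizon skips it with a warning
  short <- filter_years(tab, 1993:2014)
  expect_warning(ws <- make_windows(short, d), "horizon 20 skipped")
  expect_length(ws, 2)
})

test_that("coverage counts inclusive bounds", {
  cells <- data.frame(lo = c(1, 5, 10), hi = c(3, 7, 12))
  expect_equal(coverage(cells, c(2, 6, 11)), 1)
  expect_equal(coverage(cells, c(3, 7, 12)), 1)   # y == hi covered
  expect_equal(coverage(cells, c(1, 5, 10)), 1)   # y == lo covered
  expect_equal(coverage(cells, c(0, 6, 13)), 1 / 3)
  cells13 <- data.frame(lo = rep(0, 13), hi = c(rep(10, 10), rep(-1, 3)))
  expect_equal(coverage(cells13, rep(5, 13)), 10 / 13)
  expect_error(coverage(cells, 1:2), "3 cells")
})

test_that("bias follows the signed percent convention", {
  expect_equal(bias(7, 7), 0)
  expect_equal(bias(100, 300), -200)
  expect_equal(bias(100, 50), 50)
  expect_equal(bias(0, 0), 0)
  expect_true(is.na(bias(0, 3)))
  expect_equal(bias(c(7, 100, 0), c(7, 300, 1)), c(0, -200, NA))
})

test_that("precision is the mean predictive SD with a log10(1+x) companion", {
  proj <- list(cells = data.frame(sd = c(1, 2, 3)))
  p <- precision(proj)
  expect_equal(p$raw, 2)
  expect_equal(p$transformed, log10(3))
  expect_equal(precision(list(cells = data.frame(sd = rep(0, 4))))$raw, 0)
  # homogeneity: scaling the SDs scales the raw mean
  p10 <- precision(list(cells = data.frame(sd = 10 * c(1, 2, 3))))
  expect_equal(p10$raw, 20)
})

test_that("constant-count model on constant data gets coverage 1 and bias 0", {
  tab <- make_constant_table()
  d <- evaluation_design(horizons = c(2, 5))
  res <- evaluate(tab, model_library("constant_count"), d, seed = 4)
  expect_equal(nrow(res), 2)
  expect_equal(res$coverage, c(1, 1))
  expect_equal(res$bias, c(0, 0))
  expect_equal(res$precision_raw, c(0, 0))
  expect_equal(res$n_cells, c(3L, 3L))
})

test_that("intercept-only model undercovers badly under a strong age gradient", {
  sim <- simulate_registry(synthetic_spec(n_years = 22, drift = 0,
                                          cohort_amp = 0, seed = 44))
  d <- evaluation_design(observation_length = 10, horizons = c(2, 5))
  # Poisson variant: the NB intercept model hides the age gradient inside
  # its dispersion estimate and covers by sheer interval width
  res <- evaluate(sim$table, model_library("glm_intercept_poisson"), d,
                  seed = 5)
  expect_true(all(res$coverage < 0.5))
  res_nb <- evaluate(sim$table, model_library("glm_intercept"), d, seed = 5)
  expect_true(all(res_nb$precision_raw > 10 * res$precision_raw))
})

test_that("metrics records are reproducible bit-identically given the seed", {
  tab <- simulate_registry(synthetic_spec(n_years = 30, seed = 9))$table
  d <- evaluation_design(observation_length = 10, horizons = c(2, 5))
  models <- model_library(c("constant_rate", "glm_intercept", "gam_age_bs"))
  r1 <- evaluate(tab, models, d, seed = 31)
  r2 <- evaluate(tab, models, d, seed = 31)
  attr(r1, "projections") <- attr(r2, "projections") <- NULL
  expect_identical(r1, r2)
})

test_that("fit failures are recorded per model/horizon, not fatal", {
  tab <- make_constant_table(J = 20, I = 3)
  broken <- inc_model("broken", function(t, horizon, seed) stop("boom"))
  d <- evaluation_design(observation_length = 10, horizons = 2)
  res <- suppressWarnings(evaluate(tab, list(broken,
                                             model_library("constant_rate")[[1]]),
                                   d, seed = 1))
  expect_identical(res$error[res$model == "broken"], "boom")
  expect_true(is.na(res$coverage[res$model == "broken"]))
  expect_equal(res$coverage[res$model == "constant_rate"], 1)
})

test_that("PIT is uniform for the true model and handles single observations", {
  # analytic Poisson predictive at the true mean: PIT must look uniform
  set.seed(46)
  m <- 2000
  mu <- runif(m, 20, 120)
  y <- rpois(m, mu)
  proj <- structure(list(cells = data.frame(lo = 0, hi = 1, mean = mu,
                                            sd = sqrt(mu),
                                            year = 2000, age_lower = 20),
                         samples = NULL,
                         cdf = list(type = "pois", mu = mu)),
                    class = "inc_projection")
  ph <- pit(proj, y)
  expect_equal(sum(ph$counts), m)
  expect_gt(chisq.test(ph$counts)$p.value, 0.01)
  # one observation: one bin incremented
  proj1 <- structure(list(cells = proj$cells[1, ], samples = NULL,
                          cdf = list(type = "pois", mu = mu[1])),
                     class = "inc_projection")
  ph1 <- pit(proj1, y[1])
  expect_equal(sum(ph1$counts), 1L)
  expect_equal(max(ph1$counts), 1L)
})
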