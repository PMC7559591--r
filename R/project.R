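#' Project a fitted model forward
#'
#' Produces the predictive distribution of future counts for every cell
#' (age group x future year) up to `horizon` years beyond the last training
#' year. Bayesian fits propagate hyperparameter, latent and observation
#' noise through posterior-predictive draws (random-walk effects are extended
#' with their rw2 predictive distribution); maximum-likelihood fits use the
#' plug-in predictive at the MLE; constant fits are degenerate points.
#'
#' Equal-tailed 95% intervals use the discrete convention: `lo` is the
#' smallest count with predictive CDF >= 0.025 and `hi` the smallest with
#' CDF >= 0.975 (sample quantiles of that type when draws are used).
#'
#' @param fit An `inc_fit`.
#' @param future_N `horizon x I` matrix of future person-years (rows =
#'   successive future years; a vector is treated as one year).
#' @param horizon Number of future years (>= 1).
#' @param n_samples Predictive draws for stochastic fits (>= 100).
#' @param seed RNG seed for predictive draws.
#' @return An `inc_projection`: cell table (`year`, `age_lower`, `mean`,
#'   `sd`, `lo`, `hi`) plus predictive draws/CDF machinery for PIT and
#'   coverage computations.
#' @export
project <- function(fit, future_N, horizon = 1L, n_samples = 2000L,
                    seed = 1L) {
  stopifnot(inherits(fit, "inc_fit"), horizon >= 1)
  I <- length(fit$age_lower)
  if (is.vector(future_N)) future_N <- matrix(future_N, nrow = 1)
  future_N <- as.matrix(future_N)
  if (nrow(future_N) < horizon)
    stop("future_N has ", nrow(future_N), " rows but horizon is ", horizon)
  future_N <- future_N[seq_len(horizon), , drop = FALSE]
  if (ncol(future_N) != I)
    stop("future_N has ", ncol(future_N), " columns but the fit has ", I,
         " age groups")
  years <- fit$last_year + seq_len(horizon)
  cells <- data.frame(year = rep(years, each = I),
                      age_lower = rep(fit$age_lower, times = horizon))
  Nvec <- as.vector(t(future_N))

  if (fit$kind == "constant") {
    point <- if (fit$mode == "rate")
      rep(fit$last_rates, times = horizon) * Nvec
    else rep(fit$last_counts, times = horizon)
    return(new_projection(fit, cells,
                          mean = point, sd = rep(0, length(point)),
                          lo = point, hi = point,
                          cdf = list(type = "point", point = point)))
  }

  if (fit$engine == "ml") {
    X <- ml_future_design(fit, cells)
    mu <- exp(drop(X %*% fit$coef) + log(Nvec))
    if (fit$family == "nb" && is.finite(fit$theta)) {
      sd <- sqrt(mu + mu^2 / fit$theta)
      lo <- stats::qnbinom(0.025, size = fit$theta, mu = mu)
      hi <- stats::qnbinom(0.975, size = fit$theta, mu = mu)
      cdf <- list(type = "nb", mu = mu, size = fit$theta)
    } else {
      sd <- sqrt(mu)
      lo <- stats::qpois(0.025, mu)
      hi <- stats::qpois(0.975, mu)
      cdf <- list(type = "pois", mu = mu)
    }
    return(new_projection(fit, cells, mean = mu, sd = sd, lo = lo, hi = hi,
                          cdf = cdf))
  }

  ## Bayesian fits: posterior-predictive draws
  draws <- switch(fit$kind,
                  bapc = bapc_predictive(fit, Nvec, cells, horizon,
                                         n_samples, seed),
                  tensor_z = tensor_predictive(fit, Nvec, cells, horizon,
                                               n_samples, seed),
                  bayes_fixed_predictive(fit, Nvec, cells, n_samples, seed))
  summarize_draws(fit, cells, draws)
}

new_projection <- function(fit, cells, mean, sd, lo, hi, cdf,
                           samples = NULL) {
  cells$mean <- as.numeric(mean)
  cells$sd <- as.numeric(sd)
  cells$lo <- as.numeric(lo)
  cells$hi <- as.numeric(hi)
  structure(list(cells = cells, samples = samples, cdf = cdf,
                 model = fit$kind, engine = fit$engine,
                 family = fit$family),
            class = "inc_projection")
}

#' @export
print.inc_projection <- function(x, ...) {
  cat("inc_projection: ", x$model, " (", x$engine, "), ",
      nrow(x$cells), " cells, years ",
      min(x$cells$year), "-", max(x$cells$year), "\n", sep = "")
  print(utils::head(x$cells, 4))
  invisible(x)
}

#' @export
as.data.frame.inc_projection <- function(x, ...) x$cells

summarize_draws <- function(fit, cells, draws) {
  S <- nrow(draws)
  lo_i <- max(1L, ceiling(0.025 * S))
  hi_i <- max(1L, ceiling(0.975 * S))
  qs <- apply(draws, 2, function(v) {
    sv <- sort.int(v)
    c(sv[lo_i], sv[hi_i])
  })
  new_projection(fit, cells,
                 mean = colMeans(draws),
                 sd = apply(draws, 2, stats::sd),
                 lo = qs[1, ], hi = qs[2, ],
                 cdf = list(type = "samples"),
                 samples = draws)
}

ml_future_design <- function(fit, cells) {
  cells$age_mid <- rep(fit$age_mid, length.out = nrow(cells))
  if (startsWith(fit$kind, "glm")) {
    glm_design(cells, fit$terms, fit$center)
  } else if (fit$kind == "gam_age") {
    i <- match(cells$age_lower, fit$age_lower)
    Bage <- fit$basis$values[i, -1, drop = FALSE]
    colnames(Bage) <- paste0("bs", seq_len(ncol(Bage)) + 1L)
    cbind(intercept = 1,
          if (fit$include_period) cbind(period = cells$year - fit$center[2]),
          Bage)
  } else stop("no future design for kind ", fit$kind)
}

bayes_fixed_predictive <- function(fit, Nvec, cells, n_samples, seed) {
  X <- ml_future_design(fit, cells)
  posterior_predictive(fit$pa, X, log(Nvec), n_samples = n_samples,
                       seed = seed)
}

tensor_predictive <- function(fit, Nvec, cells, horizon, n_samples, seed) {
  if (max(cells$year) > max(fit$years_all))
    stop("tensor fit was built for horizon ", fit$horizon_built,
         "; refit with a larger horizon")
  i <- match(cells$age_lower, fit$age_lower)
  Z <- tensor_product_rows(fit$A$values[i, , drop = FALSE],
                           fit$P$values[match(cells$year, fit$years_all), ,
                                        drop = FALSE])
  posterior_predictive(fit$pa, cbind(1, Z$values), log(Nvec),
                       n_samples = n_samples, seed = seed)
}

# rw2 predictive extension: each new value ~ N(2*prev1 - prev2, 1/tau),
# vectorized over posterior draws (rows)
rw2_extend <- function(last2, tau, steps) {
  S <- length(tau)
  out <- matrix(NA_real_, S, steps)
  prev2 <- last2[, 1]; prev1 <- last2[, 2]
  for (h in seq_len(steps)) {
    out[, h] <- stats::rnorm(S, 2 * prev1 - prev2, 1 / sqrt(tau))
    prev2 <- prev1; prev1 <- out[, h]
  }
  out
}

bapc_predictive <- function(fit, Nvec, cells, horizon, n_samples, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  pa <- fit$pa
  lex <- fit$lexis
  I <- lex$I; J <- lex$J; M <- lex$M; K <- lex$K
  S0 <- nrow(pa$x_draws)
  idx <- rep_len(seq_len(S0), n_samples)
  x <- pa$x_draws[idx, , drop = FALSE]
  mu <- x[, fit$ix$mu]
  alpha <- x[, fit$ix$age, drop = FALSE]
  beta <- x[, fit$ix$period, drop = FALSE]
  gamma <- x[, fit$ix$cohort, drop = FALSE]
  tau <- pa$tau_draws[idx, , drop = FALSE]  # age, period, cohort, iid
  beta_ext <- rw2_extend(beta[, c(J - 1L, J)], tau[, 2], horizon)
  gamma_ext <- rw2_extend(gamma[, c(K - 1L, K)], tau[, 3], horizon)
  n_cells <- nrow(cells)
  eta <- matrix(mu, n_samples, n_cells)
  for (c_i in seq_len(n_cells)) {
    h <- cells$year[c_i] - fit$last_year
    i <- match(cells$age_lower[c_i], fit$age_lower)
    k <- (J + h) + M * (I - i)
    gk <- if (k <= K) gamma[, k] else gamma_ext[, k - K]
    u <- stats::rnorm(n_samples, 0, 1 / sqrt(tau[, 4]))
    eta[, c_i] <- eta[, c_i] + alpha[, i] + beta_ext[, h] + gk + u +
      log(Nvec[c_i])
  }
  draw_counts("poisson", eta)
}

#' Write a projection to CSV
#'
#' One row per cell: year, age-group lower bound, predictive mean, SD and
#' equal-tailed 95% bounds.
#'
#' @param proj An `inc_projection`.
#' @param path Output path.
#' @param samples_path Optional path for the predictive draws (cells as
#'   columns), written only when draws are available.
#' @return Invisibly, `path`.
#' @export
write_projection_csv <- function(proj, path, samples_path = NULL) {
  stopifnot(inherits(proj, "inc_projection"))
  utils::write.csv(proj$cells, path, row.names = FALSE, quote = FALSE)
  if (!is.null(samples_path) && !is.null(proj$samples))
    utils::write.csv(proj$samples, samples_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# predictive CDF at integer q for cell index; vectorized over cells
projection_cdf <- function(proj, q) {
  cdf <- proj$cdf
  m <- nrow(proj$cells)
  stopifnot(length(q) == m)
  switch(cdf$type,
         point = as.numeric(q >= cdf$point),
         pois = stats::ppois(q, cdf$mu),
         nb = stats::pnbinom(q, size = cdf$size, mu = cdf$mu),
         samples = vapply(seq_len(m), function(c_i)
           mean(proj$samples[, c_i] <= q[c_i]), numeric(1)))
}
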