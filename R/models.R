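#' @importFrom MASS glm.nb
NULL

# age-group midpoints of a registry table (closed intervals [l, l+w-1])
age_midpoints <- function(t) t$age_lower + (t$age_width - 1) / 2

# unroll a registry table year-major: one row per (year, age) cell
unroll_cells <- function(t) {
  I <- length(t$age_lower); J <- length(t$years)
  data.frame(j = rep(seq_len(J), each = I),
             i = rep(seq_len(I), times = J),
             year = rep(t$years, each = I),
             age_mid = rep(age_midpoints(t), times = J),
             age_lower = rep(t$age_lower, times = J),
             y = as.vector(t(t$incidence)),
             N = as.vector(t(t$population)))
}

new_inc_fit <- function(kind, engine, family, t, extra = list()) {
  structure(c(list(kind = kind, engine = engine, family = family,
                   years = t$years, age_lower = t$age_lower,
                   age_width = t$age_width, last_year = max(t$years),
                   age_mid = age_midpoints(t)),
              extra),
            class = "inc_fit")
}

#' @export
print.inc_fit <- function(x, ...) {
  cat("inc_fit: ", x$kind, " (", x$engine, ", ", x$family, "), trained on ",
      min(x$years), "-", max(x$years), ", ", length(x$age_lower),
      " age groups\n", sep = "")
  if (!is.null(x$converged)) cat("  converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Constant rate/count forward fit
#'
#' The simplest reference in the model ladder: carry the last observed row
#' forward. In `rate` mode the last observed age-specific rates are applied
#' to future populations; in `count` mode the last observed counts are kept
#' as-is. The predictive distribution is degenerate (SD 0, interval equal to
#' the point).
#'
#' @param t Training [registry_table()].
#' @param mode `"rate"` or `"count"`.
#' @return An `inc_fit`.
#' @export
fit_constant <- function(t, mode = c("rate", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "registry_table"))
  last <- length(t$years)
  new_inc_fit("constant", "none", "point", t,
              list(mode = mode,
                   last_counts = t$incidence[last, ],
                   last_rates = t$incidence[last, ] / t$population[last, ],
                   converged = TRUE))
}

#' Constant projection in one call
#'
#' Convenience wrapper: [fit_constant()] followed by [project()].
#'
#' @inheritParams fit_constant
#' @param future_N `horizon x I` matrix of future person-years (required for
#'   rate mode; recycled from a vector for a single year).
#' @param horizon Number of years beyond the last training year.
#' @return An `inc_projection`.
#' @export
project_constant <- function(t, mode = c("rate", "count"), future_N,
                             horizon = 1L) {
  project(fit_constant(t, mode), future_N = future_N, horizon = horizon)
}

# fixed-effect design for the GLM ladder; centering constants from training
glm_design <- function(cells, terms, center) {
  a <- cells$age_mid - center[1]
  p <- cells$year - center[2]
  switch(terms,
         intercept = cbind(intercept = rep(1, nrow(cells))),
         age_period = cbind(intercept = 1, age = a, period = p,
                            `age:period` = a * p),
         stop("unknown term set '", terms, "'"))
}

#' Fit a GLM from the projection ladder
#'
#' Count GLM with log person-years offset: either intercept-only
#' (`Y ~ offset(log(N))`) or the age-period interaction model
#' (`Y ~ offset(log(N)) + AGE*PERIOD`). Age and period enter as numeric
#' midpoints centered at their training means. The default family is
#' negative binomial; maximum likelihood uses [MASS::glm.nb()] (dispersion
#' profiled), the Bayesian engine places vague normal priors on the
#' coefficients.
#'
#' @param t Training [registry_table()].
#' @param terms `"intercept"` or `"age_period"`.
#' @param family `"nb"` or `"poisson"`.
#' @param engine `"ml"` or `"bayes"`.
#' @param seed RNG seed (Bayes engine).
#' @param mcmc List of engine settings (`n_iter`, `burnin`, `thin`).
#' @return An `inc_fit` whose [project()] method produces full predictive
#'   distributions.
#' @export
fit_glm <- function(t, terms = c("intercept", "age_period"),
                    family = c("nb", "poisson"), engine = c("ml", "bayes"),
                    seed = 1L, mcmc = list()) {
  terms <- match.arg(terms); family <- match.arg(family)
  engine <- match.arg(engine)
  cells <- unroll_cells(t)
  center <- c(mean(age_midpoints(t)), mean(t$years))
  X <- glm_design(cells, terms, center)
  extra <- list(terms = terms, center = center)
  if (engine == "ml") {
    fit <- fit_ml_counts(cells$y, X, log(cells$N), family)
    new_inc_fit(paste0("glm_", terms), "ml", family, t, c(extra, fit))
  } else {
    prob <- latent_gaussian_problem(cells$y, log(cells$N), X = X,
                                    family = family)
    pa <- do.call(fit_latent_gaussian,
                  c(list(prob = prob, seed = seed), mcmc))
    new_inc_fit(paste0("glm_", terms), "bayes", family, t,
                c(extra, list(pa = pa,
                              converged = pa$diagnostics$converged)))
  }
}

# shared ML fitting for NB/Poisson with offset; flags non-convergence
fit_ml_counts <- function(y, X, off, family) {
  dat <- data.frame(y = y, off = off)
  theta <- Inf
  if (family == "nb") {
    # theta walking to the Poisson boundary raises iteration-limit/NaN
    # warnings for (near-)equidispersed data; that is the nested-family
    # limit, not a failure, so convergence is judged from the final IRLS
    # fit and the finiteness of the estimates
    fit <- suppressWarnings(
      tryCatch(MASS::glm.nb(y ~ 0 + X + offset(off), data = dat,
                            control = stats::glm.control(maxit = 100)),
               error = function(e) e))
    if (inherits(fit, "error")) {
      # hard NB failure at the boundary: use the Poisson limit, theta = Inf
      fit <- stats::glm(y ~ 0 + X + offset(off), data = dat,
                        family = stats::poisson())
    } else theta <- fit$theta
  } else {
    fit <- stats::glm(y ~ 0 + X + offset(off), data = dat,
                      family = stats::poisson())
  }
  cf <- stats::coef(fit)
  names(cf) <- colnames(X)
  ok <- isTRUE(fit$converged) && all(is.finite(cf)) &&
    (is.infinite(theta) || theta > 0)
  if (!ok) warning("ML fit did not converge cleanly")
  list(coef = cf, theta = theta, converged = ok,
       loglik = as.numeric(stats::logLik(fit)))
}

#' Fit a GAM with a univariate age smoother
#'
#' Linear predictor: intercept + linear period + B-spline in age
#' (`Y ~ offset(log(N)) + PERIOD + bs(AGE)`), negative-binomial family by
#' default. The first B-spline column is dropped so the basis does not
#' duplicate the intercept. Degree 0 with `n_basis` equal to the number of
#' age groups gives a saturated-in-age (indicator) model.
#'
#' @inheritParams fit_glm
#' @param n_basis Number of age basis functions; default
#'   `min(10, ceiling(I/2) + 2)`, capped at the number of age groups `I`.
#' @param degree Spline degree (default cubic).
#' @param include_period Include the linear period term (default `TRUE`).
#' @return An `inc_fit`.
#' @export
fit_gam_age_spline <- function(t, n_basis = NULL, degree = 3,
                               family = c("nb", "poisson"),
                               engine = c("ml", "bayes"),
                               include_period = TRUE, seed = 1L,
                               mcmc = list()) {
  family <- match.arg(family); engine <- match.arg(engine)
  I <- length(t$age_lower)
  if (I < 2) stop("age smoother needs at least 2 age groups")
  if (is.null(n_basis)) n_basis <- min(10L, ceiling(I / 2) + 2L, I)
  if (n_basis > I)
    stop("n_basis (", n_basis, ") exceeds the number of age groups (", I, ")")
  mids <- age_midpoints(t)
  basis <- bspline_basis(mids, n_basis, degree)
  cells <- unroll_cells(t)
  center <- c(mean(mids), mean(t$years))
  Bage <- basis$values[cells$i, -1, drop = FALSE]
  colnames(Bage) <- paste0("bs", seq_len(ncol(Bage)) + 1L)
  X <- cbind(intercept = 1,
             if (include_period) cbind(period = cells$year - center[2]),
             Bage)
  extra <- list(basis = basis, center = center,
                include_period = include_period, n_basis = n_basis)
  if (engine == "ml") {
    fit <- fit_ml_counts(cells$y, X, log(cells$N), family)
    new_inc_fit("gam_age", "ml", family, t, c(extra, fit))
  } else {
    prob <- latent_gaussian_problem(cells$y, log(cells$N), X = X,
                                    family = family)
    pa <- do.call(fit_latent_gaussian,
                  c(list(prob = prob, seed = seed), mcmc))
    new_inc_fit("gam_age", "bayes", family, t,
                c(extra, list(pa = pa,
                              converged = pa$diagnostics$converged)))
  }
}

#' Fit the Bayesian tensor-product smoother (z-model)
#'
#' Smooth age x period surface expressed as a classical random-effects term
#' `eta = intercept + Z z`, where `Z` is the row-wise Kronecker product of
#' M-spline marginal bases in age and period, `z ~ N(0, tau^-1 I)` and the
#' precision `tau` carries a loggamma(a, b) prior (default a = 1, b = 0.005).
#' Negative-binomial family. The period basis is built over the training
#' years extended by `horizon`, so future cells have well-defined design rows
#' (coefficients supported only in the future shrink to the prior, which is
#' what carries random-walk-like predictive spread).
#'
#' @inheritParams fit_glm
#' @param n_basis_age,n_basis_period Marginal basis dimensions; defaults
#'   `min(10, ceiling(I/2) + 2)` and `min(8, ceiling(J/2) + 2)`.
#' @param prior `c(a, b)` of the Gamma prior on the precision of `z`.
#' @param horizon Years beyond the training span the period basis must cover.
#' @param degree Marginal spline degree.
#' @return An `inc_fit`.
#' @export
fit_tensor_z <- function(t, n_basis_age = NULL, n_basis_period = NULL,
                         prior = c(1, 0.005), horizon = 0L, degree = 3,
                         family = c("nb", "poisson"), seed = 1L,
                         mcmc = list()) {
  family <- match.arg(family)
  I <- length(t$age_lower); J <- length(t$years)
  if (is.null(n_basis_age)) n_basis_age <- min(10L, ceiling(I / 2) + 2L)
  if (is.null(n_basis_period)) n_basis_period <- min(8L, ceiling(J / 2) + 2L)
  n_basis_age <- min(n_basis_age, I)
  mids <- age_midpoints(t)
  years_all <- seq(min(t$years), max(t$years) + horizon)
  A <- mspline_basis(mids, n_basis_age, degree)
  P <- mspline_basis(years_all, n_basis_period, degree,
                     span = range(years_all))
  cells <- unroll_cells(t)
  Z <- tensor_product_rows(A$values[cells$i, , drop = FALSE],
                           P$values[match(cells$year, years_all), ,
                                    drop = FALSE])
  prob <- latent_gaussian_problem(
    cells$y, log(cells$N), X = cbind(intercept = rep(1, nrow(cells))),
    blocks = list(list(label = "z", Z = Z$values,
                       structure = iid_structure(ncol(Z$values)),
                       prior = prior)),
    family = family)
  pa <- do.call(fit_latent_gaussian, c(list(prob = prob, seed = seed), mcmc))
  new_inc_fit("tensor_z", "bayes", family, t,
              list(pa = pa, A = A, P = P, years_all = years_all,
                   horizon_built = horizon, prior = prior,
                   converged = pa$diagnostics$converged))
}

#' Fit the Bayesian age-period-cohort (APC) model
#'
#' Poisson likelihood with linear predictor
#' `eta_ij = mu + alpha_i + beta_j + gamma_k + u_ij`, where `alpha`, `beta`
#' and `gamma` are age, period and cohort effects under second-order
#' random-walk (rw2) priors, `u` is an iid overdispersion effect, and the
#' cohort index is `k = j + M * (I - i)` with grid factor `M` the age-group
#' width (requires a constant width). All precisions carry loggamma priors.
#' Age, period and cohort effects are reported under sum-to-zero constraints
#' (the cohort effect additionally detrended); individual effects remain
#' non-identified up to linear reallocations, so the estimands to interpret
#' are the predictor `eta` and the predictive counts.
#'
#' @inheritParams fit_glm
#' @param priors Named list of `c(a, b)` Gamma precision priors for `age`,
#'   `period`, `cohort`, `iid`; default loggamma(1, 0.005) each.
#' @return An `inc_fit`; its [project()] method extrapolates the period and
#'   cohort random walks with the rw2 predictive distribution and draws fresh
#'   overdispersion effects for future cells.
#' @export
fit_bapc <- function(t, priors = NULL, seed = 1L, mcmc = list()) {
  stopifnot(inherits(t, "registry_table"))
  lex <- table_lexis(t)
  I <- lex$I; J <- lex$J; M <- lex$M; K <- lex$K
  if (I < 3 || J < 3) stop("BAPC needs at least 3 age groups and 3 periods")
  defaults <- list(age = c(1, 0.005), period = c(1, 0.005),
                   cohort = c(1, 0.005), iid = c(1, 0.005))
  priors <- utils::modifyList(defaults, as.list(priors %||% list()))
  cells <- unroll_cells(t)
  n <- nrow(cells)
  k <- cohort_index(lex, cells$i, cells$j)
  ind <- function(f, m) {
    Z <- matrix(0, n, m); Z[cbind(seq_len(n), f)] <- 1; Z
  }
  blocks <- list(
    list(label = "age", Z = ind(cells$i, I), structure = rw2_structure(I),
         prior = priors$age),
    list(label = "period", Z = ind(cells$j, J), structure = rw2_structure(J),
         prior = priors$period),
    list(label = "cohort", Z = ind(k, K), structure = rw2_structure(K),
         prior = priors$cohort),
    list(label = "iid", Z = diag(n), structure = iid_structure(n),
         prior = priors$iid))
  p <- 1L + I + J + K + n
  ix_a <- 1L + seq_len(I); ix_b <- 1L + I + seq_len(J)
  ix_g <- 1L + I + J + seq_len(K)
  A <- matrix(0, 4, p)
  A[1, ix_a] <- 1; A[2, ix_b] <- 1; A[3, ix_g] <- 1
  A[4, ix_g] <- seq_len(K) - mean(seq_len(K))
  W <- matrix(0, p, 4)
  W[1, 1] <- -1; W[ix_a, 1] <- 1
  W[1, 2] <- -1; W[ix_b, 2] <- 1
  W[1, 3] <- -1; W[ix_g, 3] <- 1
  # drift direction: moving a linear trend between the three effects leaves
  # eta unchanged because k = j + M (I - i)
  W[1, 4] <- -M * I
  W[ix_a, 4] <- M * seq_len(I)
  W[ix_b, 4] <- -seq_len(J)
  W[ix_g, 4] <- seq_len(K)
  prob <- latent_gaussian_problem(
    cells$y, log(cells$N), X = cbind(intercept = rep(1, n)),
    blocks = blocks, family = "poisson",
    constraints = list(A = A, W = W))
  pa <- do.call(fit_latent_gaussian, c(list(prob = prob, seed = seed), mcmc))
  new_inc_fit("bapc", "bayes", "poisson", t,
              list(pa = pa, lexis = lex, priors = priors,
                   ix = list(mu = 1L, age = ix_a, period = ix_b,
                             cohort = ix_g,
                             iid = 1L + I + J + K + seq_len(n)),
                   converged = pa$diagnostics$converged))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
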