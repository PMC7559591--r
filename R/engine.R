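#' Latent Gaussian count-model problem
#'
#' Bundles the ingredients of a latent Gaussian model for counts:
#' `eta = X beta + sum_r Z_r z_r + offset`, with a Poisson, negative-binomial
#' or Gaussian likelihood, vague Gaussian priors on the fixed effects, and
#' structured Gaussian priors `z_r ~ N(0, (tau_r Q_r)^-1)` on each random
#' block, `tau_r` carrying a Gamma (loggamma on the log-precision) prior.
#'
#' Intrinsic structures (rw2) make the joint prior improper along
#' likelihood-null directions; linear identifiability constraints are given as
#' a pair `(A, W)`: rows of `A` are the constraints (`A x = 0`), columns of
#' `W` are directions that leave the linear predictor unchanged (`B W = 0`,
#' `B` the full design). Reported draws are projected as
#' `x - W (A W)^{-1} A x`, which enforces the constraints exactly without
#' touching `eta`.
#'
#' @param y Observed counts (or Gaussian responses).
#' @param offset Offset vector on the linear-predictor scale (log
#'   person-years for count models). Recycled if scalar.
#' @param X Fixed-effect design matrix (may be `NULL`).
#' @param blocks List of random-effect blocks, each a list with elements
#'   `label`, `Z` (design), `structure` ([rw2_structure()]/[iid_structure()])
#'   and `prior = c(a, b)` for the Gamma prior on the precision.
#' @param family `"poisson"`, `"nb"` or `"gaussian"`.
#' @param fixed_prior_mean,fixed_prior_prec Prior mean and precision of the
#'   fixed effects (vague by default).
#' @param gaussian_sd Known observation SD for the Gaussian family.
#' @param theta_prior Shape and rate of the Gamma prior on the NB dispersion.
#' @param constraints `NULL` or `list(A = , W = )` as described above.
#' @return An object of class `latent_gaussian_problem`.
#' @export
latent_gaussian_problem <- function(y, offset, X = NULL, blocks = list(),
                                    family = c("poisson", "nb", "gaussian"),
                                    fixed_prior_mean = 0,
                                    fixed_prior_prec = 1e-6,
                                    gaussian_sd = 1,
                                    theta_prior = c(1, 0.01),
                                    constraints = NULL) {
  family <- match.arg(family)
  y <- as.numeric(y)
  n <- length(y)
  offset <- rep_len(as.numeric(offset), n)
  if (!is.null(X)) {
    X <- as.matrix(X)
    stopifnot(nrow(X) == n)
  }
  p_fixed <- if (is.null(X)) 0L else ncol(X)
  designs <- list()
  index <- list()
  pos <- p_fixed
  for (r in seq_along(blocks)) {
    b <- blocks[[r]]
    stopifnot(!is.null(b$Z), !is.null(b$structure))
    Z <- as.matrix(b$Z)
    if (nrow(Z) != n) stop("block '", b$label, "' design has ", nrow(Z),
                           " rows, expected ", n)
    m <- ncol(Z)
    if (m != nrow(b$structure$Q))
      stop("block '", b$label, "' design/structure dimension mismatch")
    if (is.null(b$prior)) b$prior <- c(1, 0.005)
    index[[r]] <- pos + seq_len(m)
    pos <- pos + m
    designs[[r]] <- Z
    blocks[[r]] <- b
  }
  B <- do.call(cbind, c(if (p_fixed) list(X) else NULL, designs))
  if (is.null(B)) stop("model has no terms")
  p <- ncol(B)
  if (!is.null(constraints)) {
    stopifnot(is.matrix(constraints$A), is.matrix(constraints$W),
              ncol(constraints$A) == p, nrow(constraints$W) == p,
              nrow(constraints$A) == ncol(constraints$W))
    if (max(abs(B %*% constraints$W)) > 1e-8)
      stop("constraint null directions W do not annihilate the design")
    AW <- constraints$A %*% constraints$W
    if (abs(det(AW)) < 1e-12)
      stop("constraint rows are not resolvable by the given null directions")
  }
  structure(list(y = y, offset = offset, X = X, blocks = blocks, B = B,
                 n = n, p = p, p_fixed = p_fixed, index = index,
                 family = family,
                 fixed_prior_mean = rep_len(fixed_prior_mean, p_fixed),
                 fixed_prior_prec = fixed_prior_prec,
                 gaussian_sd = gaussian_sd, theta_prior = theta_prior,
                 constraints = constraints),
            class = "latent_gaussian_problem")
}

# log-likelihood, gradient and negative curvature w.r.t. eta
ll_parts <- function(family, y, eta, theta, gaussian_sd) {
  eta <- pmin(pmax(eta, -40), 40)
  if (family == "poisson") {
    mu <- exp(eta)
    list(ll = sum(y * eta - mu), g = y - mu, c = mu)
  } else if (family == "nb") {
    mu <- exp(eta)
    list(ll = sum(lgamma(y + theta) - lgamma(theta) + theta * log(theta) +
                    y * eta - (y + theta) * log(theta + mu)),
         g = y - (y + theta) * mu / (theta + mu),
         c = (y + theta) * theta * mu / (theta + mu)^2)
  } else {
    s2 <- gaussian_sd^2
    list(ll = -0.5 * sum((y - eta)^2) / s2,
         g = (y - eta) / s2,
         c = rep(1 / s2, length(y)))
  }
}

#' Fit a latent Gaussian problem by MCMC
#'
#' Posterior sampler combining (i) conjugate Gibbs updates of the block
#' precisions, (ii) a one-block independence Metropolis-Hastings update of the
#' whole latent field using a Gaussian (Laplace) approximation at the
#' conditional mode as proposal, and (iii) for the negative-binomial family, a
#' random-walk update of the log dispersion. The Laplace proposal makes
#' whole-field acceptance rates high for log-concave count likelihoods, so
#' modest chain lengths give accurate posterior summaries; accuracy is
#' checked against long-run gold-standard samplers in the package tests.
#'
#' A fixed tiny ridge on every latent block keeps the chain proper along the
#' null directions of intrinsic (rw2) structures; the precision updates use
#' the intrinsic rank, so the ridge does not bias the smoothing parameters.
#' Constraints declared in the problem are applied to reported draws by exact
#' linear-predictor-invariant projection.
#'
#' @param prob A [latent_gaussian_problem()].
#' @param seed Integer RNG seed.
#' @param n_iter Total MCMC sweeps.
#' @param burnin Sweeps discarded before storage.
#' @param thin Storage thinning interval.
#' @param ridge Proper-ization ridge added to each block precision.
#' @param theta_init Initial NB dispersion.
#' @return An object of class `posterior_approx` with draw matrices
#'   (`x_draws`, `eta_draws`, `tau_draws`, `theta_draws`), the problem,
#'   acceptance/convergence diagnostics and the seed.
#' @export
fit_latent_gaussian <- function(prob, seed = 1L, n_iter = 2000L,
                                burnin = 500L, thin = 1L, ridge = 1e-6,
                                theta_init = 100) {
  stopifnot(inherits(prob, "latent_gaussian_problem"),
            n_iter > burnin, burnin >= 0, thin >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  B <- prob$B; y <- prob$y; off <- prob$offset
  n <- prob$n; p <- prob$p
  R <- length(prob$blocks)
  # fixed parts of the prior precision
  Q0_base <- matrix(0, p, p)
  if (prob$p_fixed > 0) {
    fi <- seq_len(prob$p_fixed)
    diag(Q0_base)[fi] <- prob$fixed_prior_prec
  }
  for (r in seq_len(R)) {
    ix <- prob$index[[r]]
    diag(Q0_base)[ix] <- diag(Q0_base)[ix] + ridge
  }
  mu0 <- numeric(p)
  if (prob$p_fixed > 0) mu0[seq_len(prob$p_fixed)] <- prob$fixed_prior_mean
  block_rank <- vapply(prob$blocks, function(b)
    nrow(b$structure$Q) - b$structure$rank_deficiency, numeric(1))

  # projection for constraints on reported draws
  remap <- identity
  if (!is.null(prob$constraints)) {
    A <- prob$constraints$A; W <- prob$constraints$W
    P <- W %*% solve(A %*% W)
    remap <- function(x) x - P %*% (A %*% x)
  }

  # start precisions at 1 (not the prior mean): a tight initial prior would
  # pin the random effects at zero before the likelihood can pull them out
  tau <- rep(1, R)
  theta <- theta_init
  x <- mu0
  mode_cache <- mu0
  log_sd_theta <- log(0.5)

  build_Q0 <- function(tau) {
    Q0 <- Q0_base
    for (r in seq_len(R)) {
      ix <- prob$index[[r]]
      Q0[ix, ix] <- Q0[ix, ix] + tau[r] * prob$blocks[[r]]$structure$Q
    }
    Q0
  }
  log_prior_x <- function(x, Q0) {
    d <- x - mu0
    -0.5 * sum(d * (Q0 %*% d))
  }

  S <- floor((n_iter - burnin) / thin)
  x_draws <- matrix(NA_real_, S, p)
  eta_draws <- matrix(NA_real_, S, n)
  tau_draws <- matrix(NA_real_, S, max(R, 1))
  theta_draws <- rep(NA_real_, S)
  logpost_trace <- rep(NA_real_, S)
  acc_lat <- 0L; acc_th <- 0L; n_th <- 0L
  s_out <- 0L

  for (it in seq_len(n_iter)) {
    ## 1. block precisions (conjugate given z)
    for (r in seq_len(R)) {
      ix <- prob$index[[r]]
      z <- x[ix]
      qf <- sum(z * (prob$blocks[[r]]$structure$Q %*% z))
      a <- prob$blocks[[r]]$prior[1] + block_rank[r] / 2
      b <- prob$blocks[[r]]$prior[2] + qf / 2
      tau[r] <- pmin(pmax(stats::rgamma(1, shape = a, rate = b), 1e-6), 1e8)
    }
    Q0 <- build_Q0(tau)

    ## 2. latent field: Laplace approximation at the conditional mode,
    ##    independence MH proposal
    find_mode <- function(start, fam, th) {
      m <- start
      for (newton in 1:50) {
        eta_m <- drop(B %*% m) + off
        parts <- ll_parts(fam, y, eta_m, th, prob$gaussian_sd)
        Qp <- Q0 + crossprod(B * sqrt(parts$c))
        grad <- drop(crossprod(B, parts$g)) - drop(Q0 %*% (m - mu0))
        Rch <- chol(Qp)
        step <- backsolve(Rch, backsolve(Rch, grad, transpose = TRUE))
        # damped step: only ever move uphill on the joint objective
        obj0 <- parts$ll + log_prior_x(m, Q0)
        lambda <- 1
        moved <- FALSE
        while (lambda >= 1e-6) {
          m_new <- m + lambda * step
          eta_new <- drop(B %*% m_new) + off
          obj1 <- ll_parts(fam, y, eta_new, th, prob$gaussian_sd)$ll +
            log_prior_x(m_new, Q0)
          if (is.finite(obj1) && obj1 >= obj0 - 1e-12) { moved <- TRUE; break }
          lambda <- lambda / 2
        }
        if (!moved) break
        m <- m_new
        if (max(abs(lambda * step)) < 1e-6) break
      }
      m
    }
    # the NB log-likelihood is nearly flat in eta wherever the mean grossly
    # overshoots, so seed its mode search from the (well-conditioned)
    # Poisson mode on the first sweep
    if (it == 1L && prob$family == "nb")
      mode_cache <- find_mode(mode_cache, "poisson", theta)
    m <- find_mode(mode_cache, prob$family, theta)
    mode_cache <- m
    # start the chain at the conditional mode (discarded with the burn-in)
    if (it == 1L) x <- m
    # final curvature at the mode
    eta_m <- drop(B %*% m) + off
    parts_m <- ll_parts(prob$family, y, eta_m, theta, prob$gaussian_sd)
    Qp <- Q0 + crossprod(B * sqrt(parts_m$c))
    Rch <- chol(Qp)
    prop <- m + backsolve(Rch, stats::rnorm(p))
    log_q <- function(v) {
      d <- v - m
      Rd <- Rch %*% d
      -0.5 * sum(Rd * Rd)   # log det cancels in the ratio
    }
    target <- function(v) {
      eta_v <- drop(B %*% v) + off
      ll_parts(prob$family, y, eta_v, theta, prob$gaussian_sd)$ll +
        log_prior_x(v, Q0)
    }
    t_prop <- target(prop); t_cur <- target(x)
    lr <- (t_prop - t_cur) + (log_q(x) - log_q(prop))
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      x <- prop
      acc_lat <- acc_lat + 1L
    }

    ## 3. NB dispersion (random-walk MH on log theta), after the latent
    ##    update so theta always sees the current linear predictor; held at
    ##    its near-equidispersed start for a few sweeps so early latent
    ##    misfit is not absorbed into overdispersion
    if (prob$family == "nb" && it > 5L) {
      n_th <- n_th + 1L
      eta_cur <- drop(B %*% x) + off
      th_new <- exp(log(theta) + stats::rnorm(1, 0, exp(log_sd_theta)))
      lp_cur <- ll_parts("nb", y, eta_cur, theta, 1)$ll +
        stats::dgamma(theta, prob$theta_prior[1], prob$theta_prior[2], log = TRUE) +
        log(theta)
      lp_new <- ll_parts("nb", y, eta_cur, th_new, 1)$ll +
        stats::dgamma(th_new, prob$theta_prior[1], prob$theta_prior[2], log = TRUE) +
        log(th_new)
      if (is.finite(lp_new) && log(stats::runif(1)) < lp_new - lp_cur) {
        theta <- th_new; acc_th <- acc_th + 1L
      }
      if (it <= burnin && it %% 50 == 0) {
        rate <- acc_th / n_th
        log_sd_theta <- log_sd_theta + (rate - 0.4) * 0.5
      }
    }

    ## 4. storage
    if (it > burnin && (it - burnin) %% thin == 0) {
      s_out <- s_out + 1L
      xr <- drop(remap(x))
      x_draws[s_out, ] <- xr
      eta_draws[s_out, ] <- drop(B %*% x) + off
      if (R > 0) tau_draws[s_out, seq_len(R)] <- tau
      theta_draws[s_out] <- theta
      logpost_trace[s_out] <- t_cur
    }
  }

  acc_rate <- acc_lat / n_iter
  lp <- logpost_trace[seq_len(s_out)]
  n1 <- max(2, floor(0.2 * s_out)); n2 <- max(2, floor(0.5 * s_out))
  a1 <- lp[seq_len(n1)]; a2 <- lp[(s_out - n2 + 1):s_out]
  gz <- (mean(a1) - mean(a2)) /
    sqrt(stats::var(a1) / n1 + stats::var(a2) / n2 + 1e-12)
  converged <- acc_rate > 0.05 && is.finite(gz) && abs(gz) < 6
  if (!converged)
    warning("MCMC convergence suspect: acceptance ", signif(acc_rate, 3),
            ", Geweke-type z = ", signif(gz, 3))

  structure(list(prob = prob, x_draws = x_draws[seq_len(s_out), , drop = FALSE],
                 eta_draws = eta_draws[seq_len(s_out), , drop = FALSE],
                 tau_draws = tau_draws[seq_len(s_out), , drop = FALSE],
                 theta_draws = theta_draws[seq_len(s_out)],
                 logpost = lp,
                 block_labels = vapply(prob$blocks, function(b)
                   as.character(b$label), character(1)),
                 index = prob$index, p_fixed = prob$p_fixed,
                 diagnostics = list(acceptance_latent = acc_rate,
                                    acceptance_theta = if (n_th) acc_th / n_th else NA,
                                    geweke_z = gz, converged = converged),
                 method = "laplace-imh", seed = as.integer(seed)),
            class = "posterior_approx")
}

#' @export
print.posterior_approx <- function(x, ...) {
  cat("posterior_approx (", x$method, "): ", nrow(x$x_draws), " draws, ",
      ncol(x$x_draws), " latent parameters, family ", x$prob$family, "\n",
      sep = "")
  cat("  latent acceptance ", signif(x$diagnostics$acceptance_latent, 3),
      "; converged: ", x$diagnostics$converged, "\n", sep = "")
  invisible(x)
}

#' Posterior-predictive count draws for new cells
#'
#' Generates predictive count draws for cells whose linear predictor is a
#' known linear function of the fitted latent field (design rows conformable
#' with the training design). Each stored posterior draw contributes one
#' predictive draw per cycle, so hyperparameter, latent and observation noise
#' are all propagated.
#'
#' @param pa A `posterior_approx`.
#' @param new_B Design matrix for the new cells (columns match the latent
#'   field).
#' @param new_offset Offset for the new cells (log person-years).
#' @param n_samples Number of predictive draws (>= 100).
#' @param seed RNG seed.
#' @return `n_samples x nrow(new_B)` matrix of count draws.
#' @export
posterior_predictive <- function(pa, new_B, new_offset, n_samples = 2000L,
                                 seed = 1L) {
  stopifnot(inherits(pa, "posterior_approx"))
  if (n_samples < 100) stop("need at least 100 samples for interval construction")
  new_B <- as.matrix(new_B)
  stopifnot(ncol(new_B) == ncol(pa$x_draws))
  m <- nrow(new_B)
  new_offset <- rep_len(new_offset, m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  S <- nrow(pa$x_draws)
  idx <- rep_len(seq_len(S), n_samples)
  eta <- pa$x_draws[idx, , drop = FALSE] %*% t(new_B) +
    matrix(new_offset, n_samples, m, byrow = TRUE)
  draw_counts(pa$prob$family, eta, pa$theta_draws[idx])
}

# family sampler on the count scale; eta is a draws x cells matrix
draw_counts <- function(family, eta, theta = NULL) {
  mu <- exp(pmin(eta, 40))
  nS <- nrow(eta); m <- ncol(eta)
  if (family == "poisson") {
    matrix(stats::rpois(nS * m, as.vector(mu)), nS, m)
  } else if (family == "nb") {
    matrix(stats::rnbinom(nS * m, size = rep(theta, m), mu = as.vector(mu)),
           nS, m)
  } else {
    matrix(stats::rnorm(nS * m, mean = as.vector(mu)), nS, m)
  }
}
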