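#' Specification of a synthetic registry
#'
#' Describes a generative age-period-cohort model on the log-rate scale,
#' `eta_ij = base + f_age(i) + drift * (year_j - mean) + gamma_k
#'  [+ interaction]`, with Poisson or negative-binomial counts on smooth,
#' growing population matrices. The cohort effect is built as twice-integrated
#' noise (an rw2-style smooth curve) indexed by `k = j + M (I - i)`, so the
#' generative geometry matches the Bayesian APC model exactly.
#'
#' Default sizes emulate a mid-size registry extract: 40 years, thirteen
#' 5-year age groups spanning ages 20-84, a few hundred thousand person-years
#' per cell, and a log-quadratic age curve rising from roughly 2 to 90 cases
#' per 100 000 across adult ages.
#'
#' @param n_years,start_year Calendar span.
#' @param n_ages,age_width,age_start Age-group grid.
#' @param base_log_rate Log rate at the age-curve reference.
#' @param age_curve `"quadratic"` (log-quadratic in age) or `"bump"`
#'   (Gaussian bump).
#' @param age_pars Parameters of the age curve: for `"quadratic"`,
#'   `c(lin, quad)` applied to standardized age; for `"bump"`,
#'   `c(center, width, height)` in years/log units.
#' @param drift Log-linear period drift per year.
#' @param cohort_amp Standard deviation of the smooth cohort curve (0 = none).
#' @param interaction Coefficient of a standardized age x period product term
#'   (0 = none).
#' @param noise `"poisson"` or `"nb"`.
#' @param nb_dispersion NB size parameter (smaller = more overdispersed).
#' @param pop_start Person-years per age group in the first year (vector or
#'   scalar).
#' @param pop_growth Annual relative population growth.
#' @param seed Integer seed; simulation is a deterministic function of the
#'   spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_years = 40L, start_year = 1975L, n_ages = 13L,
                           age_width = 5L, age_start = 20L,
                           base_log_rate = -8.5,
                           age_curve = c("quadratic", "bump"),
                           age_pars = c(1.6, 0.25),
                           drift = 0.01, cohort_amp = 0.15,
                           interaction = 0,
                           noise = c("poisson", "nb"), nb_dispersion = 30,
                           pop_start = 4e5, pop_growth = 0.005,
                           seed = 1L) {
  age_curve <- match.arg(age_curve)
  noise <- match.arg(noise)
  stopifnot(n_years >= 2, n_ages >= 2, age_width >= 1, nb_dispersion > 0,
            all(pop_start > 0))
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 n_ages = as.integer(n_ages),
                 age_width = as.integer(age_width),
                 age_start = as.integer(age_start),
                 base_log_rate = base_log_rate, age_curve = age_curve,
                 age_pars = age_pars, drift = drift,
                 cohort_amp = cohort_amp, interaction = interaction,
                 noise = noise, nb_dispersion = nb_dispersion,
                 pop_start = rep_len(pop_start, n_ages),
                 pop_growth = pop_growth, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a registry table with known APC truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with `table` (a [registry_table()]) and `truth`: the log-rate
#'   matrix `eta`, the rate matrix, and the age/period/cohort effect vectors
#'   used, for parameter-recovery tests.
#' @export
simulate_registry <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  I <- spec$n_ages; J <- spec$n_years; M <- spec$age_width
  years <- spec$start_year + seq_len(J) - 1L
  age_lower <- spec$age_start + (seq_len(I) - 1L) * M
  mids <- age_lower + (M - 1) / 2
  a_std <- (mids - mean(mids)) / stats::sd(mids)

  age_eff <- switch(spec$age_curve,
                    quadratic = spec$age_pars[1] * a_std +
                      spec$age_pars[2] * a_std^2,
                    bump = spec$age_pars[3] *
                      exp(-0.5 * ((mids - spec$age_pars[1]) /
                                    spec$age_pars[2])^2))
  age_eff <- age_eff - mean(age_eff)
  period_eff <- spec$drift * (years - mean(years))

  lex <- lexis_spec(I, J, M)
  cohort_eff <- numeric(lex$K)
  if (spec$cohort_amp > 0) {
    raw <- cumsum(cumsum(stats::rnorm(lex$K)))
    k <- seq_len(lex$K)
    detr <- stats::residuals(stats::lm(raw ~ k))
    cohort_eff <- detr / max(stats::sd(detr), 1e-12) * spec$cohort_amp
  }

  eta <- matrix(spec$base_log_rate, J, I)
  for (j in seq_len(J)) for (i in seq_len(I)) {
    eta[j, i] <- eta[j, i] + age_eff[i] + period_eff[j] +
      cohort_eff[cohort_index(lex, i, j)] +
      spec$interaction * a_std[i] * (years[j] - mean(years)) /
        stats::sd(years)
  }
  rate <- exp(eta)
  over <- which(rate >= 1, arr.ind = TRUE)
  if (nrow(over) > 0)
    stop("simulated rate >= 1 at year ", years[over[1, 1]], ", age group ",
         age_lower[over[1, 2]], "; lower base_log_rate or effect sizes")

  pop <- outer((1 + spec$pop_growth)^(seq_len(J) - 1L), spec$pop_start)
  mu <- pop * rate
  y <- if (spec$noise == "poisson")
    stats::rpois(J * I, as.vector(mu))
  else stats::rnbinom(J * I, size = spec$nb_dispersion, mu = as.vector(mu))
  tab <- registry_table(years, age_lower,
                        matrix(y, J, I), pop, age_width = M)
  list(table = tab,
       truth = list(eta = eta, rate = rate, age = age_eff,
                    period = period_eff, cohort = cohort_eff, mu = mu))
}

#' Named library of synthetic scenarios
#'
#' A ladder of generative scenarios matching the model ladder, so that each
#' model is correctly specified for at least one scenario: `flat` (constant
#' rate), `age_only`, `age_drift`, `age_period_interaction`, `full_apc` and
#' `overdispersed` (full APC with NB noise).
#'
#' @param seed Base seed; each scenario gets a distinct derived seed.
#' @return Named list of [synthetic_spec()] objects.
#' @export
scenario_library <- function(seed = 1L) {
  s <- as.integer(seed)
  list(
    flat = synthetic_spec(age_pars = c(0, 0), drift = 0, cohort_amp = 0,
                          seed = s),
    age_only = synthetic_spec(drift = 0, cohort_amp = 0, seed = s + 1L),
    age_drift = synthetic_spec(cohort_amp = 0, seed = s + 2L),
    age_period_interaction = synthetic_spec(cohort_amp = 0,
                                            interaction = 0.3,
                                            seed = s + 3L),
    full_apc = synthetic_spec(seed = s + 4L),
    overdispersed = synthetic_spec(noise = "nb", nb_dispersion = 15,
                                   seed = s + 5L))
}
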