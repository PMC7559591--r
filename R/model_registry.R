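#' Declare a model for benchmarking
#'
#' Wraps a fitting closure so [evaluate()] and the command-line tools can
#' treat every model in the ladder uniformly.
#'
#' @param id Short machine-readable identifier.
#' @param fit Function `(table, horizon, seed) -> inc_fit`.
#' @param label Human-readable description.
#' @return An object of class `inc_model`.
#' @export
inc_model <- function(id, fit, label = id) {
  stopifnot(is.character(id), is.function(fit))
  structure(list(id = id, fit = fit, label = label), class = "inc_model")
}

#' @export
print.inc_model <- function(x, ...) {
  cat("inc_model:", x$id, "-", x$label, "\n")
  invisible(x)
}

#' The standard model ladder
#'
#' Builds the benchmark models by name, from least to most complex:
#' \describe{
#'   \item{`constant_rate`, `constant_count`}{last observed rates/counts
#'     carried forward, degenerate intervals.}
#'   \item{`glm_intercept`}{intercept-only count GLM with offset.}
#'   \item{`glm_intercept_poisson`}{intercept-only Poisson GLM; with the NB
#'     family an intercept-only model absorbs any age gradient into its
#'     dispersion estimate and its predictive intervals balloon, so the
#'     Poisson variant is the one that exhibits the classic overconfidence
#'     of ignoring age (see the methods vignette).}
#'   \item{`glm_age_period`}{GLM with linear age, period and their
#'     interaction.}
#'   \item{`gam_age_bs`}{GAM with a B-spline age smoother and linear period.}
#'   \item{`tensor_z`}{Bayesian tensor-product (M-spline) age x period
#'     smoother, z-model representation.}
#'   \item{`bapc`}{Bayesian age-period-cohort model with rw2 priors and
#'     overdispersion.}
#' }
#' GLMs and GAMs use the negative-binomial family; BAPC is Poisson with an
#' explicit overdispersion effect.
#'
#' @param names Character vector of model ids (default: the full ladder).
#' @param glm_engine `"ml"` or `"bayes"` for the GLM/GAM members.
#' @param mcmc List of MCMC settings passed to Bayesian fits.
#' @param n_samples Unused here; predictive draw counts are set in
#'   [evaluate()]/[project()].
#' @return List of [inc_model()] objects.
#' @export
model_library <- function(names = c("constant_rate", "glm_intercept",
                                    "glm_age_period", "gam_age_bs",
                                    "tensor_z", "bapc"),
                          glm_engine = "ml", mcmc = list(), n_samples = NULL) {
  build <- function(nm) {
    switch(nm,
      constant_rate = inc_model("constant_rate",
        function(t, horizon, seed) fit_constant(t, "rate"),
        "constant rates forward"),
      constant_count = inc_model("constant_count",
        function(t, horizon, seed) fit_constant(t, "count"),
        "constant counts forward"),
      glm_intercept = inc_model("glm_intercept",
        function(t, horizon, seed)
          fit_glm(t, "intercept", family = "nb", engine = glm_engine,
                  seed = seed, mcmc = mcmc),
        "intercept-only NB GLM"),
      glm_intercept_poisson = inc_model("glm_intercept_poisson",
        function(t, horizon, seed)
          fit_glm(t, "intercept", family = "poisson", engine = glm_engine,
                  seed = seed, mcmc = mcmc),
        "intercept-only Poisson GLM"),
      glm_age_period = inc_model("glm_age_period",
        function(t, horizon, seed)
          fit_glm(t, "age_period", family = "nb", engine = glm_engine,
                  seed = seed, mcmc = mcmc),
        "NB GLM with age, period and interaction"),
      gam_age_bs = inc_model("gam_age_bs",
        function(t, horizon, seed)
          fit_gam_age_spline(t, family = "nb", engine = glm_engine,
                             seed = seed, mcmc = mcmc),
        "NB GAM with B-spline age smoother"),
      tensor_z = inc_model("tensor_z",
        function(t, horizon, seed)
          fit_tensor_z(t, horizon = horizon, seed = seed, mcmc = mcmc),
        "Bayesian tensor-product (M-spline) smoother"),
      bapc = inc_model("bapc",
        function(t, horizon, seed)
          fit_bapc(t, seed = seed, mcmc = mcmc),
        "Bayesian age-period-cohort model"),
      stop("unknown model '", nm, "'"))
  }
  lapply(names, build)
}
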