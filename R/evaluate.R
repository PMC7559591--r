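#' Rolling hold-out evaluation design
#'
#' Backtesting layout: for each projection horizon `n`, a model is trained on
#' the `L` years ending `n` years before the most recent observed year `T`
#' (training window `[T - n - L + 1, T - n]`) and scored on the observed
#' year `T`. Defaults follow common registry practice: a 15-year observation
#' window and horizons of 2, 5, 10, 15 and 20 years.
#'
#' @param observation_length Training window length `L` in years.
#' @param horizons Integer vector of projection horizons.
#' @param target_year Evaluation year `T`; defaults to the last year of the
#'   table when windows are built.
#' @return An object of class `evaluation_design`.
#' @export
evaluation_design <- function(observation_length = 15L,
                              horizons = c(2L, 5L, 10L, 15L, 20L),
                              target_year = NULL) {
  stopifnot(observation_length >= 1, all(horizons >= 1))
  structure(list(observation_length = as.integer(observation_length),
                 horizons = as.integer(sort(unique(horizons))),
                 target_year = target_year),
            class = "evaluation_design")
}

#' Enumerate training/target windows
#'
#' @param t A [registry_table()].
#' @param d An [evaluation_design()].
#' @return List with one element per feasible horizon:
#'   `list(horizon, train_years, target_year)`. Horizons the table cannot
#'   support (fewer than `L + n` years ending at `T`) are skipped with a
#'   warning.
#' @export
make_windows <- function(t, d) {
  stopifnot(inherits(t, "registry_table"), inherits(d, "evaluation_design"))
  Tyr <- d$target_year %||% max(t$years)
  L <- d$observation_length
  out <- list()
  for (n in d$horizons) {
    train <- seq(Tyr - n - L + 1L, Tyr - n)
    if (!all(train %in% t$years) || !(Tyr %in% t$years)) {
      warning("horizon ", n, " skipped: needs years ", min(train), "-", Tyr)
      next
    }
    out[[length(out) + 1L]] <- list(horizon = n, train_years = train,
                                    target_year = Tyr)
  }
  out
}

#' Interval coverage
#'
#' Fraction of observed counts lying inside their equal-tailed predictive
#' interval, bounds inclusive. Degenerate intervals (constant models) cover
#' only an exactly equal observation.
#'
#' @param proj An `inc_projection` (or anything with `cells$lo`/`cells$hi`).
#' @param observed Observed counts, one per projected cell.
#' @return Fraction in `[0, 1]`.
#' @export
coverage <- function(proj, observed) {
  cells <- if (!is.null(proj$cells)) proj$cells else proj
  if (length(observed) != nrow(cells))
    stop("got ", length(observed), " observations for ", nrow(cells), " cells")
  mean(cells$lo <= observed & observed <= cells$hi)
}

#' Relative projection bias (percent)
#'
#' `0` when observed equals predicted, else
#' `100 * (observed - predicted) / observed`; negative values mean the model
#' over-predicted. Undefined (`NA`) when the observed count is 0 and the
#' prediction is not; such cells are excluded from aggregates and counted.
#'
#' @param observed Observed counts (vectorized).
#' @param predicted Predictive means.
#' @return Percent bias per cell, `NA` where undefined.
#' @export
bias <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), all(observed >= 0))
  out <- ifelse(observed == predicted, 0,
                100 * (observed - predicted) / observed)
  out[observed == 0 & predicted != 0] <- NA_real_
  out
}

#' Projection precision
#'
#' Arithmetic mean of the per-cell predictive standard deviations (as a
#' precision measure: smaller = more precise), together with a
#' compressed companion `log10(1 + mean SD)` convenient for plotting across
#' registries of different size.
#'
#' @param proj An `inc_projection`.
#' @return List with `raw` and `transformed`.
#' @export
precision <- function(proj) {
  cells <- if (!is.null(proj$cells)) proj$cells else proj
  raw <- mean(cells$sd)
  list(raw = raw, transformed = log10(1 + raw))
}

#' Benchmark a set of models on one registry table
#'
#' The package's core loop: for every model and every feasible horizon `n`,
#' fit on the `L`-year training window, project to the target year using the
#' actually observed future populations, and aggregate per-age-group metrics
#' (coverage of the 95% band, percent bias, predictive SD) by arithmetic
#' mean. Fit failures are recorded and skipped, never fatal. Bias truncation
#' (e.g. at -200 for display) is a plotting concern and is never applied to
#' stored records.
#'
#' @param t A [registry_table()] (already age-filtered as desired).
#' @param models List of model descriptors from [model_library()] /
#'   [inc_model()].
#' @param d An [evaluation_design()].
#' @param seed Integer; per-(model, horizon) seeds are derived from it, so a
#'   rerun with the same seed reproduces records exactly.
#' @param n_samples Predictive draws per projection.
#' @return A `data.frame` (class `metrics_record`) with one row per model x
#'   horizon: `model`, `horizon`, `n_cells`, `coverage`, `bias`,
#'   `bias_n_undefined`, `precision_raw`, `precision_transformed`, `error`.
#'   Projections are attached as `attr(, "projections")`.
#' @export
evaluate <- function(t, models, d = evaluation_design(), seed = 1L,
                     n_samples = 2000L) {
  stopifnot(inherits(t, "registry_table"))
  if (inherits(models, "inc_model")) models <- list(models)
  windows <- make_windows(t, d)
  if (length(windows) == 0) stop("no feasible horizon for this table")
  rows <- list()
  projections <- list()
  counter <- 0L
  for (m in models) {
    stopifnot(inherits(m, "inc_model"))
    for (w in windows) {
      counter <- counter + 1L
      # derive per-fit seeds in double precision to avoid 32-bit overflow
      fit_seed <- as.integer((as.numeric(seed) * 1000 + counter * 7) %%
                               2147483629)
      train <- filter_years(t, w$train_years)
      future_years <- seq(max(w$train_years) + 1L, w$target_year)
      future_N <- t$population[match(future_years, t$years), , drop = FALSE]
      res <- tryCatch({
        fit <- m$fit(train, horizon = w$horizon, seed = fit_seed)
        proj <- project(fit, future_N, horizon = w$horizon,
                        n_samples = n_samples, seed = fit_seed + 1L)
        target_cells <- proj$cells$year == w$target_year
        proj_target <- proj
        proj_target$cells <- proj$cells[target_cells, , drop = FALSE]
        if (!is.null(proj$samples))
          proj_target$samples <- proj$samples[, target_cells, drop = FALSE]
        if (proj$cdf$type %in% c("pois", "nb", "point"))
          proj_target$cdf <- lapply(proj$cdf, function(v)
            if (length(v) == nrow(proj$cells)) v[target_cells] else v)
        obs <- t$incidence[match(w$target_year, t$years), ]
        b <- bias(obs, proj_target$cells$mean)
        pr <- precision(proj_target)
        list(record = data.frame(
          model = m$id, horizon = w$horizon,
          n_cells = nrow(proj_target$cells),
          coverage = coverage(proj_target, obs),
          bias = mean(b, na.rm = TRUE),
          bias_n_undefined = sum(is.na(b)),
          precision_raw = pr$raw,
          precision_transformed = pr$transformed,
          error = NA_character_,
          stringsAsFactors = FALSE),
          projection = proj_target)
      }, error = function(e) {
        list(record = data.frame(
          model = m$id, horizon = w$horizon, n_cells = NA_integer_,
          coverage = NA_real_, bias = NA_real_,
          bias_n_undefined = NA_integer_, precision_raw = NA_real_,
          precision_transformed = NA_real_,
          error = conditionMessage(e), stringsAsFactors = FALSE),
          projection = NULL)
      })
      rows[[counter]] <- res$record
      projections[[paste(m$id, w$horizon, sep = "_h")]] <- res$projection
    }
  }
  out <- do.call(rbind, rows)
  if (length(t$meta)) for (nm in names(t$meta)) out[[nm]] <- t$meta[[nm]]
  class(out) <- c("metrics_record", class(out))
  attr(out, "projections") <- projections
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Probability integral transform for count forecasts
#'
#' Nonrandomized PIT adapted to discreteness: per cell the value
#' `(F(y) + F(y - 1)) / 2` of the predictive CDF `F`, binned into equal-width
#' bins on `[0, 1]`. A calibrated forecast gives a uniform histogram;
#' under-dispersed forecasts give the characteristic U shape.
#'
#' @param proj An `inc_projection` with CDF access (draws or analytic).
#' @param observed Observed counts, one per cell.
#' @param bins Number of histogram bins (default 10).
#' @return List with `counts` (per bin), `breaks` and the per-cell `pit`
#'   values.
#' @export
pit <- function(proj, observed, bins = 10L) {
  stopifnot(inherits(proj, "inc_projection"))
  m <- nrow(proj$cells)
  if (length(observed) != m)
    stop("got ", length(observed), " observations for ", m, " cells")
  Fy <- projection_cdf(proj, observed)
  Fy1 <- projection_cdf(proj, observed - 1)
  z <- (Fy + Fy1) / 2
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- as.integer(table(cut(z, breaks, include.lowest = TRUE)))
  list(counts = counts, breaks = breaks, pit = z)
}

#' Write metrics records to CSV and JSON
#'
#' @param metrics A `metrics_record` data frame from [evaluate()].
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the metrics.
#' @export
write_metrics <- function(metrics, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(metrics)
  if (!is.null(csv_path))
    utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", digits = NA,
                         na = "null")
  invisible(metrics)
}
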