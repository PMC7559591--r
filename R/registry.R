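#' Registry incidence/population table
#'
#' Container for the paired matrices a population-based registry publishes:
#' incidence counts `Y` and person-years at risk `N`, with calendar years in
#' rows (ascending) and age groups in columns (ascending, constant width).
#'
#' @param years Integer vector of calendar years, one per row. Must be
#'   strictly increasing with step 1 (re-ordered if supplied unsorted).
#' @param age_lower Integer vector of age-group lower bounds, one per column,
#'   strictly increasing with a constant step.
#' @param incidence Non-negative integer matrix of case counts,
#'   `length(years)` x `length(age_lower)`.
#' @param population Positive numeric matrix of person-years at risk, same
#'   shape as `incidence`.
#' @param age_width Width of each age group in years. Defaults to the common
#'   difference of `age_lower` (or 1 for a single column).
#' @param open_top Logical; `TRUE` if the last age group is open-ended
#'   ("85+"): its upper bound is treated as infinite and the default age
#'   filter never retains it.
#' @param meta Optional named list of metadata (entity, sex, registry name)
#'   carried through to evaluation records.
#'
#' @return An object of class `registry_table` with elements `years`,
#'   `age_lower`, `age_width`, `age_upper`, `incidence`, `population`, `meta`.
#' @examples
#' tab <- registry_table(2000:2004, seq(20, 80, by = 5),
#'                       matrix(5L, 5, 13), matrix(1e5, 5, 13))
#' dim(tab$incidence)
#' @export
registry_table <- function(years, age_lower, incidence, population,
                           age_width = NULL, open_top = FALSE, meta = list()) {
  years <- as.integer(years)
  age_lower <- as.integer(age_lower)
  incidence <- as.matrix(incidence)
  population <- as.matrix(population)
  if (!identical(dim(incidence), dim(population)))
    stop("incidence (", paste(dim(incidence), collapse = "x"),
         ") and population (", paste(dim(population), collapse = "x"),
         ") matrices differ in shape")
  if (nrow(incidence) != length(years))
    stop("incidence has ", nrow(incidence), " rows but ", length(years),
         " years were given")
  if (ncol(incidence) != length(age_lower))
    stop("incidence has ", ncol(incidence), " columns but ", length(age_lower),
         " age groups were given")
  ord <- order(years)
  years <- years[ord]
  incidence <- incidence[ord, , drop = FALSE]
  population <- population[ord, , drop = FALSE]
  if (length(years) > 1 && any(diff(years) != 1L))
    stop("years must be consecutive calendar years; got gaps at ",
         paste(years[which(diff(years) != 1L)], collapse = ", "))
  if (anyDuplicated(years)) stop("duplicated years in table")
  if (length(age_lower) > 1) {
    steps <- diff(age_lower)
    if (any(steps <= 0)) stop("age-group lower bounds must be strictly increasing")
    if (length(unique(steps)) != 1)
      stop("mixed age-group widths (steps ", paste(unique(steps), collapse = ", "),
           ") are not supported")
    if (is.null(age_width)) age_width <- steps[1]
    if (age_width != steps[1])
      stop("age_width (", age_width, ") does not match spacing of lower bounds (",
           steps[1], ")")
  } else if (is.null(age_width)) age_width <- 1L
  age_width <- as.integer(age_width)

  bad <- which(!is.finite(incidence) | incidence < 0 |
                 abs(incidence - round(incidence)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("incidence must be non-negative integer; offending cell: year ",
         years[bad[1, 1]], ", age group ", age_lower[bad[1, 2]])
  bad <- which(!is.finite(population) | population <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("population must be strictly positive; offending cell: year ",
         years[bad[1, 1]], ", age group ", age_lower[bad[1, 2]])

  age_upper <- age_lower + age_width - 1L
  if (open_top) age_upper[length(age_upper)] <- Inf
  labels <- age_group_labels(age_lower, age_width, open_top)
  storage.mode(incidence) <- "double"
  incidence <- round(incidence)
  dimnames(incidence) <- dimnames(population) <- list(years, labels)
  structure(list(years = years, age_lower = age_lower,
                 age_width = age_width, age_upper = age_upper,
                 incidence = incidence, population = population, meta = meta),
            class = "registry_table")
}

age_group_labels <- function(age_lower, age_width, open_top = FALSE) {
  labels <- if (age_width == 1L) as.character(age_lower)
            else paste0(age_lower, "-", age_lower + age_width - 1L)
  if (open_top) labels[length(labels)] <- paste0(age_lower[length(labels)], "+")
  labels
}

#' @export
print.registry_table <- function(x, ...) {
  cat("registry_table: ", length(x$years), " years (", min(x$years), "-",
      max(x$years), "), ", length(x$age_lower), " age groups of width ",
      x$age_width, " (", colnames(x$incidence)[1], " .. ",
      colnames(x$incidence)[ncol(x$incidence)], ")\n", sep = "")
  cat("  total cases: ", sum(x$incidence), "; mean rate: ",
      signif(sum(x$incidence) / sum(x$population), 4), "\n", sep = "")
  invisible(x)
}

# Parse "20", "20-24" or "85+" style age-group headers by leading integer.
parse_age_labels <- function(labels) {
  labels <- trimws(sub("^X", "", labels))
  lower <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", labels)))
  if (anyNA(lower))
    stop("cannot parse age-group labels: ",
         paste(labels[is.na(lower)], collapse = ", "))
  list(lower = lower, open_top = grepl("\\+\\s*$", labels[length(labels)]))
}

#' Read a registry table from paired CSV files
#'
#' Each file is a rectangular CSV whose first column holds the calendar year
#' and whose remaining headers are age-group labels: a bare lower bound
#' (`"20"`), a range (`"20-24"`), or an open top group (`"85+"`). Rows may be
#' in any order; the returned table is normalized to ascending years.
#'
#' @param incidence_path Path to the incidence-count CSV.
#' @param population_path Path to the person-years CSV (same layout).
#' @param meta Optional metadata list attached to the table.
#' @return A validated [registry_table()].
#' @seealso [write_registry_csv()]
#' @export
read_registry_csv <- function(incidence_path, population_path, meta = list()) {
  read_one <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2) stop("file ", path, " needs a year column plus age columns")
    for (j in seq_len(ncol(df))) {
      if (!is.numeric(df[[j]]))
        stop("non-numeric cells in column '", names(df)[j], "' of ", path)
    }
    df
  }
  inc <- read_one(incidence_path)
  pop <- read_one(population_path)
  if (!identical(dim(inc), dim(pop)))
    stop("shape mismatch: incidence ", nrow(inc), "x", ncol(inc) - 1,
         " vs population ", nrow(pop), "x", ncol(pop) - 1)
  if (!identical(names(inc)[-1], names(pop)[-1]))
    stop("age-group headers differ between incidence and population files")
  oi <- order(inc[[1]]); op <- order(pop[[1]])
  if (!identical(as.integer(inc[[1]][oi]), as.integer(pop[[1]][op])))
    stop("year columns differ between incidence and population files")
  ages <- parse_age_labels(names(inc)[-1])
  registry_table(years = inc[[1]][oi], age_lower = ages$lower,
                 incidence = as.matrix(inc[oi, -1, drop = FALSE]),
                 population = as.matrix(pop[op, -1, drop = FALSE]),
                 open_top = ages$open_top, meta = meta)
}

#' Write a registry table to paired CSV files
#'
#' Inverse of [read_registry_csv()]: round-tripping reproduces the table
#' exactly for integer counts and decimal populations.
#'
#' @param t A [registry_table()].
#' @param incidence_path,population_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_registry_csv <- function(t, incidence_path, population_path) {
  stopifnot(inherits(t, "registry_table"))
  write_one <- function(m, path) {
    df <- data.frame(year = t$years, m, check.names = FALSE)
    names(df) <- c("year", colnames(t$incidence))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  write_one(t$incidence, incidence_path)
  write_one(t$population, population_path)
  invisible(c(incidence_path, population_path))
}

#' Restrict a registry table to an age range
#'
#' Keeps exactly those age-group columns whose full closed interval
#' `[lower, lower + width - 1]` lies inside `[min_age, max_age]`. The default
#' range 20-84 drops childhood ages and the open-ended 85+ group, the usual
#' restriction when registries with different top groups must stay comparable
#' and the APC grid needs a fixed age-group width.
#'
#' @param t A [registry_table()].
#' @param min_age,max_age Closed age bounds in years.
#' @return A `registry_table` with the surviving columns; years unchanged.
#' @export
filter_age_range <- function(t, min_age = 20, max_age = 84) {
  stopifnot(inherits(t, "registry_table"), min_age <= max_age)
  keep <- t$age_lower >= min_age & t$age_upper <= max_age
  if (!any(keep))
    stop("no age group lies fully inside [", min_age, ", ", max_age, "]")
  registry_table(t$years, t$age_lower[keep],
                 t$incidence[, keep, drop = FALSE],
                 t$population[, keep, drop = FALSE],
                 age_width = t$age_width, open_top = FALSE, meta = t$meta)
}

#' Slice a registry table to a span of years
#'
#' @param t A [registry_table()].
#' @param years Integer vector of consecutive years to keep.
#' @return A `registry_table` containing only those rows.
#' @export
filter_years <- function(t, years) {
  stopifnot(inherits(t, "registry_table"))
  keep <- t$years %in% years
  if (sum(keep) != length(years))
    stop("years ", paste(setdiff(years, t$years), collapse = ", "),
         " not present in table")
  registry_table(t$years[keep], t$age_lower,
                 t$incidence[keep, , drop = FALSE],
                 t$population[keep, , drop = FALSE],
                 age_width = t$age_width,
                 open_top = is.infinite(t$age_upper[length(t$age_upper)]),
                 meta = t$meta)
}

#' Crude incidence rates
#'
#' @param t A [registry_table()].
#' @return Matrix of elementwise rates `Y / N` (years x age groups).
#' @export
rates <- function(t) {
  stopifnot(inherits(t, "registry_table"))
  t$incidence / t$population
}

#' Lexis grid geometry
#'
#' Describes an age x period grid: `I` age groups, `J` periods and the grid
#' factor `M`, the ratio of age-group width to period width (5 for 5-year age
#' groups with yearly data, 1 for single ages). The number of distinct birth
#' cohorts the grid touches is `K = M * (I - 1) + J`.
#'
#' @param I Number of age groups (rows of the Lexis grid).
#' @param J Number of periods.
#' @param M Positive integer grid factor.
#' @return An object of class `lexis_spec` with elements `I`, `J`, `M`, `K`.
#' @export
lexis_spec <- function(I, J, M = 1L) {
  I <- as.integer(I); J <- as.integer(J); M <- as.integer(M)
  stopifnot(I >= 1, J >= 1, M >= 1)
  structure(list(I = I, J = J, M = M, K = M * (I - 1L) + J),
            class = "lexis_spec")
}

#' Lexis spec of a registry table
#'
#' Periods are assumed yearly, so the grid factor equals the age-group width.
#' @param t A [registry_table()].
#' @return A [lexis_spec()].
#' @export
table_lexis <- function(t) {
  stopifnot(inherits(t, "registry_table"))
  lexis_spec(I = length(t$age_lower), J = length(t$years), M = t$age_width)
}

#' Cohort index on a Lexis grid
#'
#' The birth cohort reached by age group `i` in period `j` is
#' `k = j + M * (I - i)`: the oldest age group observed in the first period
#' belongs to cohort 1, and `k` increases towards younger ages and later
#' periods up to `K = M * (I - 1) + J`.
#'
#' @param spec A [lexis_spec()].
#' @param i Age-group index (1-based, vectorized).
#' @param j Period index (1-based, vectorized).
#' @return Integer cohort index/indices in `1..K`.
#' @export
cohort_index <- function(spec, i, j) {
  stopifnot(inherits(spec, "lexis_spec"))
  i <- as.integer(i); j <- as.integer(j)
  if (any(i < 1L | i > spec$I)) stop("age index out of range 1..", spec$I)
  if (any(j < 1L | j > spec$J)) stop("period index out of range 1..", spec$J)
  j + spec$M * (spec$I - i)
}
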