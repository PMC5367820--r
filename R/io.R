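# Readers and writers for incidence / population CSV pairs in the layout of
# registry extracts: a cases file and a person-years file keyed by age (and
# optionally calendar year, pooled on read).

#' Column-map configuration for incidence CSV pairs
#'
#' Describes how to interpret a cases/population CSV pair: which columns
#' hold age, calendar year (optional; pooled when present), case counts and
#' person-years, the target age-group width, and how to treat the terminal
#' open-ended group.
#'
#' @param age column name for age (single year of age or group lower bound).
#' @param year optional column name for calendar year; when present, counts
#'   and person-years are summed over years within each age group.
#' @param cases column name for case counts in the cases file.
#' @param population column name for person-years in the population file.
#' @param age_width width of the target age groups in years (default 5).
#' @param max_age exclusive upper bound of the analysis ages (default 85).
#' @param terminal policy for ages at or above `max_age`: `"drop"` (default;
#'   an open-ended terminal group has no defensible midpoint) or `"cap"`
#'   (keep as one group `[max_age, max_age + age_width)`).
#' @return list of class `"column_map_config"`.
#' @export
column_map_config <- function(age = "age", year = NULL, cases = "cases",
                              population = "population", age_width = 5,
                              max_age = 85, terminal = c("drop", "cap")) {
  terminal <- match.arg(terminal)
  if (age_width <= 0) stop("age_width must be > 0")
  structure(list(age = age, year = year, cases = cases,
                 population = population, age_width = age_width,
                 max_age = max_age, terminal = terminal),
            class = "column_map_config")
}

#' Read a column-map configuration from a YAML file
#'
#' @param path path to a YAML file whose keys match the arguments of
#'   [column_map_config()].
#' @return a `"column_map_config"`.
#' @export
read_column_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(column_map_config, cfg)
}

.read_one <- function(path, config, value_col) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(config$age, config$year, value_col)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("columns missing from ", path, ": ", paste(miss, collapse = ", "))
  age <- suppressWarnings(as.numeric(df[[config$age]]))
  if (any(is.na(age)))
    stop("non-numeric age values in ", path)
  val <- df[[value_col]]
  grp <- floor(age / config$age_width) * config$age_width
  agg <- stats::aggregate(list(value = val), list(age_lo = grp), sum)
  agg[order(agg$age_lo), ]
}

#' Read an incidence table from a cases/population CSV pair
#'
#' Reads the two files, pools over calendar years when the configuration
#' names a year column, aggregates ages into `age_width`-year groups, joins
#' cases to person-years by age group, applies the terminal-group policy,
#' and validates the result as an [incidence_table()]. Dropped rows are
#' reported via `message()`.
#'
#' @param cases_path CSV of case counts.
#' @param population_path CSV of person-years.
#' @param config a [column_map_config()].
#' @return an [incidence_table()].
#' @export
read_incidence <- function(cases_path, population_path,
                           config = column_map_config()) {
  stopifnot(inherits(config, "column_map_config"))
  cs <- .read_one(cases_path, config, config$cases)
  py <- .read_one(population_path, config, config$population)
  if (!isTRUE(all.equal(cs$age_lo, py$age_lo)))
    stop("age groups differ between files; offenders: ",
         paste(union(setdiff(cs$age_lo, py$age_lo),
                     setdiff(py$age_lo, cs$age_lo)), collapse = ", "))
  if (any(abs(cs$value - round(cs$value)) > 1e-8))
    stop("non-integer case counts in ", cases_path)
  keep <- cs$age_lo < config$max_age
  n_drop <- sum(!keep)
  if (config$terminal == "drop" && n_drop > 0) {
    message("dropping ", n_drop, " terminal age group(s) at or above age ",
            config$max_age)
    cs <- cs[keep, ]; py <- py[keep, ]
  }
  incidence_table(cs$age_lo, cs$age_lo + config$age_width,
                  cases = cs$value, person_years = py$value)
}

#' Write an incidence table as a cases/population CSV pair
#'
#' Inverse of [read_incidence()] under the same configuration: the age
#' column holds the group lower bound.
#'
#' @param table an [incidence_table()].
#' @param cases_path,population_path output CSV paths.
#' @param config a [column_map_config()].
#' @return invisibly, the two paths.
#' @export
write_incidence <- function(table, cases_path, population_path,
                            config = column_map_config()) {
  stopifnot(inherits(table, "incidence_table"))
  cs <- data.frame(age = table$age_lo, cases = table$cases)
  py <- data.frame(age = table$age_lo, population = table$person_years)
  names(cs) <- c(config$age, config$cases)
  names(py) <- c(config$age, config$population)
  utils::write.csv(cs, cases_path, row.names = FALSE)
  utils::write.csv(py, population_path, row.names = FALSE)
  invisible(c(cases_path, population_path))
}

#' Serialize a fit result to JSON
#'
#' Writes the model id, fitted parameters, negative log-likelihood, AIC
#' (both parameter-count conventions), and convergence flag.
#'
#' @param fit an [fit_mle()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "msce_fit"))
  x <- list(model = fit$model$id, params = as.list(fit$params),
            nll = fit$nll, aic = fit$aic, aic_fitted = fit$aic_fitted,
            k = fit$k, k_structural = fit$k_structural,
            converged = fit$converged)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
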