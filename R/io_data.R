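#' @keywords internal
"_PACKAGE"

SURVEY_CLASSES <- c("calf", "adult_female", "adult_male")

#' Construct a survey matrix object
#'
#' A `survey_matrix` holds winter aerial-survey class counts for a run of
#' consecutive calendar years: calves, adult females and adult males
#' (\eqn{A = 3} classes). Counts are stored as reals because class counts
#' are typically derived from ratio estimates applied to a sightability-
#' corrected total and need not be integral. A year with no survey is kept
#' as an explicit all-`NA` row, never dropped, so that missing years
#' contribute nothing to the fit while keeping the year axis consecutive.
#'
#' @param years integer vector of consecutive calendar years.
#' @param counts numeric matrix, `length(years)` x 3, columns
#'   `calf`, `adult_female`, `adult_male`. `NA` rows mark missing surveys.
#' @param totals optional data.frame with columns `year`, `total`,
#'   `ci_low`, `ci_high` carrying the survey's own corrected totals.
#' @return an object of class `survey_matrix`.
#' @export
survey_matrix <- function(years, counts, totals = NULL) {
  years <- as.integer(years)
  counts <- as.matrix(counts)
  if (length(years) == 0L) stop("no survey records")
  if (anyDuplicated(years)) {
    stop("duplicate year in survey data: ", years[duplicated(years)][1])
  }
  o <- order(years)
  years <- years[o]
  counts <- counts[o, , drop = FALSE]
  if (length(years) > 1L) {
    gaps <- which(diff(years) != 1L)
    if (length(gaps)) {
      stop(sprintf("survey years not consecutive: gap between %d and %d",
                   years[gaps[1]], years[gaps[1] + 1L]))
    }
  }
  if (ncol(counts) != 3L) stop("survey counts must have exactly 3 classes")
  storage.mode(counts) <- "double"
  if (any(counts < 0, na.rm = TRUE)) stop("negative survey count")
  miss <- is.na(counts)
  if (any(miss) && !all(rowSums(miss) %in% c(0L, 3L))) {
    stop("a survey year must be fully observed or fully missing")
  }
  dimnames(counts) <- list(years, SURVEY_CLASSES)
  structure(list(years = years, counts = counts, totals = totals),
            class = "survey_matrix")
}

#' Read an aerial-survey class-count CSV
#'
#' Expects a UTF-8 CSV with header
#' `year,calf,adult_female,adult_male[,total,ci_low,ci_high]`. Rows are
#' normalized to ascending year; duplicate years, negative counts and
#' gaps in the year sequence are hard errors. Empty cells in the three
#' class columns mark a year with no survey (kept, flagged missing).
#'
#' @param path path to the CSV file.
#' @return a [survey_matrix()].
#' @export
read_survey <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no survey records")
  need <- c("year", SURVEY_CLASSES)
  if (!all(need %in% names(df))) {
    stop("survey CSV must have columns: ", paste(need, collapse = ", "))
  }
  totals <- NULL
  if (all(c("total", "ci_low", "ci_high") %in% names(df))) {
    totals <- df[order(df$year), c("year", "total", "ci_low", "ci_high")]
    rownames(totals) <- NULL
  }
  survey_matrix(df$year, as.matrix(df[, SURVEY_CLASSES]), totals = totals)
}

#' Write a survey matrix back to CSV
#'
#' Inverse of [read_survey()] up to column order and float formatting.
#'
#' @param sm a [survey_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(sm, path) {
  df <- data.frame(year = sm$years, sm$counts, row.names = NULL,
                   check.names = FALSE)
  if (!is.null(sm$totals)) {
    df <- merge(df, sm$totals, by = "year", all.x = TRUE, sort = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @export
print.survey_matrix <- function(x, ...) {
  cat(sprintf("Aerial survey class counts: %d-%d (%d years, %d missing)\n",
              min(x$years), max(x$years), length(x$years),
              sum(is.na(x$counts[, 1]))))
  print(x$counts)
  invisible(x)
}

#' Construct telemetry mortality counts
#'
#' Per-study annual counts of deaths `v` among `n` collared adults at
#' risk at the start of the year. Study labels are provenance only; use
#' [pool_telemetry()] before fitting. Years with no monitoring carry an
#' explicit `NA` record rather than being silently treated as `v = n = 0`.
#'
#' @param year,study,deaths,at_risk parallel vectors, one element per
#'   study-year record.
#' @return an object of class `telemetry_counts` (a data.frame).
#' @export
telemetry_counts <- function(year, study, deaths, at_risk) {
  df <- data.frame(year = as.integer(year), study = as.character(study),
                   deaths = as.numeric(deaths), at_risk = as.numeric(at_risk),
                   stringsAsFactors = FALSE)
  has <- !is.na(df$deaths) & !is.na(df$at_risk)
  if (any(df$deaths[has] < 0) || any(df$at_risk[has] < 0)) {
    stop("negative telemetry count")
  }
  bad <- has & df$deaths > df$at_risk
  if (any(bad)) {
    stop(sprintf("deaths exceed at-risk in %d (%s)",
                 df$year[bad][1], df$study[bad][1]))
  }
  class(df) <- c("telemetry_counts", "data.frame")
  df
}

#' Read a telemetry mortality CSV
#'
#' Expects a UTF-8 CSV with header `year,study,deaths,at_risk`; several
#' studies may share a year. Records are kept per study; pooling is done
#' by [pool_telemetry()].
#'
#' @param path path to the CSV file.
#' @return a [telemetry_counts()] object.
#' @export
read_telemetry <- function(path) {
  if (!file.exists(path)) stop("telemetry file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "study", "deaths", "at_risk")
  if (!all(need %in% names(df))) {
    stop("telemetry CSV must have columns: ", paste(need, collapse = ", "))
  }
  telemetry_counts(df$year, df$study, df$deaths, df$at_risk)
}

#' Pool telemetry counts across studies
#'
#' Sums deaths and at-risk counts over all studies within a year, the
#' pooling under which annual mortality enters the reconstruction
#' objective. The output spans every year from the first to the last
#' monitored year; years absent from all studies are marked no-data
#' (`NA` deaths and at-risk), never zero.
#'
#' @param tc a [telemetry_counts()] object.
#' @param years optional integer vector forcing the output year span
#'   (e.g. the survey years); defaults to the telemetry span.
#' @return a pooled `telemetry_counts` with one row per year and
#'   `study = "pooled"`.
#' @export
pool_telemetry <- function(tc, years = NULL) {
  obs <- tc[!is.na(tc$deaths) & !is.na(tc$at_risk), , drop = FALSE]
  if (is.null(years)) years <- seq(min(obs$year), max(obs$year))
  v <- tapply(obs$deaths, factor(obs$year, levels = years), sum)
  n <- tapply(obs$at_risk, factor(obs$year, levels = years), sum)
  telemetry_counts(years, "pooled", as.numeric(v), as.numeric(n))
}

#' Bundled northeastern Minnesota moose tables
#'
#' `moose_survey()` returns the 2005-2020 winter aerial-survey class
#' counts (with sightability-corrected totals and 90% CIs);
#' `moose_telemetry()` returns the per-study 2005-2019 telemetry
#' mortality records for collared adults. These are the study's inputs,
#' bundled so every analysis runs with no download.
#'
#' @return a [survey_matrix()] or [telemetry_counts()] object.
#' @export
moose_survey <- function() {
  read_survey(system.file("extdata", "survey_mn_2005_2020.csv",
                          package = "moosespr", mustWork = TRUE))
}

#' @rdname moose_survey
#' @export
moose_telemetry <- function() {
  read_telemetry(system.file("extdata", "telemetry_mn_2005_2019.csv",
                             package = "moosespr", mustWork = TRUE))
}
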