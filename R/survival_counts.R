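#' Annual adult survival from pooled death/at-risk counts
#'
#' The count-based estimator \eqn{\hat S_i = 1 - v_i / n_i}: the fraction
#' of collared adults at risk at the start of year \eqn{i} that survived
#' it. Its binomial standard error is \eqn{\sqrt{\hat S(1-\hat S)/n}},
#' undefined (reported `NA`) when no deaths or no survivors occurred —
#' with zero observed events the binomial variance estimate degenerates
#' and precludes an estimate of variation. Confidence intervals are
#' normal-approximation on the probability scale, clipped to [0, 1];
#' they are diagnostic only and never enter the reconstruction
#' objective.
#'
#' @param tc pooled [telemetry_counts()] (one record per year); years
#'   marked no-data propagate as `NA` estimates.
#' @param conf_levels confidence levels for the reported intervals.
#' @return a `data.frame` of class `survival_series` with columns
#'   `year, deaths, at_risk, estimate, se` and, per level,
#'   `ci<level>_low`/`ci<level>_high`.
#' @export
annual_survival <- function(tc, conf_levels = c(0.90, 0.95)) {
  if (any(tc$study != "pooled", na.rm = TRUE)) tc <- pool_telemetry(tc)
  v <- tc$deaths
  n <- tc$at_risk
  est <- 1 - v / n
  se <- sqrt(est * (1 - est) / n)
  se[!is.na(v) & (v == 0 | v == n)] <- NA_real_
  out <- data.frame(year = tc$year, deaths = v, at_risk = n,
                    estimate = est, se = se)
  for (lev in conf_levels) {
    z <- stats::qnorm(1 - (1 - lev) / 2)
    tag <- sprintf("ci%d", round(lev * 100))
    out[[paste0(tag, "_low")]] <- pmax(0, est - z * se)
    out[[paste0(tag, "_high")]] <- pmin(1, est + z * se)
  }
  class(out) <- c("survival_series", "data.frame")
  out
}

#' Write a survival series as tidy CSV
#'
#' @param ss a `survival_series` from [annual_survival()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival <- function(ss, path) {
  utils::write.csv(ss, path, row.names = FALSE, na = "")
  invisible(path)
}
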