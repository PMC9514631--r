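# Vital-rate forecasting and stochastic cohort projection.
#
# Survival is forecast on the logit scale and per-capita recruitment on
# the log scale, so every draw back-transforms into (0, 1) and (0, Inf)
# respectively. The forecast model is AR(1) with drift fitted by least
# squares; a degenerate fit (zero variance, explosive or inestimable
# slope) falls back to a random walk with drift, using the historical
# innovation SD.

#' Forecast a vital-rate series
#'
#' Fits x_t = a + b x_(t-1) + e on the transformed scale and returns
#' h-step-ahead means and prediction standard deviations:
#' mean_h = a(1 + b + ... + b^(h-1)) + b^h x_m and
#' var_h = sigma^2 (1 + b^2 + ... + b^(2(h-1))).
#'
#' @param values historical rates (at least 5 non-missing values).
#' @param years calendar years of `values`.
#' @param horizon number of years ahead to forecast.
#' @param scale `"logit"` (survival) or `"log"` (recruitment).
#' @return list of class `rate_forecast`: future `years`, `mean` (back-
#'   transformed point forecast), `mean_t`/`sd_t` on the transformed
#'   scale, the `scale`, and fitted coefficients.
#' @export
forecast_rates <- function(values, years, horizon,
                           scale = c("logit", "log")) {
  scale <- match.arg(scale)
  keep <- !is.na(values)
  values <- values[keep]
  years <- years[keep]
  if (length(values) < 5L) stop("need at least 5 historical values")
  fwd <- switch(scale, logit = stats::qlogis, log = log)
  bwd <- switch(scale, logit = stats::plogis, log = exp)
  eps <- 1e-9
  x <- if (scale == "logit") fwd(pmin(pmax(values, eps), 1 - eps)) else {
    fwd(pmax(values, eps))
  }
  m <- length(x)
  degenerate <- stats::var(x) < 1e-12
  a <- b <- sigma <- NA_real_
  if (!degenerate) {
    fit <- stats::lm(x[-1] ~ x[-m])
    b <- unname(stats::coef(fit)[2])
    a <- unname(stats::coef(fit)[1])
    sigma <- sqrt(sum(stats::residuals(fit)^2) / max(1, m - 3))
    if (!is.finite(b) || abs(b) >= 1) degenerate <- TRUE
  }
  h <- seq_len(horizon)
  if (degenerate) {
    # slope exactly 1 (pure trend) or inestimable: random walk with
    # drift, innovation SD from the historical differences
    model <- "rw_drift"
    d <- diff(x)
    drift <- if (length(d)) mean(d) else 0
    innov <- if (length(d) > 1) stats::sd(d) else 0
    mean_t <- x[m] + h * drift
    sd_t <- innov * sqrt(h)
  } else {
    model <- "ar1_drift"
    mean_t <- a * cumsum(b^(h - 1)) + b^h * x[m]
    sd_t <- sigma * sqrt(cumsum(b^(2 * (h - 1))))
  }
  structure(list(years = years[length(years)] + h,
                 mean = bwd(mean_t), mean_t = mean_t, sd_t = sd_t,
                 scale = scale, model = model,
                 coef = c(a = a, b = b, sigma = sigma)),
            class = "rate_forecast")
}

#' Stochastic cohort projection from a starting state
#'
#' Projects calves, adult females and adult males forward one year at a
#' time: per simulation and year, annual survival S_t and per-capita
#' recruitment R_t are drawn from their forecast distributions on the
#' transformed scales (independent across years), next-winter calves
#' are R_t x females_t, and adults follow [project_adults()]. Only
#' parameter (environmental) stochasticity enters by default;
#' `demographic = TRUE` additionally draws binomial adult survivors and
#' Poisson calves for synthetic studies.
#'
#' @param start named length-3 vector: starting winter abundances
#'   (calf, adult_female, adult_male).
#' @param start_year the calendar year of `start`.
#' @param rf_surv,rf_rec [forecast_rates()] objects covering the horizon
#'   (logit and log scale respectively).
#' @param horizon years to project (defaults to the forecast length).
#' @param n_sims number of simulations.
#' @param seed RNG seed; identical seeds reproduce bit-identically.
#' @param demographic add demographic (binomial/Poisson) noise.
#' @return list of class `projection_result`: `years` (start year and
#'   horizon), `trajectories` (n_sims x years x classes array),
#'   `summary` data.frame (per year: class and total medians with 90%
#'   envelopes), `lambda` (per-trajectory annual growth summary),
#'   `n_sims`, `seed`.
#' @export
stochastic_project <- function(start, start_year, rf_surv, rf_rec,
                               horizon = length(rf_surv$years),
                               n_sims = 1000, seed = 1,
                               demographic = FALSE) {
  stopifnot(n_sims >= 1, horizon >= 1,
            length(rf_surv$mean_t) >= horizon,
            length(rf_rec$mean_t) >= horizon)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  S <- stats::plogis(matrix(stats::rnorm(n_sims * horizon,
                                         rep(rf_surv$mean_t[1:horizon],
                                             each = n_sims),
                                         rep(rf_surv$sd_t[1:horizon],
                                             each = n_sims)),
                            n_sims, horizon))
  R <- exp(matrix(stats::rnorm(n_sims * horizon,
                               rep(rf_rec$mean_t[1:horizon], each = n_sims),
                               rep(rf_rec$sd_t[1:horizon], each = n_sims)),
                  n_sims, horizon))
  years <- start_year + 0:horizon
  traj <- array(NA_real_, c(n_sims, horizon + 1L, 3L),
                dimnames = list(NULL, years, SURVEY_CLASSES))
  traj[, 1, ] <- matrix(start, n_sims, 3, byrow = TRUE)
  for (t in seq_len(horizon)) {
    cal <- traj[, t, 1]; fem <- traj[, t, 2]; mal <- traj[, t, 3]
    if (demographic) {
      nf <- round(cal * 0.5 + fem)
      nm <- round(cal * 0.5 + mal)
      traj[, t + 1, 2] <- stats::rbinom(n_sims, nf, S[, t])
      traj[, t + 1, 3] <- stats::rbinom(n_sims, nm, S[, t])
      traj[, t + 1, 1] <- stats::rpois(n_sims, R[, t] * fem)
    } else {
      traj[, t + 1, 2] <- project_adults(cal, fem, S[, t])
      traj[, t + 1, 3] <- project_adults(cal, mal, S[, t])
      traj[, t + 1, 1] <- R[, t] * fem
    }
  }
  totals <- apply(traj, c(1, 2), sum)
  qs <- function(m) apply(m, 2, stats::quantile,
                          probs = c(0.05, 0.5, 0.95), names = FALSE)
  smry <- do.call(rbind, lapply(c(SURVEY_CLASSES, "total"), function(cl) {
    m <- if (cl == "total") totals else traj[, , cl, drop = TRUE]
    if (n_sims == 1L) m <- matrix(m, nrow = 1)
    q <- qs(m)
    data.frame(year = years, class = cl, median = q[2, ],
               ci90_low = q[1, ], ci90_high = q[3, ])
  }))
  rownames(smry) <- NULL
  res <- structure(list(years = years, trajectories = traj,
                        summary = smry, n_sims = n_sims, seed = seed,
                        horizon = horizon),
                   class = "projection_result")
  res$lambda <- growth_rate(res)
  res
}

#' Annual growth rate over a projection
#'
#' Per trajectory, the geometric-mean annual growth
#' lambda = (N_total(end) / N_total(start))^(1/horizon), summarized
#' across simulations by the median and empirical 90% interval.
#'
#' @param result a `projection_result`.
#' @return list: `per_sim`, `median`, `ci90_low`, `ci90_high`.
#' @export
growth_rate <- function(result) {
  totals <- apply(result$trajectories, c(1, 2), sum)
  if (result$n_sims == 1L) totals <- matrix(totals, nrow = 1)
  lam <- (totals[, ncol(totals)] / totals[, 1])^(1 / result$horizon)
  q <- stats::quantile(lam, c(0.05, 0.5, 0.95), names = FALSE)
  list(per_sim = lam, median = q[2], ci90_low = q[1], ci90_high = q[3])
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Stochastic projection %d-%d, %d simulations (seed %d)\n",
              min(x$years), max(x$years), x$n_sims, x$seed))
  cat(sprintf("  lambda median %.3f (90%% envelope %.3f-%.3f)\n",
              x$lambda$median, x$lambda$ci90_low, x$lambda$ci90_high))
  print(x$summary[x$summary$class == "total", ], digits = 4, row.names = FALSE)
  invisible(x)
}
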