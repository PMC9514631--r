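# Inverse-Hessian standard errors with goodness-of-fit variance
# inflation. The Hessian of half the chi-square objective is used so the
# objective behaves like -2 log-likelihood and a quadratic objective
# (x - a)^2 / s returns SE = sqrt(s) exactly.

#' Inverse-Hessian standard errors at the reconstruction optimum
#'
#' Numerically differentiates half the composed objective
#' (survey + telemetry chi-square) twice with respect to the natural
#' parameters at the fitted point and takes square roots of the inverse
#' Hessian's diagonal. Parameters pinned at a box bound have no interior
#' curvature to exploit: they are flagged and their SE reported missing.
#' A non-positive-definite Hessian triggers a warning and a
#' pseudo-inverse fallback, with affected parameters flagged.
#'
#' @param recon a fitted `moose_reconstruction`.
#' @return list of class `uncertainty_report`: `parameter` names,
#'   `estimate`, `se_raw`, `cov` (raw covariance), `boundary` and
#'   `ill_conditioned` flags. [inflate()] adds the scale factor.
#' @export
hessian_se <- function(recon) {
  survey <- recon$survey
  tc <- recon$telemetry
  years <- recon$theta$years
  x_hat <- theta_flatten(recon$theta)
  half_obj <- function(x) {
    th <- theta_unflatten(x, years)
    0.5 * (joint_objective(th, survey) +
             if (is.null(tc)) 0 else telemetry_objective(th, tc))
  }
  H <- pracma::hessian(half_obj, x_hat)
  H <- (H + t(H)) / 2

  cfg <- recon$cfg
  ns <- length(years) - 1L
  tol <- 1e-6
  boundary <- c(
    x_hat[seq_len(ns)] <= cfg$surv_bounds[1] + tol |
      x_hat[seq_len(ns)] >= cfg$surv_bounds[2] - tol,
    x_hat[-seq_len(ns)] <= cfg$abund_bounds[1] + tol |
      x_hat[-seq_len(ns)] >= cfg$abund_bounds[2] * (1 - tol))

  V <- try(solve(H), silent = TRUE)
  ill <- rep(FALSE, length(x_hat))
  if (inherits(V, "try-error") || any(diag(V) < 0)) {
    warning("Hessian not positive definite; using pseudo-inverse")
    V <- pracma::pinv(H)
    ill <- diag(V) < 0
  }
  se <- sqrt(pmax(diag(V), 0))
  se[boundary | ill] <- NA_real_
  nm <- c(paste0("S_", years[-length(years)]),
          paste0("N1_", SURVEY_CLASSES),
          paste0("R_", years[-1]))
  structure(list(parameter = nm, estimate = unname(x_hat),
                 se_raw = unname(se), cov = V,
                 boundary = boundary, ill_conditioned = ill,
                 inflation_factor = NA_real_, df = NA_integer_,
                 K = length(x_hat), se_inflated = NULL),
            class = "uncertainty_report")
}

#' Goodness-of-fit variance inflation
#'
#' Reconstruction models tend to understate uncertainty, so variances
#' are scaled by the goodness-of-fit factor \eqn{c = \chi^2_{df} / df},
#' where the chi-square statistic is taken over the observed survey
#' cells only and \eqn{df = A \times Y - K} with K the number of free
#' parameters. SEs are multiplied by `sqrt(max(1, c))`: the factor is
#' floored at one, since deflating would defeat its purpose as a guard
#' (a message is emitted when c < 1).
#'
#' @param report an `uncertainty_report` from [hessian_se()].
#' @param recon the fitted `moose_reconstruction`.
#' @return the report with `inflation_factor`, `df` and `se_inflated`
#'   filled in.
#' @export
inflate <- function(report, recon) {
  a <- recon$survey$counts
  Y <- nrow(a)
  df <- 3L * Y - report$K
  if (df <= 0) stop("non-positive degrees of freedom")
  chi2 <- joint_objective(recon$theta, recon$survey)
  c_hat <- chi2 / df
  if (c_hat < 1) message(sprintf("inflation factor %.3f < 1; floored", c_hat))
  report$inflation_factor <- c_hat
  report$df <- df
  report$se_inflated <- report$se_raw * sqrt(max(1, c_hat))
  report
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("Uncertainty report: K = %d, df = %s, inflation c = %s\n",
              x$K, x$df,
              if (is.na(x$inflation_factor)) "(not set)"
              else sprintf("%.3f", x$inflation_factor)))
  df <- data.frame(parameter = x$parameter, estimate = x$estimate,
                   se_raw = x$se_raw)
  if (!is.null(x$se_inflated)) df$se_inflated <- x$se_inflated
  print(df, digits = 4)
  invisible(x)
}

#' Delta-method intervals for derived quantities
#'
#' Propagates the (inflated) parameter covariance through the projection
#' recursion to annual totals \eqn{N_{i\cdot}} and per-capita
#' recruitment \eqn{R_i}, via a numerical Jacobian, and forms normal
#' confidence intervals floored at zero.
#'
#' @param recon the fitted `moose_reconstruction`.
#' @param report an inflated `uncertainty_report` (see [inflate()]).
#' @param alpha interval tail mass (0.10 gives 90% intervals).
#' @return data.frame: `quantity`, `year`, `estimate`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
derived_ci <- function(recon, report, alpha = 0.10) {
  years <- recon$theta$years
  Y <- length(years)
  derive <- function(x) {
    N <- build_expected(theta_unflatten(x, years))
    c(rowSums(N), N[-1, 1] / N[-Y, 2])
  }
  x_hat <- theta_flatten(recon$theta)
  J <- pracma::jacobian(derive, x_hat)
  V <- report$cov * max(1, report$inflation_factor, na.rm = TRUE)
  var_q <- pmax(rowSums((J %*% V) * J), 0)
  se <- sqrt(var_q)
  est <- derive(x_hat)
  z <- stats::qnorm(1 - alpha / 2)
  data.frame(
    quantity = rep(c("total", "per_capita_recruitment"), c(Y, Y - 1L)),
    year = c(years, years[-Y]),
    estimate = est, se = se,
    ci_low = pmax(0, est - z * se),
    ci_high = est + z * se,
    row.names = NULL)
}
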