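# Cohort projection model and minimum chi-square reconstruction.
#
# The population is tracked in A = 3 winter classes (calves, adult
# females, adult males) over Y consecutive years. Free parameters are
# annual adult survival S_i (i = 1..Y-1), the three year-1 cohort
# abundances, and the calf cohort ("recruitment") entering each later
# winter. All other adult cells follow deterministically from the
# invariance recursion, so the optimizer never free-fits them.

#' Construct a parameter vector for the reconstruction model
#'
#' @param years the Y consecutive calendar years covered.
#' @param survival numeric length Y-1, annual survival \eqn{S_i} in
#'   (0, 1) for the transition out of each of the first Y-1 years.
#' @param initial numeric length 3, year-1 cohort abundances
#'   (calves, adult females, adult males), all > 0.
#' @param recruitment numeric length Y-1, calf cohort entering winters
#'   2..Y, all > 0.
#' @return an object of class `param_vector`.
#' @export
param_vector <- function(years, survival, initial, recruitment) {
  years <- as.integer(years)
  Y <- length(years)
  stopifnot(Y >= 2, length(survival) == Y - 1, length(initial) == 3,
            length(recruitment) == Y - 1)
  if (any(!is.finite(c(survival, initial, recruitment)))) {
    stop("non-finite parameter value")
  }
  if (any(survival <= 0 | survival >= 1)) stop("survival outside (0, 1)")
  if (any(c(initial, recruitment) <= 0)) stop("abundance parameter <= 0")
  structure(list(years = years,
                 survival = stats::setNames(survival, years[-Y]),
                 initial = stats::setNames(initial, SURVEY_CLASSES),
                 recruitment = stats::setNames(recruitment, years[-1])),
            class = "param_vector")
}

#' @export
length.param_vector <- function(x) 2L * (length(x$years) - 1L) + 3L

# flat <-> structured; order: survival, initial, recruitment
theta_flatten <- function(theta) {
  c(theta$survival, theta$initial, theta$recruitment)
}

theta_unflatten <- function(x, years) {
  Y <- length(years)
  param_vector(years, x[seq_len(Y - 1)], x[Y - 1 + 1:3],
               x[(Y + 2) + seq_len(Y - 1)])
}

#' One step of the adult-cohort invariance recursion
#'
#' Adults of one sex next winter are the survivors of this winter's
#' like-sexed adults plus half of this winter's calves (the 0.5 is the
#' fixed sex ratio at birth): `(prev_calves * 0.5 + prev_adults) * s`.
#'
#' @param prev_calves,prev_adults current-winter abundances (>= 0).
#' @param s annual survival in [0, 1].
#' @return next-winter adult abundance for that sex.
#' @export
project_adults <- function(prev_calves, prev_adults, s) {
  if (any(s < 0 | s > 1)) stop("survival outside [0, 1]")
  (prev_calves * 0.5 + prev_adults) * s
}

#' Expected abundance matrix under a parameter vector
#'
#' Deterministically expands the free parameters into the full Y x 3
#' abundance matrix: row 1 is the initial cohorts, later calf cells are
#' the recruitment parameters, and later adult cells are obtained by
#' chaining [project_adults()] forward (the invariance property).
#'
#' @param theta a [param_vector()].
#' @return numeric matrix, years x classes.
#' @export
build_expected <- function(theta) {
  Y <- length(theta$years)
  N <- matrix(NA_real_, Y, 3, dimnames = list(theta$years, SURVEY_CLASSES))
  N[1, ] <- theta$initial
  s <- theta$survival
  r <- theta$recruitment
  for (i in 2:Y) {
    N[i, 1] <- r[i - 1]
    N[i, 2] <- (N[i - 1, 1] * 0.5 + N[i - 1, 2]) * s[i - 1]
    N[i, 3] <- (N[i - 1, 1] * 0.5 + N[i - 1, 3]) * s[i - 1]
  }
  N
}

#' Pearson chi-square contribution of one survey cell
#'
#' `(observed - expected)^2 / expected`, with the denominator floored at
#' 1e-8 as a numeric guard (the optimizer's bounds keep expected cells
#' well above the floor).
#'
#' @param observed,expected cell counts.
#' @return the cell's chi-square contribution.
#' @export
cell_chisq <- function(observed, expected) {
  expected <- pmax(expected, 1e-8)
  if (any(expected <= 0)) stop("non-positive expected cell")
  (observed - expected)^2 / expected
}

#' Joint survey objective
#'
#' Sum of [cell_chisq()] over every observed survey cell, including
#' year-1 and calf cells (both carry free parameters, anchoring the fit
#' to the survey). Missing survey years contribute zero.
#'
#' @param theta a [param_vector()] or an expected matrix from
#'   [build_expected()].
#' @param survey a [survey_matrix()] whose years match `theta$years`.
#' @return the joint chi-square.
#' @export
joint_objective <- function(theta, survey) {
  N <- if (is.matrix(theta)) theta else build_expected(theta)
  a <- survey$counts
  if (!identical(dim(a), dim(N))) stop("survey/parameter dimension mismatch")
  obs <- !is.na(a)
  sum(cell_chisq(a[obs], N[obs]))
}

#' Telemetry mortality objective
#'
#' Compares observed collar deaths to those expected under the survival
#' parameters: \eqn{\sum_i (v_i - n_i(1-S_i))^2 / (n_i(1-S_i))}, summed
#' over years with telemetry; no-data years contribute zero. Bounds on
#' \eqn{S_i} keep the denominator positive.
#'
#' @param theta a [param_vector()].
#' @param tc pooled [telemetry_counts()].
#' @return the telemetry chi-square.
#' @export
telemetry_objective <- function(theta, tc) {
  idx <- match(tc$year, as.integer(names(theta$survival)))
  keep <- !is.na(idx) & !is.na(tc$deaths)
  if (!any(keep)) return(0)
  s <- theta$survival[idx[keep]]
  e <- tc$at_risk[keep] * (1 - s)
  sum((tc$deaths[keep] - e)^2 / e)
}

#' Fit configuration
#'
#' @param surv_bounds,abund_bounds box bounds on survival and abundance
#'   parameters. Survival is kept off 1 so telemetry denominators stay
#'   positive; abundance off 0 so Pearson denominators do.
#' @param restarts extra optimizer starts beyond the deterministic one.
#' @param jitter_sd sd of multiplicative log-normal jitter on restarts.
#' @param seed RNG seed for restart jitter.
#' @param maxit,pgtol,factr L-BFGS-B controls.
#' @param default_survival starting survival where telemetry is absent.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(surv_bounds = c(0.01, 0.999),
                       abund_bounds = c(1, 50000),
                       restarts = 10, jitter_sd = 0.2, seed = 20220927,
                       maxit = 10000, pgtol = 1e-8, factr = 1e4,
                       default_survival = 0.85) {
  structure(list(surv_bounds = surv_bounds, abund_bounds = abund_bounds,
                 restarts = restarts, jitter_sd = jitter_sd, seed = seed,
                 maxit = maxit, pgtol = pgtol, factr = factr,
                 default_survival = default_survival),
            class = "fit_config")
}

#' Read a fit configuration from YAML
#'
#' @param path YAML file whose keys match the [fit_config()] arguments.
#' @return a `fit_config`.
#' @export
read_fit_config <- function(path) {
  do.call(fit_config, yaml::read_yaml(path))
}

# transform between natural and optimizer scales: survival through a
# generalized logit onto its box, abundances through log.
transform_pack <- function(cfg, Y) {
  ns <- Y - 1L
  sb <- cfg$surv_bounds
  ab <- log(cfg$abund_bounds)
  list(
    to_z = function(x) {
      p <- (x[seq_len(ns)] - sb[1]) / diff(sb)
      c(stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12)),
        log(x[-seq_len(ns)]))
    },
    to_theta = function(z) {
      c(sb[1] + diff(sb) * stats::plogis(z[seq_len(ns)]),
        exp(z[-seq_len(ns)]))
    },
    lower = c(rep(-30, ns), rep(ab[1], ns + 3L)),
    upper = c(rep(30, ns), rep(ab[2], ns + 3L))
  )
}

initial_theta <- function(survey, tc, cfg) {
  years <- survey$years
  Y <- length(years)
  s0 <- rep(cfg$default_survival, Y - 1)
  idx <- match(tc$year, years[-Y])
  keep <- !is.na(idx) & !is.na(tc$deaths)
  s0[idx[keep]] <- 1 - tc$deaths[keep] / tc$at_risk[keep]
  s0 <- pmin(pmax(s0, cfg$surv_bounds[1] + 0.01), cfg$surv_bounds[2] - 0.01)
  cl <- function(x) pmin(pmax(x, cfg$abund_bounds[1]), cfg$abund_bounds[2])
  counts <- survey$counts
  # fall back to column medians for missing survey cells
  med <- apply(counts, 2, stats::median, na.rm = TRUE)
  for (j in 1:3) counts[is.na(counts[, j]), j] <- med[j]
  param_vector(years, s0, cl(counts[1, ]), cl(counts[-1, 1]))
}

#' Minimum chi-square population reconstruction
#'
#' Minimizes `joint_objective + telemetry_objective` over the free
#' parameters with box bounds, via L-BFGS-B on a transformed scale
#' (generalized-logit survival, log abundances) so the box becomes
#' simple and gradients well scaled. The deterministic start takes
#' survival from pooled telemetry (1 - v/n, else 0.85) and abundances
#' from the survey cells; `cfg$restarts` further starts jitter that
#' point log-normally under a fixed seed, and the best objective wins.
#'
#' @param survey a [survey_matrix()].
#' @param tc [telemetry_counts()]; pooled automatically. May be `NULL`
#'   to fit on survey data alone.
#' @param cfg a [fit_config()].
#' @return an object of class `moose_reconstruction`: the fitted
#'   `theta` ([param_vector()]), `abundance` matrix, per-year `total`,
#'   `objective_value`, `converged`, `gradient_norm`, `n_restarts_used`,
#'   plus the inputs for downstream stages.
#' @export
fit_reconstruction <- function(survey, tc = NULL, cfg = fit_config()) {
  if (length(survey$years) < 2L) stop("need at least 2 survey years")
  if (!is.null(tc) && any(tc$study != "pooled", na.rm = TRUE)) {
    tc <- pool_telemetry(tc)
  }
  years <- survey$years
  Y <- length(years)
  tr <- transform_pack(cfg, Y)

  # fast objective on the flat natural vector: same arithmetic as
  # build_expected/joint_objective/telemetry_objective, without the S3
  # construction, since the optimizer calls it tens of thousands of times
  ns <- Y - 1L
  a <- survey$counts
  obs_mask <- !is.na(a)
  if (!is.null(tc)) {
    t_idx <- match(tc$year, years[-Y])
    t_keep <- !is.na(t_idx) & !is.na(tc$deaths)
    t_idx <- t_idx[t_keep]
    t_v <- tc$deaths[t_keep]
    t_n <- tc$at_risk[t_keep]
  }
  obj_flat <- function(x) {
    s <- x[seq_len(ns)]
    N <- matrix(NA_real_, Y, 3)
    N[1, ] <- x[ns + 1:3]
    N[-1, 1] <- x[ns + 3L + seq_len(ns)]
    for (i in 2:Y) {
      half <- N[i - 1, 1] * 0.5
      N[i, 2] <- (half + N[i - 1, 2]) * s[i - 1]
      N[i, 3] <- (half + N[i - 1, 3]) * s[i - 1]
    }
    val <- sum((a[obs_mask] - N[obs_mask])^2 / pmax(N[obs_mask], 1e-8))
    if (!is.null(tc)) {
      e <- t_n * (1 - s[t_idx])
      val <- val + sum((t_v - e)^2 / e)
    }
    val
  }
  obj_z <- function(z) obj_flat(tr$to_theta(z))

  x0 <- theta_flatten(initial_theta(survey, tc, cfg))
  starts <- list(x0)
  if (cfg$restarts > 0) {
    old <- .Random.seed_save()
    set.seed(cfg$seed)
    for (k in seq_len(cfg$restarts)) {
      xk <- x0 * exp(stats::rnorm(length(x0), 0, cfg$jitter_sd))
      ns <- Y - 1L
      xk[seq_len(ns)] <- pmin(pmax(xk[seq_len(ns)],
                                   cfg$surv_bounds[1] + 1e-3),
                              cfg$surv_bounds[2] - 1e-3)
      xk[-seq_len(ns)] <- pmin(pmax(xk[-seq_len(ns)],
                                    cfg$abund_bounds[1]),
                               cfg$abund_bounds[2])
      starts[[k + 1L]] <- xk
    }
    .Random.seed_restore(old)
  }

  best <- NULL
  n_used <- 0L
  for (st in starts) {
    n_used <- n_used + 1L
    fit <- try(stats::optim(tr$to_z(st), obj_z, method = "L-BFGS-B",
                            lower = tr$lower, upper = tr$upper,
                            control = list(maxit = cfg$maxit,
                                           pgtol = cfg$pgtol,
                                           factr = cfg$factr)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")

  g <- numeric_gradient(obj_z, best$par)
  # projected gradient: zero out components pushing into an active bound
  act_lo <- best$par <= tr$lower + 1e-9 & g > 0
  act_hi <- best$par >= tr$upper - 1e-9 & g < 0
  g[act_lo | act_hi] <- 0
  gnorm <- max(abs(g))
  # L-BFGS-B may abort its line search at machine precision (code 52);
  # a tiny projected gradient on the transformed scale is convergence
  converged <- best$convergence == 0 || gnorm < 1e-3
  theta_hat <- theta_unflatten(tr$to_theta(best$par), years)
  if (!converged) {
    warning(sprintf("reconstruction did not converge (grad norm %.3g)",
                    gnorm))
  }
  N <- build_expected(theta_hat)
  structure(list(theta = theta_hat, abundance = N,
                 total = rowSums(N), objective_value = best$value,
                 converged = converged, gradient_norm = gnorm,
                 n_restarts_used = n_used - 1L,
                 survey = survey, telemetry = tc, cfg = cfg),
            class = "moose_reconstruction")
}

# central-difference gradient on the optimizer scale; central so the
# curvature term cancels and the norm is honest at a near-exact optimum
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' @export
print.moose_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("Population reconstruction, %d-%d\n",
                     "  objective %.4f, converged: %s, restarts used: %d\n"),
              min(x$theta$years), max(x$theta$years),
              x$objective_value, x$converged, x$n_restarts_used))
  print(round(cbind(x$abundance, total = x$total), 1))
  invisible(x)
}

#' Per-capita recruitment from a fitted reconstruction
#'
#' Calves entering next winter per adult female alive this winter:
#' \eqn{R_i = N_{i+1,1} / N_{i,2}} for the first Y-1 years. The series
#' therefore ends one year before the abundance series.
#'
#' @param recon a `moose_reconstruction` (or an expected matrix).
#' @return data.frame with columns `year`, `recruitment`.
#' @export
per_capita_recruitment <- function(recon) {
  N <- if (is.matrix(recon)) recon else recon$abundance
  Y <- nrow(N)
  fem <- N[-Y, 2]
  R <- ifelse(fem > 0, N[-1, 1] / fem, NA_real_)
  data.frame(year = as.integer(rownames(N))[-Y], recruitment = unname(R))
}
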