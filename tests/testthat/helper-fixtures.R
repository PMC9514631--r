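# Shared fixtures, memoized so expensive fits run once per suite.

.moose_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .moose_cache)) {
    assign(key, force(expr), envir = .moose_cache)
  }
  get(key, envir = .moose_cache)
}

# full fit on the bundled study tables, with restart timing recorded
study_fit <- function() {
  memo("study_fit", {
    t0 <- Sys.time()
    fit <- fit_reconstruction(moose_survey(), moose_telemetry(),
                              fit_config())
    attr(fit, "elapsed_s") <- as.numeric(Sys.time() - t0, units = "secs")
    fit
  })
}

study_report <- function() {
  memo("study_report", inflate(hessian_se(study_fit()), study_fit()))
}

# a small noise-free 4-year instance with known truth
toy_truth <- function(years = 2001:2004) {
  param_vector(years,
               survival = c(0.85, 0.75, 0.80),
               initial = c(400, 900, 800),
               recruitment = c(350, 300, 280))
}

toy_perfect_survey <- function() {
  survey_matrix(2001:2004, build_expected(toy_truth()))
}

# recovery study shared by the survival-error and CI-coverage checks:
# 100 replicates of the decline scenario at survey CV 10% and 50
# collared adults per year, each refit from its own data
recovery_study <- function(n_rep = 100) {
  memo("recovery_study", {
    truth <- decline_scenario(survey_cv = 0.10, telemetry_n = 50)
    true_s <- truth$theta$survival
    true_tot <- rowSums(build_expected(truth$theta))
    cfg <- fit_config(restarts = 0)
    s_err <- c()
    covered <- c()
    for (r in seq_len(n_rep)) {
      d <- generate_dataset(truth, seed = 1000 + r)
      fit <- fit_reconstruction(d$survey, d$telemetry, cfg)
      s_err <- c(s_err, abs(fit$theta$survival - true_s))
      rep_r <- inflate(hessian_se(fit), fit)
      ci <- derived_ci(fit, rep_r, alpha = 0.10)
      tot <- ci[ci$quantity == "total", ]
      covered <- c(covered,
                   tot$ci_low <= true_tot & true_tot <= tot$ci_high)
    }
    list(s_err = s_err, covered = covered, n_rep = n_rep)
  })
}

# study projection shared by forecast and acceptance tests
study_projection <- function(n_sims = 1000, seed = 42) {
  key <- sprintf("proj_%d_%d", n_sims, seed)
  memo(key, {
    fit <- study_fit()
    yrs <- fit$theta$years
    rf_s <- forecast_rates(fit$theta$survival, yrs[-length(yrs)],
                           10, "logit")
    r <- per_capita_recruitment(fit)
    rf_r <- forecast_rates(r$recruitment, r$year, 10, "log")
    stochastic_project(fit$abundance[nrow(fit$abundance), ], max(yrs),
                       rf_s, rf_r, n_sims = n_sims, seed = seed)
  })
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
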