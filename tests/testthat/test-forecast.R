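test_that("a constant series forecasts itself", {
  rf <- forecast_rates(rep(0.85, 8), 2001:2008, horizon = 10,
                       scale = "logit")
  expect_equal(rf$mean, rep(0.85, 10))
  expect_true(all(diff(rf$sd_t) >= 0))
  expect_identical(rf$years, 2009:2018)
})

test_that("a pure trend on the transformed scale recovers its drift", {
  drift <- -0.07
  x <- seq(-0.5, by = drift, length.out = 12)
  rf <- forecast_rates(plogis(x), 2001:2012, horizon = 5, scale = "logit")
  expect_equal(diff(rf$mean_t), rep(drift, 4), tolerance = 1e-6)
  expect_equal(rf$mean_t[1], x[12] + drift, tolerance = 1e-6)
  # same on the log scale
  rf2 <- forecast_rates(exp(x), 2001:2012, horizon = 5, scale = "log")
  expect_equal(diff(rf2$mean_t), rep(drift, 4), tolerance = 1e-6)
})

test_that("an AR(1) signal is recovered by the least-squares fit", {
  set.seed(33)
  a <- 0.3; b <- 0.6
  x <- numeric(400)
  x[1] <- a / (1 - b)
  for (t in 2:400) x[t] <- a + b * x[t - 1] + rnorm(1, 0, 0.1)
  rf <- forecast_rates(plogis(x), seq_along(x), 3, "logit")
  expect_equal(unname(rf$coef["b"]), b, tolerance = 0.1)
  expect_equal(unname(rf$coef["a"]), a, tolerance = 0.15)
  expect_identical(rf$model, "ar1_drift")
})

test_that("forecasts respect the transform ranges and input checks", {
  fit <- study_fit()
  yrs <- fit$theta$years
  rf <- forecast_rates(fit$theta$survival, yrs[-length(yrs)], 10, "logit")
  expect_true(all(rf$mean > 0 & rf$mean < 1))
  expect_error(forecast_rates(c(0.8, 0.9, 0.85, 0.8), 2001:2004, 5),
               "at least 5")
})

test_that("zero-variance forecasts reproduce the deterministic path", {
  rf_s <- structure(list(years = 2021:2030, mean_t = rep(qlogis(0.85), 10),
                         sd_t = rep(0, 10), scale = "logit"),
                    class = "rate_forecast")
  rf_r <- structure(list(years = 2021:2030, mean_t = rep(log(0.35), 10),
                         sd_t = rep(0, 10), scale = "log"),
                    class = "rate_forecast")
  start <- c(calf = 500, adult_female = 1400, adult_male = 1250)
  proj <- stochastic_project(start, 2020, rf_s, rf_r, n_sims = 25,
                             seed = 4)
  # every trajectory equals the hand-rolled deterministic recursion
  det <- matrix(NA_real_, 11, 3)
  det[1, ] <- start
  for (t in 1:10) {
    det[t + 1, 2] <- (det[t, 1] * 0.5 + det[t, 2]) * 0.85
    det[t + 1, 3] <- (det[t, 1] * 0.5 + det[t, 3]) * 0.85
    det[t + 1, 1] <- 0.35 * det[t, 2]
  }
  for (k in 1:25) {
    expect_equal(unname(proj$trajectories[k, , ]), det)
  }
  expect_equal(proj$summary$ci90_low, proj$summary$ci90_high)
})

test_that("survival 1 with no recruitment converts calves then holds", {
  rf_s <- structure(list(years = 2021:2030, mean_t = rep(40, 10),
                         sd_t = rep(0, 10), scale = "logit"),
                    class = "rate_forecast")
  rf_r <- structure(list(years = 2021:2030, mean_t = rep(-700, 10),
                         sd_t = rep(0, 10), scale = "log"),
                    class = "rate_forecast")
  proj <- stochastic_project(c(400, 1000, 900), 2020, rf_s, rf_r,
                             n_sims = 1, seed = 1)
  tr <- proj$trajectories[1, , ]
  expect_equal(unname(tr[2, ]), c(0, 1200, 1100), tolerance = 1e-12)
  expect_equal(unname(tr[11, ]), c(0, 1200, 1100), tolerance = 1e-12)
  expect_true(all(diff(tr[, 2]) >= 0))
})

test_that("identical seeds give bit-identical projections", {
  fit <- study_fit()
  yrs <- fit$theta$years
  rf_s <- forecast_rates(fit$theta$survival, yrs[-length(yrs)], 10,
                         "logit")
  r <- per_capita_recruitment(fit)
  rf_r <- forecast_rates(r$recruitment, r$year, 10, "log")
  run <- function(seed) {
    stochastic_project(fit$abundance[16, ], max(yrs), rf_s, rf_r,
                       n_sims = 200, seed = seed)
  }
  p1 <- run(7)
  p2 <- run(7)
  expect_identical(p1$trajectories, p2$trajectories)
  expect_identical(p1$summary, p2$summary)
  p3 <- run(8)
  expect_false(identical(p1$trajectories, p3$trajectories))
})

test_that("the 90% envelope contains the deterministic mean trajectory", {
  fit <- study_fit()
  yrs <- fit$theta$years
  rf_s <- forecast_rates(fit$theta$survival, yrs[-length(yrs)], 10,
                         "logit")
  r <- per_capita_recruitment(fit)
  rf_r <- forecast_rates(r$recruitment, r$year, 10, "log")
  proj <- study_projection(n_sims = 1000, seed = 42)
  rf_s0 <- rf_s; rf_s0$sd_t <- rep(0, 10)
  rf_r0 <- rf_r; rf_r0$sd_t <- rep(0, 10)
  det <- stochastic_project(fit$abundance[16, ], max(yrs), rf_s0, rf_r0,
                            n_sims = 1, seed = 1)
  dt <- det$summary[det$summary$class == "total", "median"]
  tot <- proj$summary[proj$summary$class == "total", ]
  expect_true(all(tot$ci90_low <= dt & dt <= tot$ci90_high))
})

test_that("projection medians are Monte-Carlo stable", {
  p1 <- study_projection(n_sims = 1000, seed = 42)
  p2 <- study_projection(n_sims = 4000, seed = 42)
  m1 <- p1$summary[p1$summary$class == "total", "median"]
  m2 <- p2$summary[p2$summary$class == "total", "median"]
  expect_true(all(abs(m1 - m2) / m2 < 0.02))
})

test_that("growth rate has its closed forms in degenerate cases", {
  mk <- function(tot0, totH, horizon) {
    traj <- array(0, c(1, horizon + 1, 3))
    traj[1, , 1] <- seq(tot0, totH, length.out = horizon + 1)
    structure(list(trajectories = traj, n_sims = 1, horizon = horizon),
              class = "projection_result")
  }
  expect_equal(growth_rate(mk(1000, 1000, 10))$median, 1)
  expect_equal(growth_rate(mk(1000, 500, 10))$median, 0.5^(1 / 10))
})
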