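test_that("adult projection step follows the invariance recursion", {
  expect_equal(project_adults(0, 100, 1.0), 100)
  expect_equal(project_adults(200, 300, 0.8), 320)
  expect_equal(project_adults(50, 0, 0.0), 0)
  expect_equal(project_adults(c(0, 200), c(100, 300), c(1, 0.8)),
               c(100, 320))
  expect_error(project_adults(10, 10, 1.2), "outside")
  expect_error(project_adults(10, 10, -0.1), "outside")
})

test_that("expected matrix expands the free parameters deterministically", {
  th <- param_vector(2001:2002, survival = 0.9,
                     initial = c(1000, 3000, 2000), recruitment = 800)
  N <- build_expected(th)
  expect_equal(unname(N[2, ]), c(800, 3150, 2250))
  # near-zero survival empties the adult cells
  th0 <- param_vector(2001:2003, survival = c(1e-9, 1e-9),
                      initial = c(1000, 3000, 2000),
                      recruitment = c(800, 700))
  expect_lt(max(build_expected(th0)[2:3, 2:3]), 1e-4)
  # high survival with steady recruitment accumulates adults
  thg <- param_vector(2001:2006, survival = rep(0.999, 5),
                      initial = c(500, 500, 500),
                      recruitment = rep(500, 5))
  Ng <- build_expected(thg)
  expect_true(all(diff(Ng[, 2]) > 0))
  expect_true(all(diff(Ng[, 3]) > 0))
})

test_that("fitted adult cells satisfy the invariance property exactly", {
  fit <- study_fit()
  N <- fit$abundance
  s <- fit$theta$survival
  for (i in 2:nrow(N)) {
    expect_identical(N[i, 2],
                     unname((N[i - 1, 1] * 0.5 + N[i - 1, 2]) * s[i - 1]))
    expect_identical(N[i, 3],
                     unname((N[i - 1, 1] * 0.5 + N[i - 1, 3]) * s[i - 1]))
  }
  expect_equal(fit$total, rowSums(N))
})

test_that("cell chi-square is the Pearson contribution", {
  expect_equal(cell_chisq(10, 10), 0)
  expect_equal(cell_chisq(0, 4), 4)
  expect_equal(round(cell_chisq(3200, 3150), 4), 0.7937)
})

test_that("joint objective is an additive sum over observed cells", {
  sm <- toy_perfect_survey()
  th <- toy_truth()
  expect_equal(joint_objective(th, sm), 0)
  # perturb a single observed cell: objective equals that cell's term
  N <- build_expected(th)
  sm1 <- sm
  sm1$counts[2, 2] <- N[2, 2] + 50
  expect_equal(joint_objective(th, sm1), 50^2 / N[2, 2])
  # doubling the deviation quadruples the contribution
  sm2 <- sm
  sm2$counts[2, 2] <- N[2, 2] + 100
  expect_equal(joint_objective(th, sm2), 4 * joint_objective(th, sm1))
  # a missing year contributes zero
  smm <- sm
  smm$counts[3, ] <- NA_real_
  expect_equal(joint_objective(th, smm), 0)
  expect_error(joint_objective(param_vector(2001:2003, c(0.8, 0.8),
                                            c(10, 10, 10), c(5, 5)), sm),
               "dimension mismatch")
})

test_that("telemetry objective compares observed to expected deaths", {
  th <- param_vector(2001:2003, survival = c(0.8, 1 - 9 / 22),
                     initial = c(100, 100, 100), recruitment = c(50, 50))
  tc0 <- telemetry_counts(2001, "pooled", 2, 10)
  expect_equal(telemetry_objective(th, tc0), 0)
  tc1 <- telemetry_counts(2001, "pooled", 3, 10)
  expect_equal(telemetry_objective(th, tc1), 0.5)  # (3-2)^2 / 2
  tc2 <- telemetry_counts(2002, "pooled", 9, 22)
  expect_equal(telemetry_objective(th, tc2), 0)
  # no-data years drop out
  tc3 <- telemetry_counts(c(2001, 2002), "pooled", c(3, NA), c(10, NA))
  expect_equal(telemetry_objective(th, tc3), 0.5)
})

test_that("joint objective scales linearly with the count scale", {
  sm <- toy_perfect_survey()
  th <- toy_truth()
  sm$counts <- sm$counts * 1.07  # misfit everywhere
  base <- joint_objective(th, sm)
  for (c_scale in c(0.5, 2, 10)) {
    sm_c <- sm
    sm_c$counts <- sm$counts * c_scale
    th_c <- param_vector(th$years, th$survival, th$initial * c_scale,
                         th$recruitment * c_scale)
    expect_equal(joint_objective(th_c, sm_c), c_scale * base)
  }
})

test_that("noise-free synthetic data is recovered with objective ~ 0", {
  truth <- toy_truth()
  sm <- toy_perfect_survey()
  fit <- fit_reconstruction(sm, tc = NULL, cfg = fit_config(restarts = 2))
  expect_true(fit$converged)
  expect_lt(fit$objective_value, 1e-6)
  expect_equal(unname(fit$theta$initial), unname(truth$initial),
               tolerance = 1e-3)
  expect_equal(unname(fit$theta$survival), unname(truth$survival),
               tolerance = 1e-3)
})

test_that("optimizer beats an exhaustive coarse grid on a 3-year instance", {
  years <- 2001:2003
  truth <- param_vector(years, c(0.82, 0.74), c(420, 910, 780),
                        c(360, 310))
  set.seed(11)
  obs <- build_expected(truth) * matrix(exp(rnorm(9, 0, 0.08)), 3, 3)
  sm <- survey_matrix(years, obs)

  # independent brute-force oracle: direct arithmetic on the 7-parameter
  # grid, no package objective code
  g <- expand.grid(
    s1 = seq(0.6, 0.95, by = 0.05), s2 = seq(0.6, 0.95, by = 0.05),
    n11 = seq(300, 550, by = 50), n12 = seq(700, 1100, by = 100),
    n13 = seq(600, 1000, by = 100), n21 = seq(250, 450, by = 50),
    n31 = seq(200, 400, by = 50))
  e22 <- (g$n11 * 0.5 + g$n12) * g$s1
  e23 <- (g$n11 * 0.5 + g$n13) * g$s1
  e32 <- (g$n21 * 0.5 + e22) * g$s2
  e33 <- (g$n21 * 0.5 + e23) * g$s2
  chi <- function(a, e) (a - e)^2 / e
  grid_obj <- chi(obs[1, 1], g$n11) + chi(obs[1, 2], g$n12) +
    chi(obs[1, 3], g$n13) + chi(obs[2, 1], g$n21) +
    chi(obs[2, 2], e22) + chi(obs[2, 3], e23) +
    chi(obs[3, 1], g$n31) + chi(obs[3, 2], e32) + chi(obs[3, 3], e33)

  fit <- fit_reconstruction(sm, tc = NULL, cfg = fit_config(restarts = 3))
  expect_lte(fit$objective_value, min(grid_obj) + 1e-6)
})

test_that("per-capita recruitment is next-winter calves per female", {
  th <- toy_truth()
  N <- build_expected(th)
  r <- per_capita_recruitment(N)
  expect_equal(r$year, 2001:2003)
  expect_equal(r$recruitment, unname(N[2:4, 1] / N[1:3, 2]))
  # no calves next winter means zero recruitment
  N0 <- N
  N0[2, 1] <- 0
  expect_equal(per_capita_recruitment(N0)$recruitment[1], 0)
})
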