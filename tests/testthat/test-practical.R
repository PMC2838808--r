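## Monte-Carlo practical identifiability: solution clouds, trimming and
## ellipsoid summaries, cost contours.

test_that("zero-noise replicates all reproduce the truth", {
  mm <- decay_gain_toy()
  d <- simple_design(times = seq(0.5, 4, by = 0.5))
  cl <- monte_carlo_cloud(mm$model, d, mm$space, c("k", "a"),
                          theta_true = mm$space$nominal, n_reps = 10,
                          noise_spec = list(rel = 0, floor = 1e-9),
                          master_seed = 1)
  expect_equal(nrow(cl$estimates), 10)
  dev <- sweep(cl$estimates, 2, mm$space$nominal[c("k", "a")], "/") - 1
  expect_lt(max(abs(dev)), 1e-5)
})

test_that("cloud spread matches the closed-form least-squares sd for a
           linear-in-parameter model", {
  ## y(t) = th * t + eps, eps ~ N(0, sigma^2):
  ## sd(th_hat) = sigma / sqrt(sum t_i^2)
  mm <- linear_toy(th = 2)
  ts <- c(1, 2, 3, 4)
  d <- experiment_design("toy_exp",
                         stimulus_profile("persistent", duration = 4),
                         observables = "y", sampling_times = ts,
                         noise_rel = 0, noise_floor = 0.5)
  cl <- monte_carlo_cloud(mm$model, d, mm$space, "th",
                          theta_true = mm$space$nominal, n_reps = 500,
                          noise_spec = list(rel = 0, floor = 0.5),
                          master_seed = 11)
  sd_mc <- stats::sd(cl$estimates[, "th"])
  sd_th <- 0.5 / sqrt(sum(ts^2))
  expect_lt(abs(sd_mc - sd_th) / sd_th, 0.1)
})

test_that("replicate seeds depend only on the master seed (order
           invariance and reproducibility)", {
  mm <- decay_gain_toy()
  d <- simple_design(times = c(0.5, 1, 2, 4))
  a <- monte_carlo_cloud(mm$model, d, mm$space, c("k", "a"),
                         theta_true = mm$space$nominal, n_reps = 8,
                         noise_spec = list(rel = 0.05, floor = 1e-4),
                         master_seed = 3)
  b <- monte_carlo_cloud(mm$model, d, mm$space, c("k", "a"),
                         theta_true = mm$space$nominal, n_reps = 8,
                         noise_spec = list(rel = 0.05, floor = 1e-4),
                         master_seed = 3)
  expect_identical(a$estimates, b$estimates)
  cc <- monte_carlo_cloud(mm$model, d, mm$space, c("k", "a"),
                          theta_true = mm$space$nominal, n_reps = 8,
                          noise_spec = list(rel = 0.05, floor = 1e-4),
                          master_seed = 4)
  expect_false(identical(a$estimates, cc$estimates))
})

test_that("trimming and ellipsoid fit behave on synthetic clouds", {
  set.seed(1)
  ## isotropic Gaussian: all pairwise eccentricities close to 1
  X <- matrix(rnorm(3000, mean = 10, sd = 0.5), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  cl <- solution_cloud(X)
  fit <- trim_and_fit(cl)
  expect_true(all(fit$ecc[upper.tri(fit$ecc)] >= 1))
  expect_true(all(fit$ecc[upper.tri(fit$ecc)] < 1.3))
  ## per-coordinate trimming retains about 90% per coordinate
  for (j in 1:3) {
    inside_j <- mean(X[, j] >= fit$q[1, j] & X[, j] <= fit$q[2, j])
    expect_equal(inside_j, 0.9, tolerance = 0.02)
  }
  ## axes orthonormal, lengths sorted descending
  expect_equal(crossprod(fit$axes), diag(3), tolerance = 1e-10)
  expect_true(all(diff(fit$lengths) <= 1e-12))
  ## perfectly correlated pair: capped and flagged degenerate
  Y <- cbind(p = X[, 1], q = 2 * X[, 1])
  fit2 <- trim_and_fit(solution_cloud(Y))
  expect_equal(fit2$ecc["p", "q"], 1e3)
  expect_true(fit2$degenerate["p", "q"])
  expect_error(trim_and_fit(solution_cloud(X[1:10, ])), "20")
})

test_that("eccentricity is invariant to rescaling one parameter's
           units", {
  set.seed(2)
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  X <- matrix(rnorm(2000), ncol = 2) %*% chol(S)
  X <- sweep(X, 2, c(5, 7), "+")
  colnames(X) <- c("a", "b")
  f1 <- trim_and_fit(solution_cloud(X))
  X2 <- X
  X2[, 2] <- X2[, 2] * 1000
  f2 <- trim_and_fit(solution_cloud(X2))
  expect_equal(f1$ecc["a", "b"], f2$ecc["a", "b"], tolerance = 0.05)
})

test_that("uncertainty report: degenerate cloud and exact-mean cases", {
  X <- matrix(rep(c(2, 3), each = 30), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  X <- X + 0  # constant cloud
  cl <- solution_cloud(X)
  fit <- trim_and_fit(cl)
  ur <- uncertainty_report(cl, fit, theta_true = c(a = 2, b = 3))
  expect_equal(ur$table$C_theta, c(0, 0))
  expect_equal(ur$table$C_pct, c(0, 0))
  expect_equal(ur$table$delta_pct, c(0, 0))
  expect_equal(ur$pseudo_volume, 0)
})

test_that("cost contours: circular for a separable quadratic, straight
           open valley for the sum-only toy", {
  mm <- decay_gain_toy()
  d <- simple_design(times = seq(0.5, 4, by = 0.5))
  truth <- predict_observables(mm$model, mm$space$nominal, d)
  truth$sd <- rep(0.05, nrow(truth))
  prob <- calibration_problem(mm$model, d, truth, mm$space,
                              free = c("k", "a"))
  cc <- cost_contours(prob, c("k", "a"), n_grid = 15)
  imin <- which(cc$J == min(cc$J), arr.ind = TRUE)
  expect_equal(cc$par1[imin[1]], 0.4, tolerance = 0.15)
  expect_equal(cc$par2[imin[2]], 0.8, tolerance = 0.15)
  ## sum-only toy: open valley along k1 + k2 = const
  ms <- sum_only_toy()
  ds <- simple_design(times = c(0.5, 1, 2))
  tr2 <- predict_observables(ms$model, ms$space$nominal, ds)
  tr2$sd <- rep(0.01, nrow(tr2))
  prob2 <- calibration_problem(ms$model, ds, tr2, ms$space,
                               free = c("k1", "k2"))
  cc2 <- cost_contours(prob2, c("k1", "k2"), n_grid = 21)
  expect_true(cc2$open_valley)
  expect_lt(cc2$valley_correlation, -0.5)
})
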