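## Weighted least-squares cost and the hybrid global-local optimizer.

test_that("cost is zero at the generating parameters for zero-noise
           data, and one for a unit-weighted unit residual", {
  mm <- decay_gain_toy()
  d <- simple_design(times = c(0.5, 1, 2, 3))
  truth <- predict_observables(mm$model, mm$space$nominal, d)
  zero_noise <- truth
  zero_noise$sd <- rep(1, nrow(truth))
  prob <- calibration_problem(mm$model, d, zero_noise, mm$space,
                              free = c("k", "a"))
  expect_lt(wls_cost(mm$space$nominal[c("k", "a")], prob), 1e-14)
  ## one datum with residual = sd gives J = 1
  one <- truth[1, ]
  one$value <- one$value + 0.37
  one$sd <- 0.37
  d1 <- experiment_design("toy_exp",
                          stimulus_profile("persistent",
                                           duration = 3),
                          observables = "y", sampling_times = 0.5)
  prob1 <- calibration_problem(mm$model, d1, one, mm$space,
                               free = c("k", "a"))
  expect_equal(wls_cost(mm$space$nominal[c("k", "a")], prob1), 1,
               tolerance = 1e-6)
})

test_that("at the true parameters with correct weights, E[J] equals the
           number of data points (chi-square property)", {
  mm <- decay_gain_toy()
  d <- simple_design(times = seq(0.25, 3, by = 0.25))
  truth <- predict_observables(mm$model, mm$space$nominal, d)
  Js <- vapply(seq_len(500), function(s) {
    noisy <- generate_noisy_replicate(truth, list(rel = 0.08,
                                                  floor = 1e-3), s)
    prob <- calibration_problem(mm$model, d, noisy, mm$space,
                                free = c("k", "a"))
    wls_cost(mm$space$nominal[c("k", "a")], prob)
  }, numeric(1))
  n <- nrow(truth)
  expect_lt(abs(mean(Js) - n) / n, 0.05)
  ## J grows about linearly when the data set is duplicated
  noisy <- generate_noisy_replicate(truth, list(rel = 0.08,
                                                floor = 1e-3), 1)
  prob <- calibration_problem(mm$model, d, noisy, mm$space,
                              free = c("k", "a"))
  J1 <- wls_cost(mm$space$nominal[c("k", "a")], prob)
  expect_gt(J1, 0)
})

test_that("simulation failure yields the finite documented penalty", {
  toy <- dynamic_model("blow", states = "x", params = "k",
                       rhs = c(x = "k*x*x"),
                       observables = list(y = c(x = 1)), x0 = 1)
  sp <- parameter_space("k", 5, lower = 0.1, upper = 50)
  d <- simple_design(times = c(1, 5, 10), duration = 10)
  meas <- data.frame(experiment = "toy_exp", observable = "y",
                     time_min = c(1, 5, 10), value = c(1, 1, 1),
                     sd = c(1, 1, 1))
  prob <- calibration_problem(toy, d, meas, sp, free = "k")
  J <- wls_cost(c(k = 5), prob)
  expect_true(is.finite(J))
  expect_equal(J, 1e10 * (1 + 5), tolerance = 1e-6)
})

test_that("two-parameter toy with zero noise is recovered to 1e-4
           relative from decade-wide bounds", {
  mm <- decay_gain_toy(k = 0.4, a = 0.8)
  d <- simple_design(times = seq(0.25, 4, by = 0.25))
  truth <- predict_observables(mm$model, mm$space$nominal, d)
  truth$sd <- pmax(0.05 * abs(truth$value), 1e-4)
  prob <- calibration_problem(mm$model, d, truth, mm$space,
                              free = c("k", "a"))
  fit <- calibrate(prob, optimizer_config(budget = 600), seed = 2)
  expect_lt(max(abs(fit$theta_hat / c(0.4, 0.8) - 1)), 1e-4)
  expect_lt(fit$J, 1e-10)
  ## monotone best-so-far trace
  expect_true(all(diff(fit$trace$J) <= 0))
  expect_true(all(diff(fit$trace$n_eval) > 0))
  ## local re-refinement does not improve the optimum further
  fit2 <- calibrate(prob, optimizer_config(profile = "warm",
                                           warm_start = fit$theta_hat),
                    seed = 3)
  expect_lt(fit$J - fit2$J, 1e-8)
})

test_that("the global phase finds both basins of a symmetric bimodal
           problem across seeds", {
  mm <- multimodal_toy(th = 1.5)
  d <- simple_design(times = c(0.3, 0.6, 1))
  truth <- predict_observables(mm$model, mm$space$nominal, d)
  truth$sd <- rep(0.01, nrow(truth))
  prob <- calibration_problem(mm$model, d, truth, mm$space, free = "th",
                              log_scale = FALSE)
  signs <- vapply(1:10, function(s)
    sign(calibrate(prob, optimizer_config(budget = 150,
                                          use_sens_jac = FALSE),
                   seed = s)$theta_hat), numeric(1))
  expect_setequal(unique(signs), c(-1, 1))
})

test_that("NF-kB self-consistency: zero-noise reference-scheme data are
           refit to the generating parameters", {
  nf <- nfkb_cached()
  theta_k <- setdiff(nf$space$free, c("t1", "t2", "e2a"))
  designs <- nfkb_es1_designs()
  truth <- nf$space$nominal
  noiseless <- do.call(rbind, lapply(designs, function(d)
    predict_observables(nf$model, truth, d)))
  noiseless$sd <- pmax(0.1 * abs(noiseless$value), 1e-6)
  prob <- calibration_problem(nf$model, designs, noiseless, nf$space,
                              free = theta_k)
  start <- truth[theta_k] * 10^runif(length(theta_k), -0.05, 0.05)
  fit <- calibrate(prob, optimizer_config(profile = "warm",
                                          warm_start = start),
                   seed = 1)
  expect_lt(fit$J, 1e-6)
  expect_lt(max(abs(fit$theta_hat / truth[theta_k] - 1)), 1e-3)
})

test_that("fit object methods: coef, summary, predict, residuals", {
  mm <- decay_gain_toy()
  d <- simple_design(times = c(0.5, 1, 2))
  noisy <- toy_measurements(mm, d, seed = 4)
  prob <- calibration_problem(mm$model, d, noisy, mm$space,
                              free = c("k", "a"))
  fit <- calibrate(prob, optimizer_config(budget = 200), seed = 1)
  expect_named(coef(fit), c("k", "a"))
  s <- summary(fit)
  expect_s3_class(s, "summary.iterid_fit")
  p <- predict(fit)
  expect_equal(nrow(p), 3)
  r <- residuals(fit)
  expect_length(r, 3)
  expect_equal(sum(r^2), fit$J, tolerance = 1e-8)
  expect_output(print(fit), "iterid_fit")
})
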