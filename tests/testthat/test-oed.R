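## Fisher information, design criteria, CRLB and design optimisation.

test_that("FIM of the decay toy matches the closed form
           (t e^{-kt})^2 / sigma^2", {
  mm <- decay_toy(k = 0.5, x0 = 1)
  t1 <- 1.7
  d <- experiment_design("one",
                         stimulus_profile("persistent", duration = 3),
                         observables = "y", sampling_times = t1,
                         noise_rel = 0, noise_floor = 0.2)
  F <- fisher_information(mm$model, mm$space$nominal, d, "k")
  expect_equal(as.numeric(F), (t1 * exp(-0.5 * t1))^2 / 0.2^2,
               tolerance = 1e-5)
})

test_that("zero-sensitivity parameters give zero FIM rows/columns and
           information is additive over schemes", {
  model <- dynamic_model("gh", states = "x", params = c("k", "ghost"),
                         rhs = c(x = "-k*x"),
                         observables = list(y = c(x = 1)), x0 = 1)
  sp <- parameter_space(c("k", "ghost"), c(0.5, 1))
  dA <- simple_design(times = c(0.5, 1))
  dB <- simple_design(times = c(2, 3))
  th <- sp$nominal
  FA <- fisher_information(model, th, dA, c("k", "ghost"))
  FB <- fisher_information(model, th, dB, c("k", "ghost"))
  FAB <- fisher_information(model, th, list(dA, dB), c("k", "ghost"))
  expect_equal(FA["ghost", ], c(k = 0, ghost = 0))
  expect_equal(unclass(FAB), unclass(FA) + unclass(FB),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("design criteria: determinant and minimum eigenvalue, with
           monotone E under PSD increments", {
  F <- diag(c(4, 9))
  expect_equal(design_criterion(F, "D"), 36)
  expect_equal(design_criterion(F, "E"), 4)
  Fs <- matrix(c(1, 1, 1, 1), 2)  # singular
  expect_equal(design_criterion(Fs, "D"), 0, tolerance = 1e-12)
  expect_equal(design_criterion(Fs, "E"), 0, tolerance = 1e-12)
  set.seed(1)
  for (i in 1:20) {
    A <- crossprod(matrix(rnorm(9), 3))
    B <- crossprod(matrix(rnorm(9), 3))
    expect_gte(design_criterion(A + B, "E"),
               design_criterion(A, "E") - 1e-10)
  }
})

test_that("CRLB from the FIM: diagonal case, singular flag, and
           agreement with closed-form linear-regression sd", {
  F <- diag(c(1 / 0.3^2, 1 / 0.7^2))
  dimnames(F) <- list(c("a", "b"), c("a", "b"))
  pu <- predicted_uncertainty_from_fim(F)
  expect_equal(unname(pu$sd), c(0.3, 0.7), tolerance = 1e-12)
  expect_false(pu$singular)
  Fs <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"),
                                                 c("a", "b")))
  pus <- predicted_uncertainty_from_fim(Fs)
  expect_true(pus$singular)
  expect_true(all(is.infinite(pus$sd)))
  ## linear regression y = th * t: CRLB = sigma / sqrt(sum t^2)
  mm <- linear_toy(th = 2)
  ts <- c(1, 2, 3, 4)
  d <- experiment_design("lin",
                         stimulus_profile("persistent", duration = 4),
                         observables = "y", sampling_times = ts,
                         noise_rel = 0, noise_floor = 0.5)
  Fl <- fisher_information(mm$model, mm$space$nominal, d, "th")
  pul <- predicted_uncertainty_from_fim(Fl)
  expect_equal(unname(pul$sd), 0.5 / sqrt(sum(ts^2)), tolerance = 1e-5)
})

test_that("the optimal single sampling time for the decay rate is
           t = 1/k", {
  k <- 0.8
  mm <- decay_toy(k = k, x0 = 1)
  res <- optimize_design(
    mm$model, mm$space$nominal, "k",
    criterion = "E",
    constraints = list(observables = "y", max_pulses = 1,
                       max_samples = 1, dur_range = c(3 / k, 3 / k + 1e-6),
                       min_gap = 1e-4, noise_rel = 0, noise_floor = 0.2),
    budget = 400, pop = 16, seed = 2)
  t_opt <- res$design$sampling_times[["y"]]
  expect_equal(t_opt, 1 / k, tolerance = 0.01)
})

test_that("a dominating prior makes the objective flat and is flagged",
{
  mm <- decay_toy()
  prior <- matrix(1e6, 1, 1, dimnames = list("k", "k"))
  res <- optimize_design(
    mm$model, mm$space$nominal, "k", prior_fim = prior,
    criterion = "E",
    constraints = list(observables = "y", max_pulses = 1,
                       max_samples = 2, dur_range = c(2, 4),
                       noise_rel = 0, noise_floor = 0.2),
    budget = 120, pop = 12, seed = 1)
  expect_true(res$flat)
  expect_lt((res$value - res$prior_value) / res$prior_value, 1e-3)
})

test_that("the optimised design dominates random feasible designs", {
  mm <- twocomp_toy()
  cons <- list(observables = "y", max_pulses = 2, max_samples = 5,
               dur_range = c(4, 10), min_gap = 0.1,
               noise_rel = 0.1, noise_floor = 1e-3)
  res <- optimize_design(mm$model, mm$space$nominal, c("k1", "k2"),
                         criterion = "E", constraints = cons,
                         budget = 300, pop = 16, seed = 3)
  set.seed(99)
  rand_vals <- vapply(1:100, function(i) {
    z <- runif(1 + 2 * cons$max_pulses + cons$max_samples)
    des <- iterid:::decode_design(z, cons, mm$model)
    design_criterion(unclass(
      fisher_information(mm$model, mm$space$nominal, des,
                         c("k1", "k2"))), "E")
  }, numeric(1))
  expect_gte(res$value, max(rand_vals) * 0.999)
  ## result criterion never below any traced iterate
  expect_true(all(res$trace$best <= res$value + 1e-12))
})

test_that("infeasible constraints are rejected before the search", {
  mm <- decay_toy()
  expect_error(optimize_design(mm$model, mm$space$nominal, "k",
                               constraints = list(observables = "y",
                                                  dur_range = c(5, 4)),
                               budget = 10, seed = 1),
               "infeasible")
})
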