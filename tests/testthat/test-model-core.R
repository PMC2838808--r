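## Model construction, NF-kB instantiation, simulation and the in-silico
## measurement generator.

test_that("NF-kB model matches its tabulated parameterisation", {
  nf <- nfkb_cached()
  sp <- nf$space
  expect_equal(nf$model$n_states, 15)
  expect_equal(nf$model$n_params, 30)
  expect_equal(unname(sp$nominal["k1"]), 2.5e-3)
  expect_equal(unname(sp$nominal["kv"]), 5)
  expect_false("kv" %in% sp$free)
  expect_equal(unname(sp$nominal["NF"]), 0.06)
  expect_length(sp$free, 13)
  expect_setequal(sp$free, c("t1", "t2", "c3a", "c4a", "c5", "k1", "k2",
                             "k3", "kprod", "kdeg", "i1", "e2a", "i1a"))
})

test_that("compiled rhs, expression rhs and affine decomposition agree", {
  nf <- nfkb_cached()
  m <- nf$model
  m_expr <- m
  m_expr$compiled <- NULL
  set.seed(42)
  for (i in 1:100) {
    x <- stats::setNames(runif(15, 0, 0.25), m$states)
    u <- sample(0:1, 1)
    th <- nf$space$nominal * runif(30, 0.5, 2)
    f_c <- unname(iterid:::model_rhs(m, x, u, th))
    f_e <- unname(iterid:::model_rhs(m_expr, x, u, th))
    f_a <- unname(iterid:::model_rhs_affine(m_expr, x, u, th))
    expect_equal(f_c, f_e, tolerance = 1e-12)
    expect_equal(f_a, f_e, tolerance = 1e-12)
  }
})

test_that("analytic Jacobians match finite differences of the rhs", {
  nf <- nfkb_cached()
  m <- nf$model
  m_expr <- m; m_expr$compiled <- NULL
  set.seed(7)
  x <- stats::setNames(runif(15, 0.01, 0.2), m$states)
  th <- nf$space$nominal
  for (u in 0:1) {
    Jc <- iterid:::model_jac_state(m, x, u, th)
    Jf <- iterid:::model_jac_state(m_expr, x, u, th)
    expect_equal(Jc, Jf, tolerance = 1e-5)
    Pc <- iterid:::model_jac_par(m, x, u, th)
    Pf <- iterid:::model_jac_par(m_expr, x, u, th)
    expect_equal(Pc, Pf, tolerance = 1e-5)
  }
})

test_that("resting state is a genuine equilibrium on the NF-kB manifold", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  xr <- resting_state(nf$model, th)
  expect_lt(attr(xr, "rhs_norm"), 1e-10)
  expect_equal(unname(iterid:::nfkb_total_nf(t(as.matrix(xr)))), 0.06,
               tolerance = 1e-9)
  ## re-simulated 1000 min unstimulated: negligible drift
  d <- experiment_design("rest", stimulus_profile("pulse",
                                                  switch_times = 999.5,
                                                  duration = 1000),
                         observables = "NFkBn",
                         sampling_times = c(500, 999))
  s <- simulate_model(nf$model, th, d, x0 = xr)
  drift <- sweep(abs(sweep(s$x, 2, xr, "-")), 2, abs(xr) + 1e-8, "/")
  expect_lt(max(drift[s$times <= 999, ]), 1e-6)
})

test_that("resting state reports failure for divergent dynamics", {
  toy <- dynamic_model("bad", states = "x", params = "k",
                       rhs = c(x = "k + x*x"),
                       observables = list(y = c(x = 1)), x0 = 1)
  expect_error(resting_state(toy, c(k = 1)), "resting|converge|failure")
})

test_that("unstimulated simulation stays constant; stimulated NF-kB
           oscillates with conserved total NF-kB", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  ## persistent stimulation: damped nuclear NF-kB oscillations
  d <- experiment_design("p6", stimulus_profile("persistent",
                                                duration = 360),
                         observables = "NFkBn",
                         sampling_times = seq(1, 360))
  s <- simulate_model(nf$model, th, d)
  y <- iterid:::observable_values(nf$model, "NFkBn", s$x)
  n_max <- sum(diff(sign(diff(y))) == -2)
  expect_gte(n_max, 2)
  expect_lt(max(abs(iterid:::nfkb_total_nf(s$x) - 0.06)), 1e-6 * 0.06)
})

test_that("total NF-kB is conserved for random parameters in bounds", {
  nf <- nfkb_cached()
  set.seed(11)
  d <- experiment_design("p", stimulus_profile("pulse",
                                               switch_times = c(0, 90),
                                               duration = 240),
                         observables = "NFkBn",
                         sampling_times = seq(10, 240, by = 10))
  for (i in 1:5) {
    th <- nf$space$nominal
    th[nf$space$free] <- th[nf$space$free] *
      10^runif(length(nf$space$free), -0.5, 0.5)
    s <- simulate_model(nf$model, th, d)
    expect_false(inherits(s, "sim_failure"))
    tot <- iterid:::nfkb_total_nf(s$x)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("halving integrator tolerances leaves sampled observables
           unchanged to 1e-5 relative", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  d <- nfkb_es1_designs()[[1]]
  p1 <- predict_observables(nf$model, th, d, rtol = 1e-8, atol = 1e-12)
  p2 <- predict_observables(nf$model, th, d, rtol = 5e-9, atol = 5e-13)
  rel <- abs(p1$value - p2$value) / pmax(abs(p2$value), 1e-10)
  expect_lt(max(rel), 1e-5)
})

test_that("composite observables are the stated linear combinations", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  d <- experiment_design(
    "obs", stimulus_profile("persistent", duration = 120),
    observables = c("total_IKK", "IKKa", "total_IkBa_cyt"),
    sampling_times = c(30, 60, 120))
  sim <- simulate_model(nf$model, th, d)
  p <- predict_observables(nf$model, th, d, sim = sim)
  idx <- match(c(30, 60, 120), sim$times)
  tot <- p$value[p$observable == "total_IKK"]
  expect_equal(tot, rowSums(sim$x[idx, c("IKKn", "IKKa", "IKKi")]),
               tolerance = 1e-12)
  cyt <- p$value[p$observable == "total_IkBa_cyt"]
  expect_equal(cyt, rowSums(sim$x[idx, c("IkBa", "IkBa_NFkB")]),
               tolerance = 1e-12)
  ## active IKK is zero in resting cells before stimulation
  xr <- resting_state(nf$model, th)
  expect_lt(abs(xr[["IKKa"]]), 1e-12)
  expect_error(predict_observables(
    nf$model, th,
    experiment_design("bad", stimulus_profile("persistent",
                                              duration = 10),
                      observables = "no_such", sampling_times = 5)),
    "unknown observable")
})

test_that("the reference scheme ES1 observes six read-outs in the
           persistent wild-type experiment", {
  es1 <- nfkb_es1_designs()
  expect_length(es1, 3)
  expect_length(es1[[1]]$observables, 6)
  expect_setequal(es1[[2]]$observables, c("NFkBn", "total_IkBa_cyt"))
  expect_equal(es1[[3]]$stimulus$switch_times, c(0, 60))
})

test_that("noise generator: moments, zero-noise limit and seeding", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  d <- experiment_design("one", stimulus_profile("persistent",
                                                 duration = 60),
                         observables = "NFkBn", sampling_times = 30)
  truth <- predict_observables(nf$model, th, d)
  ## zero noise reproduces the truth exactly
  z <- generate_noisy_replicate(truth, list(rel = 0, floor = 0), seed = 1)
  expect_identical(z$value, truth$value)
  ## same seed, bit-identical; different seed differs
  a <- generate_noisy_replicate(truth, list(rel = 0.1, floor = 0), 5)
  b <- generate_noisy_replicate(truth, list(rel = 0.1, floor = 0), 5)
  cc <- generate_noisy_replicate(truth, list(rel = 0.1, floor = 0), 6)
  expect_identical(a$value, b$value)
  expect_false(identical(a$value, cc$value))
  ## sd of many replicates matches the heteroscedastic model
  reps <- vapply(seq_len(1e4), function(s)
    generate_noisy_replicate(truth, list(rel = 0.1, floor = 0),
                             seed = s)$value[1], numeric(1))
  ratio <- stats::sd(reps) / (0.1 * abs(truth$value[1]))
  expect_gt(ratio, 0.97)
  expect_lt(ratio, 1.03)
  expect_error(generate_noisy_replicate(truth, list(rel = -1, floor = 0),
                                        1), ">= 0")
})

test_that("measurement CSV and design files round-trip", {
  nf <- nfkb_cached()
  d <- nfkb_es1_designs()[[3]]
  truth <- predict_observables(nf$model, nf$space$nominal, d)
  noisy <- generate_noisy_replicate(truth, list(rel = 0.1, floor = 1e-6),
                                    seed = 3)
  f <- tempfile(fileext = ".csv")
  write_measurements(noisy, f)
  back <- read_measurements(f)
  expect_identical(back$value, noisy$value)
  expect_identical(back$sd, noisy$sd)
  expect_identical(back$time_min, noisy$time_min)
  fj <- tempfile(fileext = ".json")
  design_to_file(d, fj)
  d2 <- design_from_file(fj)
  expect_equal(d2$sampling_times, d$sampling_times)
  expect_equal(d2$stimulus$switch_times, d$stimulus$switch_times)
  fy <- tempfile(fileext = ".yaml")
  design_to_file(d, fy)
  d3 <- design_from_file(fy)
  expect_equal(d3$sampling_times, d$sampling_times)
})

test_that("a user model declared via config behaves like the direct
           constructor", {
  cfg <- list(name = "cfg_decay",
              states = "x",
              params = list(k = 0.5),
              rhs = list(x = "-k*x"),
              observables = list(y = list(x = 1)),
              x0 = 2)
  mm <- model_from_config(cfg)
  d <- simple_design(times = c(1, 2))
  p <- predict_observables(mm$model, mm$space$nominal, d)
  expect_equal(p$value, 2 * exp(-0.5 * c(1, 2)), tolerance = 1e-7)
})
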