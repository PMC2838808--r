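## Forward sensitivities: closed-form and finite-difference oracles,
## structural zeros, relative-sensitivity contracts.

test_that("decay toy sensitivity matches the closed form
           d y / d k = -t * x0 * exp(-k t)", {
  mm <- decay_toy(k = 0.5, x0 = 1)
  ts <- c(0.5, 1, 2, 4)
  d <- simple_design(times = ts)
  sens <- forward_sensitivities(mm$model, mm$space$nominal, d, "k")
  expect_equal(as.numeric(sens$dydtheta$y),
               -ts * exp(-0.5 * ts), tolerance = 1e-6)
})

test_that("a parameter absent from rhs and observation map has an
           identically zero sensitivity column", {
  model <- dynamic_model("extra", states = "x", params = c("k", "ghost"),
                         rhs = c(x = "-k*x"),
                         observables = list(y = c(x = 1)), x0 = 1)
  d <- simple_design(times = c(1, 2, 3))
  sens <- forward_sensitivities(model, c(k = 0.5, ghost = 2), d,
                                c("k", "ghost"))
  expect_equal(max(abs(sens$dydtheta$y[, "ghost"])), 0)
  expect_gt(max(abs(sens$dydtheta$y[, "k"])), 0)
})

test_that("NF-kB forward sensitivities agree with central finite
           differences for all 13 free parameters", {
  nf <- nfkb_cached()
  th <- nf$space$nominal
  free <- nf$space$free
  d <- experiment_design("fd", stimulus_profile("persistent",
                                                duration = 360),
                         observables = c("NFkBn", "total_IkBa_cyt"),
                         sampling_times = c(30, 90, 180, 300))
  sens <- forward_sensitivities(nf$model, th, d, free,
                                rtol = 1e-10, atol = 1e-14)
  fd <- iterid:::fd_observable_sensitivities(nf$model, th, d, free,
                                             rel_step = 1e-5,
                                             rtol = 1e-12, atol = 1e-16)
  for (ob in c("NFkBn", "total_IkBa_cyt")) {
    rows <- fd$observable == ob
    for (p in free) {
      a <- sens$dydtheta[[ob]][, p]
      b <- fd[[p]][rows]
      expect_lt(max(abs(a - b)) / max(abs(b)), 1e-3)
    }
  }
})

test_that("relative sensitivities obey their defining contracts", {
  ## identity-like observable: y = x with dx/dt = 0, x0 = theta is not
  ## expressible; use the algebraic contracts on a synthetic trajectory
  mm <- decay_gain_toy()
  d <- simple_design(times = c(1, 2, 4))
  th <- mm$space$nominal
  sens <- forward_sensitivities(mm$model, th, d, c("k", "a"))
  rel <- relative_sensitivities(sens, floor = 1e-8)
  y <- sens$y$y
  for (p in c("k", "a"))
    expect_equal(rel$y[, p],
                 th[[p]] / pmax(abs(y), 1e-8) * sens$dydtheta$y[, p],
                 tolerance = 1e-12)
  ## a zero observable with finite dydtheta stays finite via the floor
  fake <- sens
  fake$y$y <- rep(0, 3)
  rel2 <- relative_sensitivities(fake, floor = 1e-6)
  expect_true(all(is.finite(rel2$y)))
  expect_equal(rel2$y[, "k"], th[["k"]] / 1e-6 * sens$dydtheta$y[, "k"],
               tolerance = 1e-12)
})

test_that("sensitivities on random small models match finite differences
           and are linear in composite observables", {
  set.seed(3)
  for (rep in 1:3) {
    ## random linear 3-state model with 4 parameters
    A <- matrix(round(runif(9, -0.8, 0.2), 2), 3)
    diag(A) <- -abs(diag(A)) - 0.5
    rhs <- c(
      x1 = sprintf("%f*x1 + %f*x2 + %f*x3 + p1", A[1, 1], A[1, 2],
                   A[1, 3]),
      x2 = sprintf("p2*x1 + %f*x2 + %f*x3", A[2, 2], A[2, 3]),
      x3 = sprintf("%f*x1 + p3*x2 + %f*x3*p4", A[3, 1], A[3, 3]))
    model <- dynamic_model("rand", states = c("x1", "x2", "x3"),
                           params = c("p1", "p2", "p3", "p4"),
                           rhs = rhs,
                           observables = list(y1 = c(x1 = 1),
                                              y2 = c(x2 = 1, x3 = 2),
                                              comp = c(x1 = 1, x2 = 1,
                                                       x3 = 2)),
                           x0 = c(1, 0.5, 0.2))
    th <- c(p1 = 0.7, p2 = 0.4, p3 = 0.3, p4 = 0.6)
    d <- experiment_design("r", stimulus_profile("persistent",
                                                 duration = 3),
                           observables = c("y1", "y2", "comp"),
                           sampling_times = c(1, 2, 3))
    sens <- forward_sensitivities(model, th, d, names(th),
                                  rtol = 1e-10, atol = 1e-13)
    fd <- iterid:::fd_observable_sensitivities(model, th, d, names(th),
                                               rtol = 1e-11, atol = 1e-14)
    for (p in names(th)) {
      a <- c(sens$dydtheta$y1[, p], sens$dydtheta$y2[, p])
      b <- fd[[p]][fd$observable %in% c("y1", "y2")]
      expect_lt(max(abs(a - b)) / max(max(abs(b)), 1e-8), 1e-3)
      ## composite = y1 + y2 as a linear combination of sensitivities
      expect_equal(sens$dydtheta$comp[, p],
                   sens$dydtheta$y1[, p] + sens$dydtheta$y2[, p],
                   tolerance = 1e-7)
    }
  }
})
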