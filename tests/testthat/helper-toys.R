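## Small fixture models used across the test files; everything is built
## in code so the suite needs no data files.

## exponential decay: dx/dt = -k x, y = x
decay_toy <- function(k = 0.5, x0 = 1) {
  model <- dynamic_model("decay", states = "x", params = "k",
                         rhs = c(x = "-k*x"),
                         observables = list(y = c(x = 1)), x0 = x0)
  space <- parameter_space("k", k, lower = k / 10, upper = k * 10)
  list(model = model, space = space)
}

## decay + gain: dx/dt = -k x + a, y = x  (2 estimable parameters)
decay_gain_toy <- function(k = 0.4, a = 0.8, x0 = 0.3) {
  model <- dynamic_model("decay_gain", states = "x", params = c("k", "a"),
                         rhs = c(x = "-k*x + a"),
                         observables = list(y = c(x = 1)), x0 = x0)
  space <- parameter_space(c("k", "a"), c(k, a))
  list(model = model, space = space)
}

## two-compartment cascade with stimulus: structurally identifiable
twocomp_toy <- function(k1 = 0.4, k2 = 0.9) {
  model <- dynamic_model("twocomp", states = c("x1", "x2"),
                         params = c("k1", "k2"),
                         rhs = c(x1 = "-k1*x1 + u",
                                 x2 = "k1*x1 - k2*x2"),
                         observables = list(y = c(x2 = 1)),
                         stimuli = "u", x0 = c(0, 0))
  space <- parameter_space(c("k1", "k2"), c(k1, k2))
  list(model = model, space = space)
}

## only the sum k1 + k2 enters the dynamics: structurally unidentifiable
sum_only_toy <- function(k1 = 0.3, k2 = 0.7) {
  model <- dynamic_model("sum_only", states = "x", params = c("k1", "k2"),
                         rhs = c(x = "-(k1+k2)*x"),
                         observables = list(y = c(x = 1)), x0 = 1)
  space <- parameter_space(c("k1", "k2"), c(k1, k2))
  list(model = model, space = space)
}

## linear-in-parameter regression through the origin: dx/dt = th, y = x
## (y(t) = th * t; the WLS estimator has a closed-form sd)
linear_toy <- function(th = 2) {
  model <- dynamic_model("linear", states = "x", params = "th",
                         rhs = c(x = "th"),
                         observables = list(y = c(x = 1)), x0 = 0)
  space <- parameter_space("th", th, lower = th / 10, upper = th * 10)
  list(model = model, space = space)
}

## symmetric double-well cost: y depends on th^2 only, two global optima
multimodal_toy <- function(th = 1.5) {
  model <- dynamic_model("bimodal", states = "x", params = "th",
                         rhs = c(x = "-(th*th)*x"),
                         observables = list(y = c(x = 1)), x0 = 1)
  space <- parameter_space("th", th, lower = -3, upper = 3)
  space$lower[] <- -3; space$upper[] <- 3
  list(model = model, space = space)
}

simple_design <- function(times = c(0.5, 1, 2, 4), duration = max(times),
                          observables = "y", noise_rel = 0.1,
                          stim = FALSE) {
  experiment_design(
    "toy_exp",
    stimulus_profile(if (stim) "pulse" else "persistent",
                     switch_times = if (stim) c(0, duration / 2) else 0,
                     duration = duration),
    observables = observables, sampling_times = times,
    noise_rel = noise_rel, noise_floor = 0)
}

## noisy measurements for a toy problem at given truth
toy_measurements <- function(mm, design, theta = NULL, rel = 0.05,
                             floor = 1e-4, seed = 1) {
  theta <- theta %||% mm$space$nominal
  truth <- predict_observables(mm$model, theta, design)
  generate_noisy_replicate(truth, list(rel = rel, floor = floor), seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nfkb_cached <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- build_nfkb_model()
    val
  }
})
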