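#' Define a control-affine dynamic model
#'
#' A `dynamic_model` couples a set of ordinary differential equations,
#' written as text expressions in the state, parameter and stimulus names,
#' with an observation map made of named linear combinations of states.
#' The right-hand side must be linear (affine) in each stimulus so that it
#' decomposes as a drift field plus stimulus-coupled fields; this is the
#' form required by the generating-series identifiability analysis.
#'
#' @param name model identifier.
#' @param states character vector of state names.
#' @param params character vector of parameter names.
#' @param rhs character vector (one per state, same order as `states`) of
#'   R expressions for the time derivatives.
#' @param observables named list; each element is a named numeric vector of
#'   state coefficients defining one observable as a linear combination.
#' @param stimuli character vector of stimulus names entering `rhs`
#'   (affinely); may be empty.
#' @param x0 numeric vector of initial conditions (used when
#'   `x0_policy = "fixed"`); for `"resting"` it seeds the settling run.
#' @param x0_policy `"fixed"` or `"resting"` (unstimulated steady state,
#'   recomputed for each parameter vector).
#' @return an object of class `dynamic_model`.
#' @export
dynamic_model <- function(name, states, params, rhs, observables,
                          stimuli = character(), x0 = NULL,
                          x0_policy = c("fixed", "resting")) {
  x0_policy <- match.arg(x0_policy)
  stopifnot(length(rhs) == length(states), length(observables) >= 1)
  if (is.null(names(observables)) || any(!nzchar(names(observables))))
    stop("observables must be a named list")
  for (ob in observables)
    if (!all(names(ob) %in% states))
      stop("observable refers to unknown state(s)")
  exprs <- lapply(rhs, function(s) parse(text = s)[[1]])
  ## drift: stimuli set to zero; stimulus fields: d rhs / d u_i
  zero_env <- stats::setNames(as.list(rep(0, length(stimuli))), stimuli)
  drift <- lapply(exprs, function(e)
    if (length(stimuli)) do.call(substitute, list(e, zero_env)) else e)
  gfields <- lapply(stimuli, function(u)
    lapply(exprs, function(e) stats::D(e, u)))
  names(gfields) <- stimuli
  if (is.null(x0)) x0 <- rep(0, length(states))
  structure(list(
    name = name, states = states, params = params,
    n_states = length(states), n_params = length(params),
    rhs_exprs = exprs, drift_exprs = drift, gfield_exprs = gfields,
    observables = observables, stimuli = stimuli,
    x0 = stats::setNames(as.numeric(x0), states), x0_policy = x0_policy,
    compiled = NULL, seed_state = NULL, conservation = NULL
  ), class = "dynamic_model")
}

#' @export
print.dynamic_model <- function(x, ...) {
  cat("<dynamic_model>", x$name, "\n")
  cat("  states:     ", x$n_states, "\n")
  cat("  parameters: ", x$n_params, "\n")
  cat("  observables:", paste(names(x$observables), collapse = ", "), "\n")
  cat("  stimuli:    ",
      if (length(x$stimuli)) paste(x$stimuli, collapse = ", ") else "(none)",
      "\n")
  cat("  x0 policy:  ", x$x0_policy, "\n")
  invisible(x)
}

## evaluate rhs at (x, u, theta); vectorised over nothing, plain numeric
model_rhs <- function(model, x, u, theta, t = 0) {
  if (!is.null(model$compiled)) {
    tr <- if (length(u)) u[[1]] else 0
    return(.Call(C_nfkb_rhs, as.numeric(x), as.numeric(tr),
                 as.numeric(theta)))
  }
  uu <- rep(as.numeric(u), length.out = max(length(model$stimuli), 1))
  env <- c(as.list(stats::setNames(as.numeric(x), model$states)),
           as.list(stats::setNames(as.numeric(theta), model$params)),
           as.list(stats::setNames(uu[seq_along(model$stimuli)],
                                   model$stimuli)),
           list(t = t))
  vapply(model$rhs_exprs, function(e) eval(e, env), numeric(1))
}

## drift + sum u_i g_i, reconstructed from the affine decomposition
model_rhs_affine <- function(model, x, u, theta, t = 0) {
  env <- c(as.list(stats::setNames(as.numeric(x), model$states)),
           as.list(stats::setNames(as.numeric(theta), model$params)),
           list(t = t))
  f <- vapply(model$drift_exprs, function(e) eval(e, env), numeric(1))
  if (length(model$stimuli))
    for (i in seq_along(model$stimuli)) {
      g <- vapply(model$gfield_exprs[[i]], function(e) eval(e, env),
                  numeric(1))
      f <- f + u[[i]] * g
    }
  f
}

## numeric state Jacobian (central differences); used for generic models
model_jac_state <- function(model, x, u, theta, h_rel = 1e-6) {
  if (!is.null(model$compiled)) {
    tr <- if (length(u)) u[[1]] else 0
    return(.Call(C_nfkb_jac, as.numeric(x), as.numeric(tr),
                 as.numeric(theta))[[1]])
  }
  n <- model$n_states
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * max(abs(x[j]), 1e-3)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (model_rhs(model, xp, u, theta) -
               model_rhs(model, xm, u, theta)) / (2 * h)
  }
  J
}

model_jac_par <- function(model, x, u, theta, h_rel = 1e-6) {
  if (!is.null(model$compiled)) {
    tr <- if (length(u)) u[[1]] else 0
    return(.Call(C_nfkb_jac, as.numeric(x), as.numeric(tr),
                 as.numeric(theta))[[2]])
  }
  n <- model$n_states
  J <- matrix(0, n, model$n_params)
  for (j in seq_len(model$n_params)) {
    h <- h_rel * max(abs(theta[j]), 1e-10)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (model_rhs(model, x, u, tp) -
               model_rhs(model, x, u, tm)) / (2 * h)
  }
  J
}

#' Describe the feasible parameter space
#'
#' @param names parameter names.
#' @param nominal nominal (reference) values, units as in the model.
#' @param free character vector or logical mask of the parameters to be
#'   estimated; the rest stay fixed at their nominal value.
#' @param lower,upper bounds defining the feasible box; defaults are one
#'   decade around the nominal for the free parameters.
#' @return an object of class `parameter_space`.
#' @export
parameter_space <- function(names, nominal, free = names,
                            lower = NULL, upper = NULL) {
  nominal <- stats::setNames(as.numeric(nominal), names)
  if (is.logical(free)) free <- names[free]
  stopifnot(all(free %in% names))
  if (is.null(lower)) lower <- nominal / 10
  if (is.null(upper)) upper <- nominal * 10
  lower <- stats::setNames(as.numeric(lower), names)
  upper <- stats::setNames(as.numeric(upper), names)
  bad <- free[lower[free] >= upper[free]]
  if (length(bad)) stop("lower >= upper for: ", paste(bad, collapse = ", "))
  out <- nominal < lower | nominal > upper
  if (any(out[free])) stop("nominal outside bounds for: ",
                           paste(names[out & names %in% free], collapse = ", "))
  structure(list(names = names, nominal = nominal, free = free,
                 lower = lower, upper = upper),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space>", length(x$names), "parameters,",
      length(x$free), "free\n")
  df <- data.frame(nominal = x$nominal,
                   free = x$names %in% x$free,
                   lower = x$lower, upper = x$upper)
  print(df, ...)
  invisible(x)
}

## replace the free entries of a full nominal vector
set_free <- function(space, theta_free) {
  th <- space$nominal
  th[names(theta_free)] <- theta_free
  th
}

#' Binary stimulus profile
#'
#' The stimulus signal is 0/1; it toggles at each switch time, starting
#' from 0 before the first one. A persistent stimulation is a single
#' switch at t = 0.
#'
#' @param kind `"persistent"` or `"pulse"`.
#' @param switch_times ordered toggle times (min); for `"persistent"` the
#'   default is a single switch at 0.
#' @param duration experiment duration (min).
#' @param max_pulses cap on the number of pulses (a pulse is an on/off pair).
#' @return object of class `stimulus_profile`.
#' @export
stimulus_profile <- function(kind = c("persistent", "pulse"),
                             switch_times = NULL, duration = 360,
                             max_pulses = 2) {
  kind <- match.arg(kind)
  if (is.null(switch_times))
    switch_times <- if (kind == "persistent") 0 else stop(
      "pulse profile needs switch_times")
  switch_times <- as.numeric(switch_times)
  if (is.unsorted(switch_times, strictly = TRUE))
    stop("switch_times must be strictly increasing")
  if (any(switch_times < 0) || any(switch_times > duration))
    stop("switch_times must lie in [0, duration]")
  if (kind == "pulse" && ceiling(length(switch_times) / 2) > max_pulses)
    stop("too many pulses")
  structure(list(kind = kind, switch_times = switch_times,
                 duration = duration),
            class = "stimulus_profile")
}

## signal value at time t (on when an odd number of switches has occurred)
stimulus_value <- function(profile, t) {
  vapply(t, function(ti) sum(profile$switch_times <= ti) %% 2, numeric(1))
}

#' Experimental design: stimulus, observables, sampling schedule, noise
#'
#' @param name experiment label.
#' @param stimulus a [stimulus_profile()].
#' @param observables character vector of observable names declared in the
#'   model the design will be simulated with.
#' @param sampling_times numeric vector (shared by all observables) or a
#'   named list with one vector per observable, strictly increasing and
#'   within `[0, duration]`.
#' @param noise_rel relative standard deviation of the measurement noise
#'   (fraction of the signal).
#' @param noise_floor absolute noise floor in observable units.
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(name, stimulus, observables, sampling_times,
                              noise_rel = 0.1, noise_floor = 1e-6) {
  if (!is.list(sampling_times))
    sampling_times <- stats::setNames(
      rep(list(as.numeric(sampling_times)), length(observables)),
      observables)
  stopifnot(all(observables %in% names(sampling_times)))
  for (ob in observables) {
    ts <- sampling_times[[ob]]
    if (is.unsorted(ts, strictly = TRUE))
      stop("sampling times must be strictly increasing (", ob, ")")
    if (any(ts < 0) || any(ts > stimulus$duration))
      stop("sampling times outside [0, duration] (", ob, ")")
  }
  if (noise_rel < 0 || noise_floor < 0)
    stop("noise_rel and noise_floor must be non-negative")
  structure(list(name = name, stimulus = stimulus,
                 observables = observables,
                 sampling_times = sampling_times[observables],
                 noise_rel = noise_rel, noise_floor = noise_floor),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>", x$name, "-", x$stimulus$kind,
      "stimulus,", x$stimulus$duration, "min\n")
  cat("  observables:", paste(x$observables, collapse = ", "), "\n")
  cat("  samples/observable:",
      paste(vapply(x$sampling_times, length, integer(1)), collapse = ", "),
      "\n")
  invisible(x)
}

## total number of (observable, time) points in a design (or list of them)
design_n_points <- function(designs) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  sum(vapply(designs, function(d)
    sum(vapply(d$sampling_times, length, integer(1))), numeric(1)))
}
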