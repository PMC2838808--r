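## Simulation of dynamic models: resting state, trajectories with a
## piecewise-constant stimulus (integration restarts at each switch), and
## in-silico measurement generation.

## parameter block layout shared with the compiled NF-kB routines
compiled_parms <- function(theta, tr, free_idx = integer()) {
  pad <- rep(0, 30)
  nf <- length(free_idx)
  if (nf) pad[seq_len(nf)] <- free_idx - 1L
  c(as.numeric(theta), tr, nf, pad)
}

## integrate the plain model over `times` with constant stimulus value
integrate_segment <- function(model, x, times, u, theta,
                              rtol = 1e-8, atol = 1e-12) {
  if (!is.null(model$compiled)) {
    cp <- model$compiled
    out <- deSolve::ode(y = as.numeric(x), times = times, func = cp$func,
                        parms = compiled_parms(theta, u),
                        dllname = cp$dllname, initfunc = cp$initfunc,
                        method = "lsoda", rtol = rtol, atol = atol)
  } else {
    rhsfun <- function(t, y, parms) {
      names(y) <- model$states
      list(model_rhs(model, y, parms$u, parms$theta, t))
    }
    out <- deSolve::ode(y = as.numeric(x), times = times, func = rhsfun,
                        parms = list(u = u, theta = theta),
                        method = "lsoda", rtol = rtol, atol = atol)
  }
  if (attr(out, "istate")[1] < 0) stop("integrator failure")
  m <- unname(out[, -1, drop = FALSE])
  colnames(m) <- model$states
  m
}

#' Unstimulated resting state of a model
#'
#' Integrates the model with all stimuli off for a long settling horizon
#' from the model's seed state, then polishes the end point with damped
#' Newton steps. Conserved directions (zero singular values of the state
#' Jacobian) are held fixed during the polish, so models with mass
#' conservation (such as total NF-kB) stay on their conservation manifold.
#'
#' @param model a [dynamic_model].
#' @param theta full named parameter vector.
#' @param t_settle settling horizon (min).
#' @param tol tolerance on the right-hand-side norm at the returned state.
#' @return named state vector with attribute `rhs_norm`.
#' @export
resting_state <- function(model, theta, t_settle = 1e4, tol = 1e-10) {
  x <- if (model$x0_policy == "resting" && !is.null(model$seed_state))
    model$seed_state(theta) else model$x0
  u <- rep(0, length(model$stimuli))
  consv <- model$conservation
  target <- if (!is.null(consv)) sum(consv * x) else NULL
  traj <- integrate_segment(model, x, c(0, t_settle / 2, t_settle), u, theta,
                            rtol = 1e-10, atol = 1e-14)
  x <- traj[nrow(traj), ]
  ## Newton polish; a known conserved total is re-imposed exactly, other
  ## null directions of the Jacobian are held fixed (pseudo-inverse step)
  for (it in 1:50) {
    f <- model_rhs(model, x, u, theta)
    if (sqrt(sum(f^2)) < tol &&
        (is.null(consv) || abs(sum(consv * x) - target) < tol)) break
    J <- model_jac_state(model, x, u, theta)
    if (!is.null(consv)) {
      dx <- qr.solve(rbind(J, consv), c(-f, target - sum(consv * x)))
    } else {
      sv <- svd(J)
      keep <- sv$d > 1e-10 * max(sv$d)
      dx <- -sv$v[, keep, drop = FALSE] %*%
        ((crossprod(sv$u[, keep, drop = FALSE], f)) / sv$d[keep])
    }
    step <- 1
    repeat {
      xn <- x + step * as.numeric(dx)
      fn <- model_rhs(model, xn, u, theta)
      if (sqrt(sum(fn^2)) < sqrt(sum(f^2)) || step < 1e-4) break
      step <- step / 2
    }
    x <- x + step * as.numeric(dx)
  }
  f <- model_rhs(model, x, u, theta)
  nrm <- sqrt(sum(f^2))
  if (!is.finite(nrm) || nrm > tol)
    stop("resting state did not converge (||rhs|| = ", signif(nrm, 3),
         "); unstimulated dynamics may be oscillatory or divergent")
  names(x) <- model$states
  attr(x, "rhs_norm") <- nrm
  x
}

## stimulus segments of a design: list of (t0, t1, u)
stimulus_segments <- function(stimulus) {
  sw <- stimulus$switch_times
  sw <- sw[sw > 0 & sw < stimulus$duration]
  edges <- c(0, sw, stimulus$duration)
  u0 <- stimulus_value(stimulus, 0)
  lapply(seq_len(length(edges) - 1), function(i)
    list(t0 = edges[i], t1 = edges[i + 1],
         u = stimulus_value(stimulus, (edges[i] + edges[i + 1]) / 2)))
}

#' Simulate a model under an experimental design
#'
#' Solves the ODE system with the design's stimulus profile using a
#' stiff-capable integrator; integration restarts at every stimulus switch
#' time so that the discontinuous signal is handled accurately. Returns
#' both a dense grid and the exact sampling times of the design.
#'
#' On integrator failure a `sim_failure` object carrying `theta` is
#' returned instead of an error, so calibration can penalise rather than
#' crash.
#'
#' @param model a [dynamic_model].
#' @param theta full named parameter vector.
#' @param design an [experiment_design()].
#' @param rtol,atol integrator tolerances.
#' @param dense_n points of the dense output grid.
#' @param x0 optional initial state; defaults to the model's policy
#'   (fixed vector or recomputed resting state).
#' @return object of class `model_trajectory`: `times`, state matrix `x`,
#'   and the design/theta used.
#' @export
simulate_model <- function(model, theta, design, rtol = 1e-8, atol = 1e-12,
                           dense_n = 200, x0 = NULL) {
  theta <- stats::setNames(as.numeric(theta), model$params)
  res <- try({
    if (is.null(x0))
      x0 <- if (model$x0_policy == "resting")
        resting_state(model, theta) else model$x0
    segs <- stimulus_segments(design$stimulus)
    sample_times <- sort(unique(unlist(design$sampling_times)))
    dense <- seq(0, design$stimulus$duration, length.out = dense_n)
    all_t <- sort(unique(c(0, sample_times, dense)))
    xs <- matrix(NA_real_, length(all_t), model$n_states,
                 dimnames = list(NULL, model$states))
    x <- x0
    for (seg in segs) {
      sel <- all_t >= seg$t0 & all_t <= seg$t1
      tseg <- sort(unique(c(seg$t0, all_t[sel], seg$t1)))
      m <- integrate_segment(model, x, tseg, seg$u, theta, rtol, atol)
      xs[sel, ] <- m[match(all_t[sel], tseg), ]
      x <- m[nrow(m), ]
    }
    list(times = all_t, x = xs)
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    return(structure(list(theta = theta, design = design,
                          message = attr(res, "condition")$message),
                     class = "sim_failure"))
  structure(list(times = res$times, x = res$x, theta = theta,
                 design = design, x0 = x0),
            class = "model_trajectory")
}

#' @export
print.model_trajectory <- function(x, ...) {
  cat("<model_trajectory>", x$design$name, "-", length(x$times),
      "time points,", ncol(x$x), "states\n")
  invisible(x)
}

## evaluate one observable (linear state combination) on a state matrix
observable_values <- function(model, obs_name, xmat) {
  w <- model$observables[[obs_name]]
  if (is.null(w)) stop("unknown observable: ", obs_name)
  as.numeric(xmat[, names(w), drop = FALSE] %*% w)
}

#' Noiseless model predictions at the design's sampling times
#'
#' @inheritParams simulate_model
#' @param sim optional precomputed trajectory from [simulate_model()].
#' @return a measurement table (class `measurement_set`): columns
#'   `experiment`, `observable`, `time_min`, `value`, `sd` (NA for
#'   noiseless predictions).
#' @export
predict_observables <- function(model, theta, design, sim = NULL, ...) {
  if (is.null(sim)) sim <- simulate_model(model, theta, design, ...)
  if (inherits(sim, "sim_failure")) return(sim)
  rows <- lapply(design$observables, function(ob) {
    ts <- design$sampling_times[[ob]]
    idx <- match(ts, sim$times)
    if (anyNA(idx)) stop("sampling times missing from trajectory")
    data.frame(experiment = design$name, observable = ob, time_min = ts,
               value = observable_values(model, ob,
                                         sim$x[idx, , drop = FALSE]),
               sd = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("measurement_set", "data.frame"),
            provenance = list(kind = "noiseless", theta = theta))
}

#' Generate a noisy in-silico measurement replicate
#'
#' Adds zero-mean Gaussian noise with heteroscedastic standard deviation
#' `sd = rel * |truth| + floor` to a noiseless measurement table; the
#' generating `sd` is stored alongside each value. Reproducible given the
#' seed.
#'
#' @param noiseless measurement table from [predict_observables()].
#' @param noise_spec list with elements `rel` (relative sd fraction) and
#'   `floor` (absolute floor, observable units).
#' @param seed integer seed.
#' @return a `measurement_set` with noisy `value` and positive `sd`.
#' @export
generate_noisy_replicate <- function(noiseless,
                                     noise_spec = list(rel = 0.1,
                                                       floor = 1e-6),
                                     seed = 1) {
  rel <- noise_spec$rel %||% 0.1
  floor_ <- noise_spec$floor %||% 1e-6
  if (rel < 0 || floor_ < 0) stop("noise rel and floor must be >= 0")
  stopifnot(all(is.finite(noiseless$value)))
  sd <- rel * abs(noiseless$value) + floor_
  out <- noiseless
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  out$value <- noiseless$value + stats::rnorm(nrow(out), 0, sd)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out$sd <- sd
  attr(out, "provenance") <- list(kind = "in-silico", seed = seed,
                                  rel = rel, floor = floor_)
  out
}
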