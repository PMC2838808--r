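## Forward (direct) parametric sensitivities along trajectories: the state
## system is augmented with one column of sensitivity states per free
## parameter and integrated simultaneously. For the built-in NF-kB model
## the augmented right-hand side (analytic state and parameter Jacobians)
## is compiled; generic declarative models use Jacobians derived
## symbolically from the rhs expressions.

## initial sensitivity dx0/dtheta. For "resting" policy this solves the
## stationarity condition Jx * S0 = -Jp on the conservation manifold:
## left-null directions u of Jx (conserved totals) add constraints
## u' S0 = 0, i.e. the conserved totals do not depend on theta.
initial_sensitivity <- function(model, x0, theta, free_idx) {
  n <- model$n_states
  if (model$x0_policy != "resting")
    return(matrix(0, n, length(free_idx)))
  u <- rep(0, length(model$stimuli))
  Jx <- model_jac_state(model, x0, u, theta)
  Jp <- model_jac_par(model, x0, u, theta)[, free_idx, drop = FALSE]
  sv <- svd(Jx)
  null <- sv$d < 1e-9 * max(sv$d)
  A <- Jx
  b <- -Jp
  if (any(null)) {
    A <- rbind(Jx, t(sv$u[, null, drop = FALSE]))
    b <- rbind(-Jp, matrix(0, sum(null), ncol(Jp)))
  }
  qr.solve(A, b)
}

## symbolic Jacobian expressions for generic models (cached on the model)
model_sym_jacs <- function(model) {
  cache <- attr(model, "sym_jacs")
  if (!is.null(cache)) return(cache)
  jx <- lapply(model$rhs_exprs, function(e)
    lapply(model$states, function(s) stats::D(e, s)))
  jp <- lapply(model$rhs_exprs, function(e)
    lapply(model$params, function(p) stats::D(e, p)))
  list(jx = jx, jp = jp)
}

#' Forward sensitivities of states and observables
#'
#' Solves the augmented state + sensitivity system for the free parameter
#' subset, with the same stimulus-discontinuity handling as
#' [simulate_model()] (restart at every switch). The initial sensitivity
#' accounts for the dependence of the resting state on the parameters.
#'
#' @param model a [dynamic_model].
#' @param theta full named parameter vector.
#' @param design an [experiment_design()].
#' @param free character vector of free parameter names.
#' @param rtol,atol integrator tolerances for the augmented system.
#' @return object of class `sensitivity_trajectory`: `times` (the union of
#'   the design's sampling times), `dxdtheta` (array time x state x
#'   parameter), and `dydtheta` (named list per observable of matrices
#'   sampling-time x parameter), plus the sampled observable values `y`.
#' @export
forward_sensitivities <- function(model, theta, design, free,
                                  rtol = 1e-7, atol = 1e-10) {
  theta <- stats::setNames(as.numeric(theta), model$params)
  free_idx <- match(free, model$params)
  if (anyNA(free_idx)) stop("unknown free parameter(s)")
  np <- length(free_idx)
  n <- model$n_states
  x0 <- if (model$x0_policy == "resting") resting_state(model, theta)
        else model$x0
  S0 <- initial_sensitivity(model, x0, theta, free_idx)
  segs <- stimulus_segments(design$stimulus)
  sample_times <- sort(unique(unlist(design$sampling_times)))
  all_t <- sort(unique(c(0, sample_times,
                         vapply(segs, `[[`, numeric(1), "t1"))))
  Y <- matrix(NA_real_, length(all_t), n * (1 + np))
  y <- c(as.numeric(x0), as.numeric(S0))
  if (!is.null(model$compiled)) {
    cp <- model$compiled
    for (seg in segs) {
      sel <- all_t >= seg$t0 & all_t <= seg$t1
      tseg <- sort(unique(c(seg$t0, all_t[sel], seg$t1)))
      out <- deSolve::ode(y = y, times = tseg, func = cp$sensfunc,
                          parms = compiled_parms(theta, seg$u, free_idx),
                          dllname = cp$dllname, initfunc = cp$initfunc,
                          method = "lsoda", rtol = rtol, atol = atol)
      if (attr(out, "istate")[1] < 0)
        return(structure(list(theta = theta, design = design,
                              message = "sensitivity integration failed"),
                         class = "sim_failure"))
      m <- unname(out[, -1, drop = FALSE])
      Y[sel, ] <- m[match(all_t[sel], tseg), ]
      y <- m[nrow(m), ]
    }
  } else {
    jacs <- model_sym_jacs(model)
    augfun <- function(t, y, parms) {
      x <- stats::setNames(y[seq_len(n)], model$states)
      S <- matrix(y[-seq_len(n)], n, np)
      env <- c(as.list(x),
               as.list(stats::setNames(theta, model$params)),
               as.list(stats::setNames(rep(parms$u, length.out =
                 length(model$stimuli)), model$stimuli)), list(t = t))
      f <- vapply(model$rhs_exprs, function(e) eval(e, env), numeric(1))
      Jx <- t(vapply(jacs$jx, function(row)
        vapply(row, function(e) eval(e, env), numeric(1)), numeric(n)))
      Jp <- t(vapply(jacs$jp, function(row)
        vapply(row[free_idx], function(e) eval(e, env), numeric(1)),
        numeric(np)))
      if (np == 1) Jp <- matrix(Jp, n, 1)
      list(c(f, as.numeric(Jx %*% S + Jp)))
    }
    for (seg in segs) {
      sel <- all_t >= seg$t0 & all_t <= seg$t1
      tseg <- sort(unique(c(seg$t0, all_t[sel], seg$t1)))
      out <- try(deSolve::ode(y = y, times = tseg, func = augfun,
                              parms = list(u = seg$u), method = "lsoda",
                              rtol = rtol, atol = atol), silent = TRUE)
      if (inherits(out, "try-error") || attr(out, "istate")[1] < 0)
        return(structure(list(theta = theta, design = design,
                              message = "sensitivity integration failed"),
                         class = "sim_failure"))
      m <- unname(out[, -1, drop = FALSE])
      Y[sel, ] <- m[match(all_t[sel], tseg), ]
      y <- m[nrow(m), ]
    }
  }
  dxd <- array(Y[, -seq_len(n), drop = FALSE],
               dim = c(length(all_t), n, np),
               dimnames = list(NULL, model$states, free))
  xmat <- Y[, seq_len(n), drop = FALSE]
  colnames(xmat) <- model$states
  dyd <- list(); yval <- list()
  for (ob in design$observables) {
    w <- model$observables[[ob]]
    ts <- design$sampling_times[[ob]]
    idx <- match(ts, all_t)
    sens <- matrix(0, length(ts), np, dimnames = list(NULL, free))
    for (s in names(w))
      sens <- sens + w[[s]] * dxd[idx, s, , drop = FALSE][, 1, ]
    if (length(ts) == 1) sens <- matrix(sens, 1, np,
                                        dimnames = list(NULL, free))
    dyd[[ob]] <- sens
    yval[[ob]] <- as.numeric(xmat[idx, names(w), drop = FALSE] %*% w)
  }
  structure(list(times = all_t, x = xmat, dxdtheta = dxd, dydtheta = dyd,
                 y = yval, free = free, theta = theta, design = design),
            class = "sensitivity_trajectory")
}

#' Relative (dimensionless) sensitivities
#'
#' `s_rel = theta_j / max(|y|, floor) * dy/dtheta_j`. The floor guards the
#' normalisation where the observable crosses zero.
#'
#' @param sens a `sensitivity_trajectory` from [forward_sensitivities()].
#' @param floor lower bound on `|y|` used in the normalisation
#'   (observable units).
#' @return list per observable of matrices sampling-time x parameter,
#'   class `relative_sensitivity`.
#' @export
relative_sensitivities <- function(sens, floor = 1e-8) {
  if (inherits(sens, "sim_failure")) return(sens)
  th <- sens$theta[sens$free]
  out <- lapply(names(sens$dydtheta), function(ob) {
    dy <- sens$dydtheta[[ob]]
    denom <- pmax(abs(sens$y[[ob]]), floor)
    sweep(dy / denom, 2, th, "*")
  })
  names(out) <- names(sens$dydtheta)
  structure(out, class = "relative_sensitivity", free = sens$free)
}

## finite-difference observable sensitivities (test oracle and fallback);
## recomputes the resting state at each perturbed theta
fd_observable_sensitivities <- function(model, theta, design, free,
                                        rel_step = 1e-5, rtol = 1e-9,
                                        atol = 1e-13) {
  theta <- stats::setNames(as.numeric(theta), model$params)
  base <- lapply(free, function(p) NULL)
  out <- NULL
  for (k in seq_along(free)) {
    h <- rel_step * max(abs(theta[[free[k]]]), 1e-12)
    tp <- theta; tp[free[k]] <- tp[free[k]] + h
    tm <- theta; tm[free[k]] <- tm[free[k]] - h
    pp <- predict_observables(model, tp, design, rtol = rtol, atol = atol)
    pm <- predict_observables(model, tm, design, rtol = rtol, atol = atol)
    d <- (pp$value - pm$value) / (2 * h)
    if (is.null(out))
      out <- data.frame(observable = pp$observable, time_min = pp$time_min)
    out[[free[k]]] <- d
  }
  out
}
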