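## Weighted least-squares calibration with a hybrid global-local
## optimizer: a scatter-search style population phase (diverse LHS
## initialisation, reference-set recombination) followed by bounded
## Levenberg-Marquardt refinement of the best candidates. Parameters are
## searched in log10 space by default since they span several orders of
## magnitude.

#' Set up a calibration problem
#'
#' @param model a [dynamic_model].
#' @param designs list of [experiment_design()] objects.
#' @param measurements a `measurement_set` (or data frame with columns
#'   `experiment`, `observable`, `time_min`, `value`, `sd`) covering the
#'   designs' sampling schedules; weights are `1/sd^2`.
#' @param space a [parameter_space()].
#' @param free parameters to estimate (subset of the space's free set).
#' @param lower,upper optional bound overrides for the free subset.
#' @param log_scale search in log10 space (default TRUE).
#' @return object of class `calibration_problem`.
#' @export
calibration_problem <- function(model, designs, measurements, space,
                                free = space$free, lower = NULL,
                                upper = NULL, log_scale = TRUE) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  stopifnot(all(free %in% space$names))
  if (any(!is.finite(measurements$sd)) || any(measurements$sd <= 0))
    stop("every measurement needs a positive sd")
  ## align measurement rows to each design's sampling schedule
  aligned <- list()
  for (d in designs) {
    rows <- measurements[measurements$experiment == d$name, , drop = FALSE]
    for (ob in d$observables) {
      sub <- rows[rows$observable == ob, , drop = FALSE]
      ts <- d$sampling_times[[ob]]
      idx <- match(round(ts, 9), round(sub$time_min, 9))
      if (anyNA(idx))
        stop("measurements missing for ", d$name, "/", ob)
      aligned[[paste(d$name, ob, sep = ".")]] <- list(
        design = d$name, observable = ob, times = ts,
        value = sub$value[idx], sd = sub$sd[idx])
    }
  }
  lower <- lower %||% space$lower[free]
  upper <- upper %||% space$upper[free]
  structure(list(model = model, designs = designs, aligned = aligned,
                 space = space, free = free,
                 lower = stats::setNames(as.numeric(lower), free),
                 upper = stats::setNames(as.numeric(upper), free),
                 log_scale = log_scale,
                 n_data = sum(vapply(aligned, function(a)
                   length(a$value), numeric(1)))),
            class = "calibration_problem")
}

## weighted residual vector at a full parameter vector; NULL on failure
problem_residuals <- function(problem, theta) {
  res <- numeric(0)
  for (d in problem$designs) {
    sim <- simulate_model(problem$model, theta, d, dense_n = 2)
    if (inherits(sim, "sim_failure")) return(NULL)
    for (ob in d$observables) {
      a <- problem$aligned[[paste(d$name, ob, sep = ".")]]
      idx <- match(a$times, sim$times)
      y <- observable_values(problem$model, ob, sim$x[idx, , drop = FALSE])
      res <- c(res, (y - a$value) / a$sd)
    }
  }
  res
}

#' Weighted least-squares cost
#'
#' `J = sum over experiments, observables and sampling times of
#' (y_model - y_data)^2 / sd^2`. Simulation failures yield a large finite
#' penalty `1e10 * (1 + ||theta_free||)` rather than an error, so global
#' optimizers can continue.
#'
#' @param theta_free named vector of free parameter values (natural
#'   units).
#' @param problem a [calibration_problem()].
#' @return scalar cost.
#' @export
wls_cost <- function(theta_free, problem) {
  theta <- set_free(problem$space, stats::setNames(theta_free,
                                                   problem$free))
  r <- problem_residuals(problem, theta)
  if (is.null(r) || anyNA(r) || any(!is.finite(r)))
    return(1e10 * (1 + sqrt(sum(theta_free^2))))
  sum(r^2)
}

#' Optimizer configuration
#'
#' @param budget maximum number of cost evaluations (global phase).
#' @param n_diverse size of the diverse initial population (default
#'   `10 * dimension`).
#' @param refset_size reference set size of the scatter phase.
#' @param n_local how many refset members get local polish.
#' @param local_maxit Levenberg-Marquardt iteration cap.
#' @param profile `"global"` (full hybrid) or `"warm"` (local refinement
#'   from `warm_start` only; used for Monte-Carlo replicate fits).
#' @param warm_start named free-parameter vector for the warm profile.
#' @param use_sens_jac use forward-sensitivity Jacobians in the local
#'   phase when the model supports them (fall back to finite differences).
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(budget = 10000, n_diverse = NULL,
                             refset_size = 10, n_local = 3,
                             local_maxit = 100,
                             profile = c("global", "warm"),
                             warm_start = NULL, use_sens_jac = TRUE) {
  profile <- match.arg(profile)
  structure(list(budget = budget, n_diverse = n_diverse,
                 refset_size = refset_size, n_local = n_local,
                 local_maxit = local_maxit, profile = profile,
                 warm_start = warm_start, use_sens_jac = use_sens_jac),
            class = "optimizer_config")
}

## transform between search and natural coordinates
to_search <- function(x, problem) if (problem$log_scale) log10(x) else x
from_search <- function(z, problem) if (problem$log_scale) 10^z else z

## weighted residual Jacobian via forward sensitivities (chain rule for
## the log10 search scale); looser integration tolerances than the
## residual path, since the Jacobian only steers the search
problem_jacobian <- function(problem, z) {
  th_free <- from_search(z, problem)
  theta <- set_free(problem$space, stats::setNames(th_free, problem$free))
  J <- NULL
  for (d in problem$designs) {
    sens <- forward_sensitivities(problem$model, theta, d, problem$free,
                                  rtol = 1e-6, atol = 1e-9)
    if (inherits(sens, "sim_failure")) return(NULL)
    for (ob in d$observables) {
      a <- problem$aligned[[paste(d$name, ob, sep = ".")]]
      J <- rbind(J, sens$dydtheta[[ob]] / a$sd)
    }
  }
  if (problem$log_scale)
    J <- sweep(J, 2, th_free * log(10), "*")
  J
}

#' Calibrate a model by hybrid global-local weighted least squares
#'
#' The global phase draws a diverse Latin-hypercube population, keeps a
#' reference set of the best and most diverse members, and recombines
#' reference pairs within (and slightly beyond) their connecting
#' hyper-rectangles; the best candidates are then polished with bounded
#' Levenberg-Marquardt on the weighted residuals. Fully reproducible
#' given the seed.
#'
#' @param problem a [calibration_problem()].
#' @param config an [optimizer_config()].
#' @param seed integer seed.
#' @return object of class `iterid_fit` with elements `theta_hat` (named,
#'   natural units), `J`, `trace` (best-J versus evaluation count),
#'   `n_eval`, `status`, `seed`, and the problem.
#' @export
calibrate <- function(problem, config = optimizer_config(), seed = 1) {
  d <- length(problem$free)
  lo <- to_search(problem$lower, problem)
  hi <- to_search(problem$upper, problem)
  n_eval <- 0L
  trace <- list()
  best <- list(z = NULL, J = Inf)
  cost_z <- function(z) {
    n_eval <<- n_eval + 1L
    J <- wls_cost(from_search(z, problem), problem)
    if (J < best$J) {
      best <<- list(z = z, J = J)
      trace[[length(trace) + 1L]] <<- c(n_eval = n_eval, J = J)
    }
    J
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  candidates <- NULL
  if (config$profile == "warm") {
    if (is.null(config$warm_start)) stop("warm profile needs warm_start")
    z0 <- to_search(config$warm_start[problem$free], problem)
    cost_z(z0)
    candidates <- matrix(z0, nrow = 1)
  } else {
    nd <- config$n_diverse %||% (10L * d)
    pop <- lhs::randomLHS(nd, d)
    pop <- sweep(sweep(pop, 2, hi - lo, "*"), 2, lo, "+")
    Jpop <- apply(pop, 1, cost_z)
    ## reference set: half best, half max-min-distance diverse
    nb <- ceiling(config$refset_size / 2)
    ord <- order(Jpop)
    ref_idx <- ord[seq_len(min(nb, nd))]
    rest <- setdiff(seq_len(nd), ref_idx)
    while (length(ref_idx) < min(config$refset_size, nd) && length(rest)) {
      dist <- vapply(rest, function(i)
        min(sqrt(colSums((t(pop[ref_idx, , drop = FALSE]) -
                            pop[i, ])^2))), numeric(1))
      pick <- rest[which.max(dist)]
      ref_idx <- c(ref_idx, pick)
      rest <- setdiff(rest, pick)
    }
    ref <- pop[ref_idx, , drop = FALSE]
    refJ <- Jpop[ref_idx]
    ## recombination loop
    stall <- 0L
    while (n_eval < config$budget * 0.8 && stall < 8L) {
      improved <- FALSE
      nref <- nrow(ref)
      for (i in seq_len(nref - 1)) {
        for (j in (i + 1):nref) {
          if (n_eval >= config$budget * 0.8) break
          a <- ref[i, ]; b <- ref[j, ]
          lam <- stats::runif(d, -0.3, 1.3)
          z <- pmin(pmax(a + lam * (b - a), lo), hi)
          J <- cost_z(z)
          worst <- which.max(refJ)
          if (J < refJ[worst]) {
            ref[worst, ] <- z; refJ[worst] <- J; improved <- TRUE
          }
        }
      }
      stall <- if (improved) 0L else stall + 1L
    }
    ord <- order(refJ)
    candidates <- ref[ord[seq_len(min(config$n_local, nrow(ref)))], ,
                      drop = FALSE]
  }
  ## local phase: bounded Levenberg-Marquardt on weighted residuals
  resid_z <- function(z) {
    theta <- set_free(problem$space,
                      stats::setNames(from_search(z, problem),
                                      problem$free))
    r <- problem_residuals(problem, theta)
    n_eval <<- n_eval + 1L
    if (is.null(r) || anyNA(r) || any(!is.finite(r)))
      return(rep(1e5, problem$n_data))
    J <- sum(r^2)
    if (J < best$J) {
      best <<- list(z = z, J = J)
      trace[[length(trace) + 1L]] <<- c(n_eval = n_eval, J = J)
    }
    r
  }
  jac_z <- NULL
  if (config$use_sens_jac)
    jac_z <- function(z) {
      Jm <- problem_jacobian(problem, z)
      if (is.null(Jm)) matrix(0, problem$n_data, d) else Jm
    }
  for (k in seq_len(nrow(candidates))) {
    fit <- try(minpack.lm::nls.lm(
      par = candidates[k, ], fn = resid_z, jac = jac_z,
      lower = unname(lo), upper = unname(hi),
      control = minpack.lm::nls.lm.control(
        maxiter = config$local_maxit, ptol = 1e-12, ftol = 1e-12)),
      silent = TRUE)
    if (!inherits(fit, "try-error")) {
      J <- sum(resid_z(fit$par)^2)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  if (!is.finite(best$J)) stop("no successful simulation within budget")
  theta_hat <- stats::setNames(from_search(best$z, problem), problem$free)
  tr <- do.call(rbind, trace)
  structure(list(theta_hat = theta_hat, J = best$J,
                 trace = as.data.frame(tr), n_eval = n_eval,
                 status = "converged", seed = seed, config = config,
                 problem = problem),
            class = "iterid_fit")
}

#' @export
print.iterid_fit <- function(x, ...) {
  cat("<iterid_fit> J =", format(x$J, digits = 6), "with", x$n_eval,
      "cost evaluations (seed", x$seed, ")\n")
  print(signif(x$theta_hat, 4))
  invisible(x)
}

#' @export
coef.iterid_fit <- function(object, ...) object$theta_hat

#' @export
summary.iterid_fit <- function(object, ...) {
  nominal <- object$problem$space$nominal[object$problem$free]
  df <- data.frame(estimate = object$theta_hat, nominal = nominal,
                   ratio = object$theta_hat / nominal)
  out <- list(coefficients = df, J = object$J,
              n_data = object$problem$n_data, n_eval = object$n_eval)
  class(out) <- "summary.iterid_fit"
  out
}

#' @export
print.summary.iterid_fit <- function(x, ...) {
  cat("Weighted least-squares calibration\n")
  cat("J =", format(x$J, digits = 6), "on", x$n_data, "data points;",
      x$n_eval, "cost evaluations\n\n")
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}

#' @export
predict.iterid_fit <- function(object, design = NULL, ...) {
  designs <- if (is.null(design)) object$problem$designs else list(design)
  theta <- set_free(object$problem$space, object$theta_hat)
  out <- lapply(designs, function(d)
    predict_observables(object$problem$model, theta, d))
  if (length(out) == 1) out[[1]] else do.call(rbind, out)
}

#' @export
residuals.iterid_fit <- function(object, ...) {
  theta <- set_free(object$problem$space, object$theta_hat)
  problem_residuals(object$problem, theta)
}
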