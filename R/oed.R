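## Fisher-information based optimal experimental design: the information
## of a candidate experiment is the noise-weighted sum of outer products
## of the observable parameter-sensitivities over all sampling points;
## designs (pulse switch times, duration, sampling times) are optimised
## for the D- (determinant) or E- (minimum eigenvalue) criterion with a
## seeded evolutionary search and constraint repair, optionally on top of
## the accumulated information of earlier experiments
## (parallel-sequential design).

#' Fisher information matrix of an experimental scheme
#'
#' `F = sum_s s_s s_s^T / sigma_s^2` with `s_s = dy/dtheta` at sampling
#' point s and `sigma_s = rel * |y_s| + floor` from the noise model
#' applied to the predicted signals. Several designs' information adds.
#'
#' @param model a [dynamic_model].
#' @param mu full parameter vector at which the information is evaluated
#'   (the current best estimate).
#' @param design one [experiment_design()] or a list of them.
#' @param free free parameter subset.
#' @param noise_spec list `rel`/`floor`; defaults to each design's own
#'   noise settings.
#' @return matrix of class `fim` with attribute `provenance`.
#' @export
fisher_information <- function(model, mu, design, free,
                               noise_spec = NULL) {
  designs <- if (inherits(design, "experiment_design")) list(design)
             else design
  p <- length(free)
  F <- matrix(0, p, p, dimnames = list(free, free))
  for (d in designs) {
    rel <- noise_spec$rel %||% d$noise_rel
    floor_ <- noise_spec$floor %||% d$noise_floor
    sens <- forward_sensitivities(model, mu, d, free)
    if (inherits(sens, "sim_failure"))
      stop("simulation failed at mu for design ", d$name)
    for (ob in d$observables) {
      dy <- sens$dydtheta[[ob]]
      sigma <- rel * abs(sens$y[[ob]]) + floor_
      for (s in seq_len(nrow(dy)))
        F <- F + tcrossprod(dy[s, ]) / sigma[s]^2
    }
  }
  structure(F, class = c("fim", "matrix"),
            provenance = list(mu = mu, free = free,
                              scheme = vapply(designs, `[[`,
                                              character(1), "name")))
}

#' Scalar design criteria of a Fisher information matrix
#'
#' @param F symmetric information matrix.
#' @param kind `"E"` (minimum eigenvalue) or `"D"` (determinant).
#' @return scalar criterion value (to be maximised).
#' @export
design_criterion <- function(F, kind = c("E", "D")) {
  kind <- match.arg(kind)
  ev <- eigen((F + t(F)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (kind == "E") min(ev) else prod(ev)
}

#' Parameter uncertainties predicted from a Fisher information matrix
#'
#' Cramer-Rao bound: standard deviations are the square roots of the
#' diagonal of the inverse information; correlations come from the
#' off-diagonal entries. A singular information matrix is flagged and
#' handled with the pseudo-inverse (infinite uncertainty along null
#' directions).
#'
#' @param F information matrix (class `fim` or plain).
#' @return list: `sd` (named), `correlation` matrix, `singular` flag.
#' @export
predicted_uncertainty_from_fim <- function(F) {
  Fs <- (F + t(F)) / 2
  eig <- eigen(Fs, symmetric = TRUE)
  tol <- 1e-12 * max(abs(eig$values))
  singular <- any(eig$values <= tol)
  inv_vals <- ifelse(eig$values > tol, 1 / eig$values, Inf)
  finite <- is.finite(inv_vals)
  cov <- eig$vectors[, finite, drop = FALSE] %*%
    diag(inv_vals[finite], sum(finite)) %*%
    t(eig$vectors[, finite, drop = FALSE])
  sd <- sqrt(diag(cov))
  if (singular) {
    null_v <- eig$vectors[, !finite, drop = FALSE]
    touched <- rowSums(abs(null_v)) > 1e-10
    sd[touched] <- Inf
  }
  denom <- outer(sd, sd)
  corr <- ifelse(is.finite(denom) & denom > 0, cov / denom, NA_real_)
  diag(corr) <- 1
  names(sd) <- rownames(F)
  dimnames(corr) <- dimnames(F)
  list(sd = sd, correlation = corr, singular = singular)
}

## decode a unit-cube decision vector into an experiment design
decode_design <- function(z, constraints, model) {
  dur_rg <- constraints$dur_range
  dur <- dur_rg[1] + z[1] * (dur_rg[2] - dur_rg[1])
  n_sw <- 2 * constraints$max_pulses
  sw <- sort(z[1 + seq_len(n_sw)]) * dur
  ## repair: enforce minimum pulse width by pushing later switches forward
  for (k in seq_along(sw)[-1])
    sw[k] <- max(sw[k], sw[k - 1] + constraints$min_gap)
  sw <- sw[sw < dur]
  if (length(sw) == 0) sw <- 0
  ts <- sort(z[1 + n_sw + seq_len(constraints$max_samples)]) * dur
  ts[1] <- max(ts[1], constraints$min_gap)
  for (k in seq_along(ts)[-1])
    ts[k] <- max(ts[k], ts[k - 1] + constraints$min_gap)
  ts <- unique(pmin(ts, dur))
  experiment_design(
    name = constraints$name %||% "oed_design",
    stimulus = stimulus_profile("pulse", switch_times = sw,
                                duration = dur,
                                max_pulses = constraints$max_pulses),
    observables = constraints$observables,
    sampling_times = ts,
    noise_rel = constraints$noise_rel %||% 0.1,
    noise_floor = constraints$noise_floor %||% 1e-6)
}

#' Optimise a dynamic experiment for information content
#'
#' Maximises `criterion(F_prior + F(design))` over the design variables:
#' experiment duration, up to `max_pulses` stimulus pulses (encoded as
#' ordered switch times with repair) and up to `max_samples` sampling
#' times (encoded as positive gaps with minimum spacing). The search is a
#' seeded (mu + lambda) evolutionary strategy, suited to the non-smooth
#' E-criterion.
#'
#' @param model a [dynamic_model].
#' @param mu parameter vector at which information is evaluated.
#' @param free free parameter subset.
#' @param prior_fim information of already-performed experiments (0 for
#'   none).
#' @param criterion `"E"` or `"D"`.
#' @param constraints list: `observables`, `max_pulses` (default 2),
#'   `max_samples` (default 15), `dur_range` (min, default c(120, 480)),
#'   `min_gap` (default 1 min), `noise_rel`, `noise_floor`, `name`.
#' @param budget criterion evaluations.
#' @param pop population size.
#' @param seed integer seed.
#' @return object of class `oed_result`: `design`, `value`, `prior_value`,
#'   `fim` (total), `predicted` (CRLB uncertainties), `trace`, `flat`
#'   (flag: objective nearly constant, prior information dominates).
#' @export
optimize_design <- function(model, mu, free, prior_fim = NULL,
                            criterion = c("E", "D"),
                            constraints = list(), budget = 2000,
                            pop = 24, seed = 1) {
  criterion <- match.arg(criterion)
  constraints$max_pulses <- constraints$max_pulses %||% 2L
  constraints$max_samples <- constraints$max_samples %||% 15L
  constraints$dur_range <- constraints$dur_range %||% c(120, 480)
  constraints$min_gap <- constraints$min_gap %||% 1
  if (is.null(constraints$observables))
    stop("constraints$observables is required")
  if (constraints$dur_range[1] >= constraints$dur_range[2] ||
      constraints$max_samples < 1 || constraints$max_pulses < 1)
    stop("infeasible design constraints")
  p <- length(free)
  if (is.null(prior_fim)) prior_fim <- matrix(0, p, p,
                                              dimnames = list(free, free))
  nz <- 1 + 2 * constraints$max_pulses + constraints$max_samples
  evals <- 0L
  score <- function(z) {
    evals <<- evals + 1L
    des <- try(decode_design(z, constraints, model), silent = TRUE)
    if (inherits(des, "try-error")) return(-Inf)
    F <- try(fisher_information(model, mu, des, free), silent = TRUE)
    if (inherits(F, "try-error")) return(-Inf)
    design_criterion(unclass(prior_fim) + unclass(F), criterion)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  P <- matrix(stats::runif(pop * nz), pop, nz)
  val <- apply(P, 1, score)
  trace <- data.frame(eval = evals, best = max(val))
  while (evals < budget) {
    ord <- order(-val)
    elite <- P[ord[seq_len(ceiling(pop / 2))], , drop = FALSE]
    n_off <- pop - nrow(elite)
    off <- matrix(0, n_off, nz)
    for (k in seq_len(n_off)) {
      pick <- sample(nrow(elite), 2)
      w <- stats::runif(1)
      child <- w * elite[pick[1], ] + (1 - w) * elite[pick[2], ]
      child <- child + stats::rnorm(nz, 0, 0.08)
      off[k, ] <- pmin(pmax(child, 0), 1)
    }
    voff <- apply(off, 1, score)
    P <- rbind(elite, off)
    val <- c(val[ord[seq_len(nrow(elite))]], voff)
    trace <- rbind(trace, data.frame(eval = evals, best = max(val)))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  bi <- which.max(val)
  best_design <- decode_design(P[bi, ], constraints, model)
  Fnew <- fisher_information(model, mu, best_design, free)
  total <- unclass(prior_fim) + unclass(Fnew)
  prior_value <- design_criterion(unclass(prior_fim), criterion)
  spread <- stats::sd(val[rank(-val) <= max(3, pop / 4)]) /
    max(abs(max(val)), 1e-300)
  structure(list(design = best_design, value = max(val),
                 prior_value = prior_value,
                 fim = structure(total, dimnames = list(free, free)),
                 new_fim = Fnew,
                 predicted = predicted_uncertainty_from_fim(total),
                 trace = trace, criterion = criterion, seed = seed,
                 flat = is.finite(spread) && spread < 1e-6 &&
                        prior_value > 0 &&
                        (max(val) - prior_value) < 1e-3 * prior_value),
            class = "oed_result")
}

#' @export
print.oed_result <- function(x, ...) {
  cat("<oed_result>", x$criterion, "criterion:",
      format(x$value, digits = 5), "\n")
  st <- x$design$stimulus
  cat("  duration:", round(st$duration, 1), "min; switch times:",
      paste(round(st$switch_times, 1), collapse = ", "), "\n")
  cat("  sampling times:",
      paste(round(x$design$sampling_times[[1]], 1), collapse = ", "),
      "\n")
  if (x$flat) cat("  note: objective nearly flat",
                  "(prior information dominates)\n")
  invisible(x)
}
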