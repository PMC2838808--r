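## Practical identifiability by Monte-Carlo replicate calibration: many
## noisy pseudo-replicates of an experimental scheme are generated and
## re-fitted; the cloud of estimates is trimmed to its per-coordinate
## [0.05, 0.95] quantile box, normalised, and summarised through a
## principal-axis (hyper-ellipsoid) fit, per-parameter expected
## uncertainties, pairwise eccentricities and a pseudo-volume.

#' Construct a solution cloud from a matrix of replicate estimates
#'
#' @param estimates matrix (replicates x parameters) with column names.
#' @param J optional per-replicate cost values.
#' @param meta optional provenance list.
#' @return object of class `solution_cloud`.
#' @export
solution_cloud <- function(estimates, J = NULL, meta = list()) {
  structure(list(estimates = as.matrix(estimates), J = J, meta = meta,
                 n_requested = meta$n_requested %||% nrow(estimates)),
            class = "solution_cloud")
}

#' @export
print.solution_cloud <- function(x, ...) {
  cat("<solution_cloud>", nrow(x$estimates), "replicates x",
      ncol(x$estimates), "parameters\n")
  invisible(x)
}

#' Monte-Carlo cloud of replicate calibrations
#'
#' A-priori mode: noiseless data are generated at `theta_true`, and each
#' replicate adds fresh seeded heteroscedastic Gaussian noise before
#' re-calibration (warm-started at the truth by default, the scaled-down
#' replicate profile). A-posteriori mode (`data` given instead of
#' `theta_true`): the scheme is first calibrated, noise is resampled
#' around the fitted predictions with the residual-estimated (stored)
#' noise levels, and the replicates are warm-started at the fit.
#'
#' Replicate seeds are derived from the master seed alone, so results are
#' independent of execution order.
#'
#' @param model a [dynamic_model].
#' @param designs list of [experiment_design()] objects (the scheme).
#' @param space a [parameter_space()].
#' @param free parameters estimated per replicate.
#' @param theta_true full parameter vector generating the data (a-priori
#'   mode); `NULL` for a-posteriori mode.
#' @param data measured `measurement_set` (a-posteriori mode).
#' @param n_reps number of replicates.
#' @param noise_spec list `rel`/`floor` for the noise generator.
#' @param config [optimizer_config()] for the replicate fits; default is
#'   the warm profile started at the generating parameters.
#' @param master_seed master seed.
#' @return a `solution_cloud`; failed replicates are dropped (an error is
#'   raised if fewer than half succeed).
#' @export
monte_carlo_cloud <- function(model, designs, space, free,
                              theta_true = NULL, data = NULL,
                              n_reps = 200,
                              noise_spec = list(rel = 0.1, floor = 1e-6),
                              config = NULL, master_seed = 1) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  if (is.null(theta_true) && is.null(data))
    stop("either theta_true (a priori) or data (a posteriori) is needed")
  mode <- if (is.null(data)) "a priori" else "a posteriori"
  if (mode == "a posteriori") {
    prob0 <- calibration_problem(model, designs, data, space, free = free)
    fit0 <- calibrate(prob0, optimizer_config(), seed = master_seed)
    theta_center <- set_free(space, fit0$theta_hat)
  } else {
    theta_center <- stats::setNames(as.numeric(theta_true), space$names)
  }
  noiseless <- lapply(designs, function(d)
    predict_observables(model, theta_center, d))
  if (any(vapply(noiseless, inherits, logical(1), "sim_failure")))
    stop("simulation failed at the generating parameters")
  if (is.null(config))
    config <- optimizer_config(profile = "warm",
                               warm_start = theta_center[free],
                               local_maxit = 40)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(master_seed)
  rep_seeds <- sample.int(2^31 - 2, n_reps)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  est <- matrix(NA_real_, n_reps, length(free),
                dimnames = list(NULL, free))
  Jv <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    noisy <- do.call(rbind, lapply(seq_along(noiseless), function(k)
      generate_noisy_replicate(noiseless[[k]], noise_spec,
                               seed = rep_seeds[r] %% (2^31 - 10) + k)))
    fit <- try({
      prob <- calibration_problem(model, designs, noisy, space,
                                  free = free)
      calibrate(prob, config, seed = rep_seeds[r])
    }, silent = TRUE)
    if (!inherits(fit, "try-error")) {
      est[r, ] <- fit$theta_hat
      Jv[r] <- fit$J
    }
  }
  ok <- !is.na(Jv)
  if (sum(ok) < n_reps / 2)
    stop("only ", sum(ok), " of ", n_reps, " replicates succeeded")
  solution_cloud(est[ok, , drop = FALSE], Jv[ok],
                 meta = list(mode = mode, master_seed = master_seed,
                             noise_spec = noise_spec,
                             theta_center = theta_center,
                             n_requested = n_reps,
                             scheme = vapply(designs, `[[`, character(1),
                                             "name")))
}

#' Trim a solution cloud and fit its principal-axis ellipsoid
#'
#' Rows outside any coordinate's [0.05, 0.95] quantile interval are
#' trimmed (robust to estimates piled at the bounds); the remaining rows
#' are normalised by their per-coordinate means so the ellipsoid is
#' scale-free, and a principal-component decomposition gives the
#' principal axes. Pairwise eccentricities measure parameter
#' correlation: they are axis ratios of the 2-D sub-ellipses on
#' sd-normalised (correlation) coordinates, sqrt((1+|r|)/(1-|r|)) for
#' correlation r, capped at 1e3 and flagged degenerate beyond -- so a
#' pair is eccentric because its estimates co-vary, not because the two
#' parameters are determined with different precision.
#'
#' @param cloud a `solution_cloud` (at least 20 rows).
#' @param probs trimming quantiles.
#' @param ecc_cap cap for degenerate (perfectly correlated) pairs.
#' @return object of class `ellipsoid_fit`: `axes` (orthonormal columns),
#'   `lengths` (semi-axis lengths, descending), `ecc` (pairwise matrix),
#'   `degenerate` (logical matrix), `trimmed` (the trimmed sub-cloud),
#'   `center` (trimmed means), `q` (the quantile box).
#' @export
trim_and_fit <- function(cloud, probs = c(0.05, 0.95), ecc_cap = 1e3) {
  X <- cloud$estimates
  if (nrow(X) < 20) stop("need at least 20 replicates")
  q <- apply(X, 2, stats::quantile, probs = probs, names = FALSE)
  inside <- rep(TRUE, nrow(X))
  for (j in seq_len(ncol(X)))
    inside <- inside & X[, j] >= q[1, j] & X[, j] <= q[2, j]
  Xt <- X[inside, , drop = FALSE]
  mu <- colMeans(Xt)
  sc <- ifelse(abs(mu) > 0, abs(mu), 1)
  Z <- sweep(Xt, 2, sc, "/")
  Zc <- sweep(Z, 2, colMeans(Z), "-")
  C <- stats::cov(Zc)
  eig <- eigen(C, symmetric = TRUE)
  lengths <- sqrt(pmax(eig$values, 0))
  p <- ncol(X)
  ecc <- matrix(1, p, p, dimnames = list(colnames(X), colnames(X)))
  degen <- matrix(FALSE, p, p, dimnames = dimnames(ecc))
  R <- suppressWarnings(stats::cor(Zc))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    v1 <- C[i, i]; v2 <- C[j, j]
    e <- if (v1 <= 0 || v2 <= 0) Inf else {
      ev <- eigen(R[c(i, j), c(i, j)], symmetric = TRUE,
                  only.values = TRUE)$values
      if (ev[2] <= 0) Inf else sqrt(ev[1] / ev[2])
    }
    if (!is.finite(e) || e > ecc_cap) {
      degen[i, j] <- degen[j, i] <- TRUE
      e <- ecc_cap
    }
    ecc[i, j] <- ecc[j, i] <- e
  }
  structure(list(axes = eig$vectors, lengths = lengths, ecc = ecc,
                 degenerate = degen, trimmed = Xt, center = mu, q = q,
                 kept_frac = mean(inside)),
            class = "ellipsoid_fit")
}

#' Uncertainty report from a Monte-Carlo solution cloud
#'
#' Per parameter: `mu` (mean of the trimmed cloud), `delta_pct`
#' (relative distance of `mu` to the known truth, a-priori mode only),
#' `C_theta` (half-width of the [0.05, 0.95] quantile interval, the
#' expected maximum uncertainty) and `C_pct = 100 * C_theta / mu`.
#' Globally: the pairwise eccentricity matrix, the most eccentric (most
#' correlated) pair, and the ellipsoid pseudo-volume (product of the
#' normalised semi-axis lengths).
#'
#' @param cloud a `solution_cloud`.
#' @param fit matching [trim_and_fit()] result (computed if missing).
#' @param theta_true optional named truth for `delta_pct`.
#' @return object of class `uncertainty_report`.
#' @export
uncertainty_report <- function(cloud, fit = NULL, theta_true = NULL) {
  if (is.null(fit)) fit <- trim_and_fit(cloud)
  X <- cloud$estimates
  mu <- fit$center
  C_theta <- (fit$q[2, ] - fit$q[1, ]) / 2
  C_pct <- 100 * C_theta / abs(mu)
  delta_pct <- if (!is.null(theta_true)) {
    tt <- theta_true[colnames(X)]
    100 * abs(mu - tt) / abs(tt)
  } else rep(NA_real_, ncol(X))
  tab <- data.frame(parameter = colnames(X), mu = mu,
                    delta_pct = delta_pct, C_theta = C_theta,
                    C_pct = C_pct, row.names = NULL)
  em <- fit$ecc
  diag(em) <- -Inf
  imax <- which(em == max(em), arr.ind = TRUE)[1, ]
  structure(list(table = tab, ecc = fit$ecc,
                 max_ecc = max(em),
                 max_ecc_pair = sort(colnames(X)[imax]),
                 pseudo_volume = prod(fit$lengths),
                 degenerate = fit$degenerate,
                 n_reps = nrow(X)),
            class = "uncertainty_report")
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat("<uncertainty_report>", x$n_reps, "replicates\n")
  print(transform(x$table, mu = signif(mu, 4),
                  delta_pct = round(delta_pct, 2),
                  C_theta = signif(C_theta, 3), C_pct = round(C_pct, 1)),
        row.names = FALSE)
  cat("most correlated pair:", paste(x$max_ecc_pair, collapse = " - "),
      "eccentricity", round(x$max_ecc, 1), "\n")
  cat("pseudo-volume:", signif(x$pseudo_volume, 3), "\n")
  invisible(x)
}

#' Cost contours over a parameter pair
#'
#' Evaluates the weighted least-squares cost on a 2-D grid with the
#' remaining parameters held fixed; flags a valley direction (elongated
#' low-cost ridge, i.e. strong correlation) and open level sets reaching
#' the grid boundary (potential non-identifiability).
#'
#' @param problem a [calibration_problem()].
#' @param pair character vector of two free parameter names.
#' @param n_grid grid resolution per axis.
#' @param ranges optional list of two ranges; defaults to the problem
#'   bounds.
#' @param theta_fixed full parameter vector for the non-grid parameters
#'   (defaults to nominal).
#' @param log_grid space the grid logarithmically.
#' @return list: `par1`, `par2` (grid axes), `J` (matrix), `open_valley`,
#'   `valley_correlation`.
#' @export
cost_contours <- function(problem, pair, n_grid = 25, ranges = NULL,
                          theta_fixed = NULL, log_grid = TRUE) {
  stopifnot(length(pair) == 2, all(pair %in% problem$free))
  theta_fixed <- theta_fixed %||% problem$space$nominal
  rg <- ranges %||% list(c(problem$lower[pair[1]], problem$upper[pair[1]]),
                         c(problem$lower[pair[2]], problem$upper[pair[2]]))
  axis <- function(r) if (log_grid)
    10^seq(log10(r[1]), log10(r[2]), length.out = n_grid)
  else seq(r[1], r[2], length.out = n_grid)
  g1 <- axis(rg[[1]]); g2 <- axis(rg[[2]])
  J <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    th <- theta_fixed[problem$free]
    th[pair] <- c(g1[i], g2[j])
    J[i, j] <- wls_cost(th, problem)
  }
  if (all(J >= 1e10)) stop("cost could not be evaluated anywhere on grid")
  ## valley diagnostics on the low-cost set
  low <- which(J <= stats::quantile(J[J < 1e10], 0.1), arr.ind = TRUE)
  vc <- if (nrow(low) > 2) stats::cor(low[, 1], low[, 2]) else 0
  edge <- any(low[, 1] %in% c(1, n_grid)) || any(low[, 2] %in% c(1, n_grid))
  list(par1 = g1, par2 = g2, J = J, pair = pair,
       valley_correlation = vc, open_valley = edge)
}
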