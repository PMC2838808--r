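## Global parameter ranking: relative sensitivities are evaluated over a
## Latin-hypercube sample of parameter space and summarised into
## importance factors (root-mean-square, mean-absolute, mean, max, min of
## the dimensionless relative sensitivities over all experiments,
## observables, sampling times and parameter draws).

#' Latin hypercube sample of the feasible parameter box
#'
#' Each free parameter's range is divided into `n_lhs` equal-probability
#' intervals containing exactly one draw; draws are paired across
#' parameters by a seeded random permutation (the standard LHS
#' construction).
#'
#' @param space a [parameter_space()].
#' @param free parameters to sample.
#' @param n_lhs sample size.
#' @param distribution `"log-uniform"` (default; equal probability per
#'   decade) or `"uniform"`.
#' @param seed integer seed.
#' @param range optional list with `lower`/`upper` named vectors
#'   overriding the space bounds.
#' @return object of class `lhs_design`: `samples` (n_lhs x n_free matrix,
#'   natural units), `strata` (interval index per draw), plus the settings.
#' @export
lhs_sample <- function(space, free = space$free, n_lhs,
                       distribution = c("log-uniform", "uniform"),
                       seed = 1, range = NULL) {
  distribution <- match.arg(distribution)
  if (n_lhs < 2) stop("n_lhs must be at least 2")
  lo <- (range$lower %||% space$lower)[free]
  hi <- (range$upper %||% space$upper)[free]
  if (any(!is.finite(lo)) || any(!is.finite(hi)))
    stop("bounds must be finite")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  u <- lhs::randomLHS(n_lhs, length(free))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  colnames(u) <- free
  samples <- u
  for (j in seq_along(free)) {
    if (distribution == "log-uniform") {
      l <- log10(max(lo[j], 1e-300)); h <- log10(hi[j])
      samples[, j] <- 10^(l + u[, j] * (h - l))
    } else {
      samples[, j] <- lo[j] + u[, j] * (hi[j] - lo[j])
    }
  }
  structure(list(samples = samples, strata = ceiling(u * n_lhs),
                 n_lhs = n_lhs, free = free, distribution = distribution,
                 seed = seed,
                 lower = stats::setNames(lo, free),
                 upper = stats::setNames(hi, free)),
            class = "lhs_design")
}

#' Importance factors from relative sensitivities over an LHS sample
#'
#' For every draw of the Latin hypercube the forward sensitivities of all
#' observables are computed for every design; the dimensionless relative
#' sensitivities are pooled over draws, experiments, observables and
#' sampling times into the five importance factors per parameter:
#' `delta_msqr = sqrt(mean(s_rel^2))`, `delta_mabs = mean(|s_rel|)`,
#' `delta_mean = mean(s_rel)`, `delta_max = max(s_rel)`,
#' `delta_min = min(s_rel)`. Slices by experiment and by observable are
#' returned alongside.
#'
#' @param model a [dynamic_model].
#' @param designs list of [experiment_design()] objects.
#' @param lhs an `lhs_design` from [lhs_sample()].
#' @param space the [parameter_space()] supplying fixed parameter values.
#' @param floor normalisation floor for the relative sensitivities.
#' @param max_fail_frac error out when more than this fraction of draws
#'   fails to simulate (the sampled range is then likely pathological).
#' @return object of class `importance_factors`: data frame `factors`
#'   (one row per parameter), slice tables, and bookkeeping (`N_D`,
#'   failed draw count).
#' @export
importance_factors <- function(model, designs, lhs, space, floor = 1e-8,
                               max_fail_frac = 0.2, rtol = 1e-6,
                               atol = 1e-9) {
  if (inherits(designs, "experiment_design")) designs <- list(designs)
  free <- lhs$free
  nf <- length(free)
  acc <- list(
    sum2 = numeric(nf), sabs = numeric(nf), ssum = numeric(nf),
    smax = rep(-Inf, nf), smin = rep(Inf, nf), n = 0)
  slice_init <- function() list(sum2 = numeric(nf), n = 0)
  by_exp <- stats::setNames(
    lapply(designs, function(d) slice_init()),
    vapply(designs, `[[`, character(1), "name"))
  obs_names <- unique(unlist(lapply(designs, `[[`, "observables")))
  by_obs <- stats::setNames(lapply(obs_names, function(o) slice_init()),
                            obs_names)
  failed <- 0L
  for (i in seq_len(nrow(lhs$samples))) {
    theta <- set_free(space, lhs$samples[i, ])
    draw_ok <- TRUE
    draw_rel <- list()
    for (d in designs) {
      sens <- try(suppressWarnings(
        forward_sensitivities(model, theta, d, free, rtol = rtol,
                              atol = atol)), silent = TRUE)
      if (inherits(sens, "try-error") || inherits(sens, "sim_failure")) {
        draw_ok <- FALSE; break
      }
      draw_rel[[d$name]] <- relative_sensitivities(sens, floor = floor)
    }
    if (!draw_ok) { failed <- failed + 1L; next }
    for (dn in names(draw_rel)) {
      for (ob in names(draw_rel[[dn]])) {
        m <- draw_rel[[dn]][[ob]]
        acc$sum2 <- acc$sum2 + colSums(m^2)
        acc$sabs <- acc$sabs + colSums(abs(m))
        acc$ssum <- acc$ssum + colSums(m)
        acc$smax <- pmax(acc$smax, apply(m, 2, max))
        acc$smin <- pmin(acc$smin, apply(m, 2, min))
        acc$n <- acc$n + nrow(m)
        by_exp[[dn]]$sum2 <- by_exp[[dn]]$sum2 + colSums(m^2)
        by_exp[[dn]]$n <- by_exp[[dn]]$n + nrow(m)
        by_obs[[ob]]$sum2 <- by_obs[[ob]]$sum2 + colSums(m^2)
        by_obs[[ob]]$n <- by_obs[[ob]]$n + nrow(m)
      }
    }
  }
  n_draws <- nrow(lhs$samples)
  if (failed > max_fail_frac * n_draws)
    stop(failed, " of ", n_draws, " draws failed to simulate; ",
         "the sampled parameter range is likely pathological")
  if (acc$n == 0) stop("no successful draws")
  factors <- data.frame(
    parameter = free,
    delta_msqr = sqrt(acc$sum2 / acc$n),
    delta_mabs = acc$sabs / acc$n,
    delta_mean = acc$ssum / acc$n,
    delta_max = acc$smax,
    delta_min = acc$smin,
    row.names = NULL)
  slice_tab <- function(sl) data.frame(
    parameter = free,
    delta_msqr = sqrt(sl$sum2 / max(sl$n, 1)),
    N_D = sl$n, row.names = NULL)
  structure(list(factors = factors, N_D = acc$n,
                 by_experiment = lapply(by_exp, slice_tab),
                 by_observable = lapply(by_obs, slice_tab),
                 n_draws = n_draws, n_failed = failed),
            class = "importance_factors")
}

#' @export
print.importance_factors <- function(x, ...) {
  cat("<importance_factors> N_D =", x$N_D, "(", x$n_failed,
      "failed draws )\n")
  df <- x$factors[order(-x$factors$delta_msqr), ]
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Rank parameters by an importance criterion
#'
#' Orders the parameters by the chosen importance factor (decreasing) and
#' proposes a partition: parameters whose criterion falls below
#' `partition_frac` times the top value are recommended to be fixed at
#' their nominal values, since their lack of influence on the observables
#' is a source of practical identifiability problems. Ties break
#' lexicographically by parameter name.
#'
#' @param factors an `importance_factors` object (or its `factors` data
#'   frame).
#' @param criterion column to rank by, default `"delta_msqr"`.
#' @param partition_frac threshold fraction of the top value.
#' @return list: `ranking` (data frame with rank), `estimate` (parameters
#'   kept for calibration), `fix` (parameters recommended fixed).
#' @export
rank_parameters <- function(factors, criterion = "delta_msqr",
                            partition_frac = 0.01) {
  df <- if (inherits(factors, "importance_factors")) factors$factors
        else factors
  val <- abs(df[[criterion]])
  ord <- order(-val, df$parameter)
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  thr <- partition_frac * max(val)
  fix <- df$parameter[abs(df[[criterion]]) < thr]
  list(ranking = df, estimate = setdiff(df$parameter, fix), fix = fix)
}

#' Ranking over several reference-centred parameter ranges
#'
#' Repeats the LHS importance-factor analysis over a set of ranges around
#' the reference vector (by default half-to-double, a decade each way, and
#' two decades up), and combines them by the mean within-range rank.
#'
#' @inheritParams importance_factors
#' @param n_lhs draws per range.
#' @param ranges list of `c(down, up)` multiplier pairs applied to the
#'   nominal: range = (nominal/down, nominal*up).
#' @param seed master seed (one derived seed per range).
#' @return list: `per_range` (importance_factors per range), `mean_rank`
#'   (data frame ordered by mean rank), `lhs_seeds`.
#' @export
rank_parameters_over_ranges <- function(model, designs, space,
                                        free = space$free, n_lhs = 100,
                                        ranges = list(c(2, 2), c(10, 10),
                                                      c(1, 100)),
                                        floor = 1e-8, seed = 1,
                                        max_fail_frac = 0.2) {
  per_range <- list()
  rank_mat <- NULL
  for (k in seq_along(ranges)) {
    rg <- ranges[[k]]
    lo <- space$nominal[free] / rg[1]
    hi <- space$nominal[free] * rg[2]
    lh <- lhs_sample(space, free, n_lhs, seed = seed + 1000 * k,
                     range = list(lower = lo, upper = hi))
    imf <- importance_factors(model, designs, lh, space, floor = floor,
                              max_fail_frac = max_fail_frac)
    per_range[[k]] <- imf
    rk <- rank_parameters(imf)
    r <- stats::setNames(rk$ranking$rank, rk$ranking$parameter)[free]
    rank_mat <- cbind(rank_mat, r)
  }
  mean_rank <- data.frame(parameter = free,
                          mean_rank = rowMeans(rank_mat),
                          row.names = NULL)
  mean_rank <- mean_rank[order(mean_rank$mean_rank, mean_rank$parameter), ]
  list(per_range = per_range, mean_rank = mean_rank,
       ranges = ranges, n_lhs = n_lhs, seed = seed)
}
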