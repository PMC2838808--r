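## Orchestration of the full identification loop: structural analysis,
## global ranking and partition, then iterated practical-identifiability
## analysis, parameter freezing and E/D-optimal design of the next
## experiment, with full seeded reproducibility and a serialisable
## report.

#' Configuration of the identification loop
#'
#' @param model_name registry name (`"nfkb"`) or a `list(model=, space=)`.
#' @param schemes list of [experiment_design()] objects to start from.
#' @param free parameters to estimate initially (default: the space's
#'   free set).
#' @param do_structural run the structural identifiability stage.
#' @param do_ranking run the global ranking stage and apply its partition.
#' @param ranking_n_lhs LHS draws per ranking range.
#' @param partition_frac ranking partition threshold (fraction of top
#'   importance).
#' @param n_reps Monte-Carlo replicates per practical-identifiability
#'   stage.
#' @param noise_spec list `rel`/`floor`.
#' @param freeze_delta_pct,freeze_C_pct "well-estimated" thresholds: a
#'   parameter whose relative bias and expected uncertainty fall below
#'   these is frozen at its current mean.
#' @param oed_constraints constraints passed to [optimize_design()]
#'   (observables default to the first scheme's).
#' @param oed_budget,oed_criterion OED search settings.
#' @param max_iter maximum loop iterations.
#' @param master_seed master seed; each stochastic stage receives a
#'   derived, logged seed.
#' @return validated list of class `loop_config`.
#' @export
loop_config <- function(model_name = "nfkb", schemes = NULL, free = NULL,
                        do_structural = TRUE, do_ranking = TRUE,
                        ranking_n_lhs = 100, partition_frac = 0.01,
                        n_reps = 100,
                        noise_spec = list(rel = 0.1, floor = 1e-6),
                        freeze_delta_pct = 1, freeze_C_pct = 10,
                        oed_constraints = list(), oed_budget = 400,
                        oed_criterion = "E", max_iter = 4,
                        master_seed = 1) {
  stopifnot(n_reps >= 20, max_iter >= 1, master_seed == floor(master_seed))
  cfg <- as.list(environment())
  class(cfg) <- "loop_config"
  cfg
}

#' Run the iterative identification loop
#'
#' Stages, in order: structural identifiability (series rank + tableau),
#' global ranking and partition (insensitive parameters fixed), then per
#' iteration: a-priori Monte-Carlo practical identifiability of the
#' current scheme, freezing of well-estimated parameters (relative bias
#' and expected uncertainty below the configured thresholds), and, if
#' parameters remain active, an optimal experiment appended to the
#' scheme with the accumulated Fisher information as prior.
#'
#' @param config a [loop_config()].
#' @return object of class `loop_report`.
#' @export
run_identification_loop <- function(config) {
  mm <- if (is.list(config$model_name) && !is.null(config$model_name$model))
    config$model_name else get_model(config$model_name)
  model <- mm$model; space <- mm$space
  schemes <- config$schemes %||% stop("schemes are required")
  free <- config$free %||% space$free
  report <- list(config = config[setdiff(names(config),
                                         c("schemes", "model_name"))],
                 model = model$name, iterations = list())
  seed_of <- function(stage, it) (config$master_seed * 97L + it * 13L +
                                    stage) %% (2^31 - 1)
  ## structural stage
  if (config$do_structural) {
    x0 <- if (model$x0_policy == "resting")
      resting_state(model, space$nominal) else model$x0
    st <- structural_identifiability(model, x0, space, free = free,
                                     method = "generating",
                                     seed = seed_of(1L, 0L))
    report$structural <- list(rank = st$rank$rank,
                              n_free = st$rank$n_free,
                              full_rank = st$rank$full_rank,
                              verdict = st$trace$overall,
                              direct = st$trace$direct,
                              order_used = st$order_used)
    if (!st$rank$full_rank)
      report$structural$deficient <- st$rank$deficient_directions
  }
  ## ranking stage and partition
  if (config$do_ranking) {
    rk <- rank_parameters_over_ranges(model, schemes, space, free = free,
                                      n_lhs = config$ranking_n_lhs,
                                      seed = seed_of(2L, 0L))
    comb <- rank_parameters(rk$per_range[[1]],
                            partition_frac = config$partition_frac)
    ## partition on the mean-rank consensus: fix parameters below the
    ## threshold in every range
    fix <- Reduce(intersect, lapply(rk$per_range, function(f)
      rank_parameters(f, partition_frac = config$partition_frac)$fix))
    report$ranking <- list(mean_rank = rk$mean_rank, fixed = fix)
    free <- setdiff(free, fix)
  }
  frozen <- list()
  active <- free
  mu_current <- space$nominal
  stop_reason <- "max iterations reached"
  for (it in seq_len(config$max_iter)) {
    rec <- list(iteration = it, active = active,
                schemes = vapply(schemes, `[[`, character(1), "name"))
    cloud <- monte_carlo_cloud(model, schemes, space, active,
                               theta_true = mu_current,
                               n_reps = config$n_reps,
                               noise_spec = config$noise_spec,
                               master_seed = seed_of(3L, it))
    fit <- trim_and_fit(cloud)
    rep_u <- uncertainty_report(cloud, fit, theta_true = space$nominal)
    rec$uncertainty <- rep_u$table
    rec$max_ecc <- rep_u$max_ecc
    rec$max_ecc_pair <- rep_u$max_ecc_pair
    rec$pseudo_volume <- rep_u$pseudo_volume
    ## freeze well-estimated parameters at their cloud mean
    tab <- rep_u$table
    ok <- tab$parameter[tab$delta_pct < config$freeze_delta_pct &
                          tab$C_pct < config$freeze_C_pct]
    if (length(ok)) {
      mu_current[ok] <- tab$mu[match(ok, tab$parameter)]
      frozen <- c(frozen, stats::setNames(as.list(
        tab$mu[match(ok, tab$parameter)]), ok))
      active <- setdiff(active, ok)
    }
    rec$frozen_now <- ok
    report$iterations[[it]] <- rec
    if (!length(active)) { stop_reason <- "all parameters resolved"; break }
    if (it == config$max_iter) break
    ## design the next experiment on top of accumulated information
    mu_fim <- mu_current
    mu_fim[active] <- tab$mu[match(active, tab$parameter)]
    prior <- fisher_information(model, mu_fim, schemes, active)
    cons <- config$oed_constraints
    cons$observables <- cons$observables %||% schemes[[1]]$observables
    cons$name <- paste0("oed_iter", it)
    oed <- optimize_design(model, mu_fim, active, prior_fim = prior,
                           criterion = config$oed_criterion,
                           constraints = cons,
                           budget = config$oed_budget,
                           seed = seed_of(4L, it))
    report$iterations[[it]]$oed <- list(
      criterion = oed$criterion, value = oed$value,
      design = design_to_list(oed$design))
    schemes <- c(schemes, list(oed$design))
  }
  report$frozen <- frozen
  report$active_final <- active
  report$stop_reason <- stop_reason
  class(report) <- "loop_report"
  report
}

#' @export
print.loop_report <- function(x, ...) {
  cat("<loop_report>", length(x$iterations), "iteration(s);",
      x$stop_reason, "\n")
  for (rec in x$iterations) {
    cat(sprintf("  it %d: %d active, worst C%% = %.1f, max ecc = %.1f\n",
                rec$iteration, length(rec$active),
                max(rec$uncertainty$C_pct), rec$max_ecc))
    if (length(rec$frozen_now))
      cat("        frozen:", paste(rec$frozen_now, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write / reload an identification-loop report
#'
#' Writes a JSON master report plus CSV tables (per-iteration uncertainty
#' tables and the uncertainty-evolution summary with one column per
#' completed scheme).
#'
#' @param report a `loop_report` (possibly partial).
#' @param outdir output directory (created if needed).
#' @return `write_report()` returns the master JSON path;
#'   `read_report()` reloads it into a list.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  master <- file.path(outdir, "report.json")
  jsonlite::write_json(unclass(report), master, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       dataframe = "columns")
  for (rec in report$iterations) {
    utils::write.csv(rec$uncertainty,
                     file.path(outdir, sprintf("uncertainty_iter%d.csv",
                                               rec$iteration)),
                     row.names = FALSE)
  }
  if (length(report$iterations)) {
    pars <- report$iterations[[1]]$uncertainty$parameter
    wide <- data.frame(parameter = pars)
    for (rec in report$iterations) {
      cp <- rec$uncertainty$C_pct[match(pars, rec$uncertainty$parameter)]
      wide[[paste0("scheme_", rec$iteration)]] <- cp
    }
    utils::write.csv(wide, file.path(outdir, "uncertainty_evolution.csv"),
                     row.names = FALSE)
  }
  invisible(master)
}

#' @rdname write_report
#' @export
read_report <- function(outdir) {
  jsonlite::read_json(file.path(outdir, "report.json"),
                      simplifyVector = FALSE)
}
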