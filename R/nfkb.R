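## Built-in model: the NF-kB regulatory module (Lipniacki-type two-feedback
## model). Two-compartment kinetics of IKK, NF-kB, the inhibitors IkBa and
## A20 and their complexes; TNF stimulation enters as a binary signal TR
## multiplying the IKK activation and A20-catalysed inactivation steps, so
## the system is control-affine in TR. Units: concentrations in uM (scaled
## per cytoplasmic volume), time in min.

nfkb_state_names <- c("IKKn", "IKKa", "IKKi", "IKKa_IkBa", "IKKa_IkBa_NFkB",
                      "NFkB", "NFkBn", "A20", "A20t", "IkBa", "IkBan",
                      "IkBat", "IkBa_NFkB", "IkBan_NFkBn", "cgent")

nfkb_param_names <- c("a1", "a2", "t1", "a3", "t2", "c1a", "c2a", "c3a",
                      "c4a", "c5a", "c6a", "c1", "c2", "c3", "c4", "c5",
                      "k1", "k2", "k3", "kprod", "kdeg", "NF", "kv",
                      "i1", "e2a", "i1a", "e1a", "c1c", "c2c", "c3c")

## nominal values; concentrations are volume-normalised so NF = 0.06
nfkb_nominal <- c(
  a1 = 0.5, a2 = 0.2, t1 = 0.1, a3 = 1, t2 = 0.1,
  c1a = 5e-7, c2a = 0, c3a = 4e-4, c4a = 0.5, c5a = 1e-4, c6a = 2e-5,
  c1 = 5e-7, c2 = 0, c3 = 4e-4, c4 = 0.5, c5 = 3e-4,
  k1 = 2.5e-3, k2 = 0.1, k3 = 1.5e-3, kprod = 2.5e-5, kdeg = 1.25e-4,
  NF = 0.06, kv = 5,
  i1 = 2.5e-3, e2a = 0.01, i1a = 1e-3, e1a = 5e-4,
  c1c = 5e-7, c2c = 0, c3c = 4e-4)

## the 13 parameters to be identified; the rest are fixed literature values
nfkb_free_params <- c("t1", "t2", "c3a", "c4a", "c5", "k1", "k2", "k3",
                      "kprod", "kdeg", "i1", "e2a", "i1a")

nfkb_rhs_text <- c(
  IKKn = "kprod - kdeg*IKKn - TR*k1*IKKn",
  IKKa = paste("TR*k1*IKKn - (k3 + kdeg)*IKKa - TR*k2*IKKa*A20",
               "- a2*IKKa*IkBa + t1*IKKa_IkBa - a3*IKKa*IkBa_NFkB",
               "+ t2*IKKa_IkBa_NFkB"),
  IKKi = "k3*IKKa + TR*k2*IKKa*A20 - kdeg*IKKi",
  IKKa_IkBa = "a2*IKKa*IkBa - t1*IKKa_IkBa",
  IKKa_IkBa_NFkB = "a3*IKKa*IkBa_NFkB - t2*IKKa_IkBa_NFkB",
  NFkB = "c6a*IkBa_NFkB - a1*NFkB*IkBa + t2*IKKa_IkBa_NFkB - i1*NFkB",
  NFkBn = "i1*kv*NFkB - a1*IkBan*NFkBn",
  A20 = "c4*A20t - c5*A20",
  A20t = "c2 + c1*NFkBn - c3*A20t",
  IkBa = paste("-a2*IKKa*IkBa - a1*IkBa*NFkB + c4a*IkBat - c5a*IkBa",
               "- i1a*IkBa + e1a*IkBan"),
  IkBan = "-a1*IkBan*NFkBn + i1a*kv*IkBa - e1a*kv*IkBan",
  IkBat = "c2a + c1a*NFkBn - c3a*IkBat",
  IkBa_NFkB = paste("a1*IkBa*NFkB - c6a*IkBa_NFkB - a3*IKKa*IkBa_NFkB",
                    "+ e2a*IkBan_NFkBn"),
  IkBan_NFkBn = "a1*IkBan*NFkBn - e2a*kv*IkBan_NFkBn",
  cgent = "c2c + c1c*NFkBn - c3c*cgent")

## rate constants are tabulated per second while the experiment clock runs
## in minutes; the factor 60 is the unit conversion
nfkb_rhs_text <- vapply(nfkb_rhs_text, function(s)
  paste0("60*(", s, ")"), character(1))

## observables measured in the reference experimental schemes: the six
## wild-type read-outs (A20 mRNA, total IKK, active IKK, total cytoplasmic
## IkBa, IkBa mRNA, free nuclear NF-kB); the two-observable subset is what
## the pulse-stimulation experiments record
nfkb_observables <- list(
  A20t = c(A20t = 1),
  total_IKK = c(IKKn = 1, IKKa = 1, IKKi = 1),
  IKKa = c(IKKa = 1),
  total_IkBa_cyt = c(IkBa = 1, IkBa_NFkB = 1),
  IkBat = c(IkBat = 1),
  NFkBn = c(NFkBn = 1))

#' Build the NF-kB regulatory-module model
#'
#' Returns the 15-state, 30-parameter two-feedback NF-kB signalling model
#' together with its parameter space: nominal values, the 13 parameters
#' flagged for identification, and default one-decade bounds. The binary
#' TNF signal `TR` enters affinely (IKK activation and the A20-catalysed
#' IKK inactivation). Total NF-kB (free + complexed, nuclear species
#' weighted by 1/kv) is conserved and equals the fixed parameter `NF`.
#'
#' @param bounds_scale half-width of the default bounds box in decades:
#'   bounds are `nominal/bounds_scale` to `nominal*bounds_scale`.
#' @return list with elements `model` ([dynamic_model]) and `space`
#'   ([parameter_space]).
#' @export
build_nfkb_model <- function(bounds_scale = 10) {
  model <- dynamic_model(
    name = "nfkb",
    states = nfkb_state_names,
    params = nfkb_param_names,
    rhs = nfkb_rhs_text,
    observables = nfkb_observables,
    stimuli = "TR",
    x0_policy = "resting")
  model$compiled <- list(dllname = "iterid", func = "nfkb_deriv",
                         sensfunc = "nfkb_sens", initfunc = "nfkb_init")
  ## seed state for the settling run: IKK at its production/degradation
  ## balance, all NF-kB sequestered in the cytoplasmic IkBa complex
  model$seed_state <- function(theta) {
    x <- stats::setNames(rep(0, 15), nfkb_state_names)
    x["IKKn"] <- theta[["kprod"]] / theta[["kdeg"]]
    x["IkBa_NFkB"] <- theta[["NF"]]
    x["IkBa"] <- 2e-3
    x
  }
  ## left-null (conservation) direction of the state Jacobian: total NF-kB
  consv <- stats::setNames(rep(0, 15), nfkb_state_names)
  consv[c("NFkB", "IKKa_IkBa_NFkB", "IkBa_NFkB")] <- 1
  consv[c("NFkBn", "IkBan_NFkBn")] <- 1 / nfkb_nominal[["kv"]]
  model$conservation <- consv
  nom <- nfkb_nominal
  space <- parameter_space(
    names = nfkb_param_names, nominal = nom, free = nfkb_free_params,
    lower = nom / bounds_scale, upper = pmax(nom * bounds_scale, 1e-12))
  list(model = model, space = space)
}

## total NF-kB across compartments, nuclear species weighted by 1/kv
nfkb_total_nf <- function(x, kv = 5) {
  x <- as.matrix(x)
  x[, "NFkB"] + x[, "IKKa_IkBa_NFkB"] + x[, "IkBa_NFkB"] +
    (x[, "NFkBn"] + x[, "IkBan_NFkBn"]) / kv
}

#' Reference experimental schemes for the NF-kB model
#'
#' `nfkb_es1_designs()` returns the surrogate of the reference scheme ES1:
#' the six wild-type observables sampled 15 times over 4 h under persistent
#' TNF, plus the two pulse-protocol observables (free nuclear NF-kB and
#' total cytoplasmic IkBa) sampled 15 times over 6 h under persistent and
#' under 1-h-pulse stimulation. The published scheme's exact sampling
#' schedules are not available, so equispaced surrogates are used.
#'
#' `nfkb_ranking_designs()` returns the three wild-type schemes used for
#' global parameter ranking: persistent, 1-h-pulse and 2-h-pulse TNF, each
#' observing all six read-outs over 6 h.
#'
#' @param noise_rel relative measurement noise (default 10%).
#' @param n_samples samples per observable.
#' @return list of [experiment_design] objects.
#' @export
nfkb_es1_designs <- function(noise_rel = 0.1, n_samples = 15) {
  lee_times <- seq(0, 240, length.out = n_samples + 1)[-1]
  hoff_times <- seq(0, 360, length.out = n_samples + 1)[-1]
  two_obs <- c("NFkBn", "total_IkBa_cyt")
  list(
    experiment_design(
      "lee_persistent",
      stimulus_profile("persistent", duration = 240),
      observables = names(nfkb_observables),
      sampling_times = lee_times, noise_rel = noise_rel),
    experiment_design(
      "hoffmann_persistent",
      stimulus_profile("persistent", duration = 360),
      observables = two_obs,
      sampling_times = hoff_times, noise_rel = noise_rel),
    experiment_design(
      "hoffmann_pulse1h",
      stimulus_profile("pulse", switch_times = c(0, 60), duration = 360),
      observables = two_obs,
      sampling_times = hoff_times, noise_rel = noise_rel))
}

#' @rdname nfkb_es1_designs
#' @export
nfkb_ranking_designs <- function(noise_rel = 0.1, n_samples = 15) {
  ts <- seq(0, 360, length.out = n_samples + 1)[-1]
  obs <- names(nfkb_observables)
  list(
    experiment_design("wt_persistent",
                      stimulus_profile("persistent", duration = 360),
                      observables = obs, sampling_times = ts,
                      noise_rel = noise_rel),
    experiment_design("wt_pulse1h",
                      stimulus_profile("pulse", switch_times = c(0, 60),
                                       duration = 360),
                      observables = obs, sampling_times = ts,
                      noise_rel = noise_rel),
    experiment_design("wt_pulse2h",
                      stimulus_profile("pulse", switch_times = c(0, 120),
                                       duration = 360),
                      observables = obs, sampling_times = ts,
                      noise_rel = noise_rel))
}

## model registry for the declarative interface and the CLI
model_registry <- new.env(parent = emptyenv())

#' Look up or register models by name
#'
#' @param name registry key.
#' @param builder zero-argument function returning `list(model=, space=)`.
#' @return `get_model()` returns the registered `list(model=, space=)`.
#' @export
get_model <- function(name) {
  if (!exists(name, envir = model_registry))
    stop("unknown model: ", name)
  get(name, envir = model_registry)()
}

#' @rdname get_model
#' @export
register_model <- function(name, builder) {
  assign(name, builder, envir = model_registry)
  invisible(name)
}

#' Build a model from a declarative config
#'
#' The config (a list, or a YAML/JSON file path) declares `states`,
#' `params` (named nominal values), `rhs` (named expressions as text),
#' `observables` (named lists of state coefficients), `stimuli`, optional
#' `free`, `lower`, `upper`, `x0` and `x0_policy`.
#'
#' @param config list or path to a YAML/JSON file.
#' @return list with `model` and `space`, as [build_nfkb_model()].
#' @export
model_from_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  pn <- names(config$params)
  obs <- lapply(config$observables, unlist)
  model <- dynamic_model(
    name = config$name %||% "user_model",
    states = config$states, params = pn,
    rhs = unlist(config$rhs)[config$states],
    observables = obs,
    stimuli = config$stimuli %||% character(),
    x0 = config$x0, x0_policy = config$x0_policy %||% "fixed")
  space <- parameter_space(
    names = pn, nominal = unlist(config$params),
    free = config$free %||% pn,
    lower = config$lower, upper = config$upper)
  list(model = model, space = space)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
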