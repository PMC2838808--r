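## Plain-text interfaces: measurement CSV (experiment, observable,
## time_min, value, sd), design JSON/YAML, report read/write.

#' Read and write measurement tables
#'
#' The CSV round-trips bit-stably: values are written with full precision
#' (`%.17g`).
#'
#' @param x a `measurement_set` (or compatible data frame).
#' @param path file path.
#' @return `read_measurements()` returns a `measurement_set`.
#' @export
write_measurements <- function(x, path) {
  df <- as.data.frame(x)[, c("experiment", "observable", "time_min",
                             "value", "sd")]
  for (cl in c("time_min", "value", "sd"))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("experiment", "observable", "time_min", "value", "sd")
  if (!all(need %in% names(df)))
    stop("measurement file must have columns ",
         paste(need, collapse = ", "))
  for (cl in c("time_min", "value", "sd"))
    df[[cl]] <- as.numeric(df[[cl]])
  structure(df[, need], class = c("measurement_set", "data.frame"),
            provenance = list(kind = "external", path = path))
}

design_to_list <- function(design) {
  list(name = design$name,
       stimulus = list(kind = design$stimulus$kind,
                       switch_times = design$stimulus$switch_times,
                       duration = design$stimulus$duration),
       observables = design$observables,
       sampling_times = design$sampling_times,
       noise_rel = design$noise_rel, noise_floor = design$noise_floor)
}

design_from_list <- function(x) {
  experiment_design(
    name = x$name,
    stimulus = stimulus_profile(x$stimulus$kind,
                                switch_times = unlist(x$stimulus$switch_times),
                                duration = x$stimulus$duration,
                                max_pulses = 100),
    observables = unlist(x$observables),
    sampling_times = lapply(x$sampling_times, unlist),
    noise_rel = x$noise_rel, noise_floor = x$noise_floor)
}

#' Write or read an experimental design (JSON or YAML by extension)
#'
#' @param design an [experiment_design()].
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @export
design_to_file <- function(design, path) {
  x <- design_to_list(design)
  if (grepl("[.]ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' @rdname design_to_file
#' @export
design_from_file <- function(path) {
  x <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE)
  design_from_list(x)
}
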