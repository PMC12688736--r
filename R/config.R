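# Run configuration: one YAML-mappable nested list covering every stage.

#' Default run configuration
#'
#' Nested settings for every pipeline stage, each with a documented
#' default: `generator` (cohort size, planted signal, seed), `screening`
#' (alpha), `fusion` (d_k, mode, epochs, step, lambda, init_sd), `svm`
#' (C, gamma), `evaluation` (endpoint scheme, E, seed_base), `ablation`
#' (K, proportion mode, cache directory) and `output_dir`.
#'
#' @return nested named list (class `run_config`).
#' @export
default_run_config <- function() {
  cfg <- list(
    generator = list(n_patients = 149L, signal_strength = 1.0,
                     signal_features = c(1L, 2L, 5L), seed = 1L),
    screening = list(alpha = 0.05),
    fusion = list(d_k = 8L, mode = "embed-sum", epochs = 200L, step = 0.01,
                  lambda = 1e-3, init_sd = 0.1),
    svm = list(C = 1.0, gamma = NULL),
    evaluation = list(scheme = "good_vs_poor", E = 5L, seed_base = 0L),
    ablation = list(K = 50L, proportion_mode = "slot_share", cache = NULL),
    output_dir = "."
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

# merge user values over defaults, rejecting unknown keys at any level
.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!(key %in% names(defaults)))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("config key ", full, " must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file mirroring [default_run_config()]; unspecified keys
#' keep their defaults, unknown keys are rejected with the offending key
#' named.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(unclass(default_run_config()), user)
  class(cfg) <- c("run_config", "list")
  cfg
}

# run_config -> per-stage objects
.generator_from_run <- function(cfg) {
  g <- cfg$generator
  default_config(n_patients = g$n_patients,
                 signal_strength = g$signal_strength,
                 signal_features = g$signal_features)
}

.model_from_run <- function(cfg) {
  model_config(d_k = cfg$fusion$d_k, mode = cfg$fusion$mode,
               epochs = cfg$fusion$epochs, step = cfg$fusion$step,
               lambda = cfg$fusion$lambda, init_sd = cfg$fusion$init_sd,
               C = cfg$svm$C, gamma = cfg$svm$gamma,
               scheme = cfg$evaluation$scheme, E = cfg$evaluation$E,
               seed_base = cfg$evaluation$seed_base)
}

# flatten a run_config into "# key: value" metadata lines
.config_metadata <- function(cfg, seed = NULL) {
  flat <- list(package = paste0("ncrtfusion ",
               as.character(utils::packageVersion("ncrtfusion"))))
  rec <- function(x, prefix) {
    for (key in names(x)) {
      full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
      v <- x[[key]]
      if (is.list(v) && !is.null(names(v))) rec(v, full)
      else flat[[full]] <<- if (is.null(v)) "default" else
        paste(format(v, digits = 6), collapse = " ")
    }
  }
  rec(unclass(cfg), "")
  if (!is.null(seed)) flat$seed <- seed
  flat
}
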