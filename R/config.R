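# Trial configuration: a single YAML document describing one full synthetic
# trial (cohort, agent, EFP model settings, schedule, outputs).

config_schema <- function() {
  list(
    seed = "numeric",
    out_dir = "character",
    cohort = c("n_test", "n_control", "diagnosis_loss_probs",
               "dropout_probs", "icc"),
    agent = c("baseline_arousal", "regulate_gain", "learning_rate",
              "noise_sd", "relax_tau"),
    efp = c("f_lo", "f_hi", "n_bands", "calibration_duration",
            "lambda_grid"),
    schedule = "character",
    n_sessions = "numeric",
    analyses = c("ancova", "mixed", "nnt", "learning")
  )
}

#' Default trial configuration
#'
#' @return a validated `efp_config` list with the package defaults: the
#'   published cohort sizes and trajectories, the standard training
#'   protocol, a 20-min calibration, and all analyses enabled.
#' @export
default_trial_config <- function() {
  validate_trial_config(list(
    seed = 1,
    out_dir = "efpnf-out",
    cohort = list(n_test = 40, n_control = 15,
                  diagnosis_loss_probs = list(test = 0.40, control = 0.15),
                  dropout_probs = list(pre = 0, post = 0.035, m1 = 0.25,
                                       m3 = 0.35, m6 = 0.5),
                  icc = 0.6),
    agent = list(baseline_arousal = 0, regulate_gain = 0.0035,
                 learning_rate = 0.1, noise_sd = 0.35, relax_tau = 5),
    efp = list(f_lo = 0.5, f_hi = 40, n_bands = 10,
               calibration_duration = 1200,
               lambda_grid = 10^seq(-3, 3, length.out = 13)),
    schedule = "efp_nf",
    n_sessions = 10,
    analyses = list(ancova = TRUE, mixed = TRUE, nnt = TRUE,
                    learning = TRUE)))
}

#' Validate a trial configuration
#'
#' Checks the configuration against the schema; unknown keys (top-level or
#' nested) are rejected so that typos cannot silently change a simulation.
#'
#' @param config a named list (e.g. parsed from YAML).
#' @return the config with class `efp_config`.
#' @export
validate_trial_config <- function(config) {
  schema <- config_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop_param("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (sec in c("cohort", "agent", "efp", "analyses")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), schema[[sec]])
      if (length(bad))
        stop_param("unknown keys in `", sec, "`: ",
                   paste(bad, collapse = ", "))
    }
  }
  if (!is.null(config$schedule) &&
      !config$schedule %in% c("efp_nf", "fmri_nf"))
    stop_param("schedule must be \"efp_nf\" or \"fmri_nf\"")
  structure(config, class = c("efp_config", "list"))
}

#' Read a trial configuration from YAML
#'
#' @param path YAML file.
#' @return a validated `efp_config`.
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: ", path)
  validate_trial_config(yaml::read_yaml(path))
}

#' Write a trial configuration to YAML
#'
#' @param config an `efp_config` (or compatible list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

config_agent <- function(config) {
  do.call(agent_params, config$agent %||% list())
}

config_cohort <- function(config) {
  cc <- config$cohort %||% list()
  cohort_params(
    n_test = cc$n_test %||% 40,
    n_control = cc$n_control %||% 15,
    diagnosis_loss_probs = unlist(cc$diagnosis_loss_probs %||%
                                    list(test = 0.40, control = 0.15)),
    dropout_probs = unlist(cc$dropout_probs %||%
                             list(pre = 0, post = 0.035, m1 = 0.25,
                                  m3 = 0.35, m6 = 0.5)),
    icc = cc$icc %||% 0.6)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable content hash of a configuration (md5 of its canonical YAML) for
# artifact provenance.
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}
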