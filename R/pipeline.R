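# High-level pipeline: simulate a full synthetic trial, analyse it, report.

#' Fit an EFP model on synthetic simultaneous EEG-BOLD calibration data
#'
#' Generates a latent arousal process, a coupled Pz recording, derives
#' energy-uniform bands from it, extracts feature windows every 3 s and fits
#' ridge weights against the hemodynamically lagged latent. This stands in
#' for the original model training on real simultaneous EEG-fMRI.
#'
#' @param duration calibration length (s); 1200 s (20 min) by default.
#' @param seed integer seed.
#' @param eeg_params list of [synthesize_eeg()] overrides.
#' @param latent_params list with `theta`, `sigma` for the latent process.
#' @param f_range band range (Hz).
#' @param n_bands number of bands.
#' @param lambda_grid ridge penalty grid.
#' @return list with `model` ([efp_model()]), `latent`, `recording`,
#'   `times`, `target`.
#' @export
calibrate_efp_model <- function(duration = 1200, seed = NULL,
                                eeg_params = list(),
                                latent_params = list(theta = 0.5, sigma = 1),
                                f_range = c(0.5, 40), n_bands = 10,
                                lambda_grid = 10^seq(-3, 3,
                                                     length.out = 13)) {
  seeds <- derive_seeds(seed, 2)
  latent <- generate_latent_arousal(theta = latent_params$theta,
                                    sigma = latent_params$sigma,
                                    duration = duration, seed = seeds[[1]])
  rec <- do.call(synthesize_eeg,
                 c(list(latent = latent, seed = seeds[[2]]), eeg_params))
  bands <- band_edges_energy_uniform(rec, n_bands = n_bands,
                                     f_range = f_range)
  times <- seq(12, duration, by = 3)
  fm <- feature_matrix(rec, bands, times)
  target <- efp_training_target(latent, times)
  model <- fit_efp_weights(fm$x, target, bands, lambda_grid = lambda_grid)
  list(model = model, latent = latent, recording = rec, times = times,
       target = target)
}

# Derive k child seeds (< 2^31) from one master seed (NULL stays NULL).
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  eval_with_seed(seed, function()
    as.list(sample.int(.Machine$integer.max - 1, k)))
}

#' Simulate a complete synthetic trial to disk
#'
#' Writes, under `out_dir`: the clinical cohort (`cohort.csv`), per-subject
#' per-session regulation success for the test arm (`sessions.csv`), the
#' generating ground truth and provenance (`ground_truth.json`), and the
#' configuration as run (`config_used.yaml`). Every artifact carries the
#' seed and the configuration hash. Output is deterministic given
#' `config$seed`.
#'
#' @param config an `efp_config` (see [default_trial_config()]).
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @param seed overrides `config$seed` when given.
#' @return `out_dir`, invisibly.
#' @export
simulate_trial <- function(config = default_trial_config(), out_dir = NULL,
                           seed = NULL) {
  config <- validate_trial_config(unclass(config))
  if (!is.null(seed)) config$seed <- seed
  out_dir <- out_dir %||% config$out_dir %||% "efpnf-out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 2)
  hash <- config_hash(config)
  stamp <- sprintf("# seed=%s config_md5=%s", format(config$seed), hash)

  cohort <- generate_clinical_cohort(config_cohort(config), seed = seeds[[1]])
  f <- file(file.path(out_dir, "cohort.csv"), "w")
  writeLines(stamp, f)
  utils::write.csv(as.data.frame(cohort), f, row.names = FALSE)
  close(f)

  agent <- config_agent(config)
  sched <- build_schedule(config$schedule %||% "efp_nf")
  n_subj <- config$cohort$n_test %||% 40
  subj_seeds <- derive_seeds(seeds[[2]], n_subj)
  succ <- t(vapply(seq_len(n_subj), function(i)
    simulate_subject_sessions(agent, config$n_sessions %||% 10, sched,
                              seed = subj_seeds[[i]]),
    numeric(config$n_sessions %||% 10)))
  sess_df <- data.frame(subject_id = rep(sprintf("S%03d", seq_len(n_subj)),
                                         each = ncol(succ)),
                        session = rep(seq_len(ncol(succ)), n_subj),
                        success = as.vector(t(succ)))
  f <- file(file.path(out_dir, "sessions.csv"), "w")
  writeLines(stamp, f)
  utils::write.csv(sess_df, f, row.names = FALSE)
  close(f)

  gt <- list(seed = config$seed, config_md5 = hash,
             cohort = unclass(config$cohort),
             agent = unclass(config$agent),
             schedule = attr(sched, "protocol_name"))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_trial_config(config, file.path(out_dir, "config_used.yaml"))
  invisible(out_dir)
}

#' Run the full clinical analysis battery on a cohort table
#'
#' Bundles the trial's inferential layer: the immediate-effect ANCOVA on the
#' clinician interview, intention-to-treat REML mixed models (and
#' per-protocol completer fits) for the self-report instruments, and
#' ARR/NNT from the loss-of-diagnosis flags.
#'
#' @param table an `efp_clinical` long table (or CSV path; comment lines
#'   starting with `#` are ignored).
#' @return object of class `efp_trial_result`.
#' @export
analyze_trial <- function(table) {
  if (is.character(table))
    table <- utils::read.csv(table, comment.char = "#",
                             stringsAsFactors = FALSE)
  res <- list()
  res$ancova <- ancova_immediate(table, "CAPS5")
  res$mixed <- list()
  res$per_protocol <- list()
  for (ins in intersect(c("PCL5", "DES2"), unique(table$instrument))) {
    res$mixed[[ins]] <- mixed_model_followup(table, ins)
    res$per_protocol[[ins]] <- tryCatch(
      mixed_model_followup(table, ins, subset_complete = TRUE),
      error = function(e) list(converged = FALSE,
                               diagnostics = conditionMessage(e)))
  }
  pre <- table[table$timepoint == "pre" & table$instrument == "CAPS5", ]
  post <- table[table$timepoint == "post" & table$instrument == "CAPS5", ]
  flags <- merge(pre[c("subject_id", "group", "diagnosis")],
                 post[c("subject_id", "diagnosis")], by = "subject_id",
                 suffixes = c("_pre", "_post"))
  flags <- flags[!is.na(flags$diagnosis_pre) & !is.na(flags$diagnosis_post) &
                   flags$diagnosis_pre, ]
  lt <- sum(flags$group == "test" & !flags$diagnosis_post)
  lc <- sum(flags$group == "control" & !flags$diagnosis_post)
  nt <- sum(flags$group == "test")
  nc <- sum(flags$group == "control")
  res$nnt <- if (nt > 0 && nc > 0) arr_and_nnt(lt, nt, lc, nc) else NULL
  res$group_means <- stats::aggregate(
    score ~ group + timepoint + instrument, data = table, FUN = mean)
  structure(res, class = "efp_trial_result")
}

#' Analyse neurofeedback training success across sessions
#'
#' Runs the condition-by-session repeated-measures ANOVA on per-block
#' condition means and the first-five vs last-five paired learning contrast
#' on per-session success.
#'
#' @param sessions either a data.frame with columns `subject`, `condition`,
#'   `session`, `value`, or a subjects x sessions success matrix (learning
#'   contrast only).
#' @param success_matrix optional subjects x sessions success matrix to use
#'   for the learning contrast when `sessions` is a block table.
#' @return list with `rm_anova` (when block data are given) and `learning`.
#' @export
analyze_efp_training <- function(sessions, success_matrix = NULL) {
  out <- list()
  if (is.data.frame(sessions)) {
    out$rm_anova <- rm_anova_condition_session(sessions)
    if (!is.null(success_matrix))
      out$learning <- paired_learning_test(success_matrix)
  } else {
    out$learning <- paired_learning_test(sessions)
  }
  out
}

#' Write a human-readable markdown report of a trial analysis
#'
#' @param result an `efp_trial_result` from [analyze_trial()].
#' @param path output markdown file.
#' @return `path`, invisibly.
#' @export
write_trial_report <- function(result, path) {
  ln <- c("# Synthetic trial analysis", "")
  a <- result$ancova
  ln <- c(ln, "## Immediate effect (ANCOVA on post scores, pre as covariate)",
          sprintf("- %s: F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f",
                  a$instrument, a$df[1], a$df[2], a$F, a$p,
                  a$partial_eta_sq),
          sprintf("- adjusted means: test %.2f, control %.2f",
                  a$adjusted_group_means["test"],
                  a$adjusted_group_means["control"]), "")
  if (!is.null(result$nnt)) {
    n <- result$nnt
    ln <- c(ln, "## Loss of diagnosis",
            sprintf(paste0("- ARR = %.3f (95%% CI %.3f to %.3f), NNT = %s"),
                    n$arr, n$ci_arr["lower"], n$ci_arr["upper"],
                    if (n$beneficial) sprintf("%.2f", n$nnt)
                    else "not beneficial"), "")
  }
  for (ins in names(result$mixed)) {
    m <- result$mixed[[ins]]
    if (isTRUE(m$converged)) {
      ln <- c(ln, sprintf("## Follow-up mixed model (%s, ITT)", ins))
      for (i in seq_len(nrow(m$fixed)))
        ln <- c(ln, sprintf("- %s: F(%d, %d) = %.2f, p = %.4g",
                            m$fixed$effect[i], m$fixed$numDF[i],
                            m$fixed$denDF[i], m$fixed$F[i], m$fixed$p[i]))
      ln <- c(ln, "")
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' Serialize a trial result bundle to JSON
#'
#' @param result an `efp_trial_result`.
#' @param path output file.
#' @param seed,config_md5 optional provenance fields embedded in the JSON.
#' @return `path`, invisibly.
#' @export
write_trial_result <- function(result, path, seed = NULL, config_md5 = NULL) {
  obj <- rapply(unclass(result), unclass, how = "replace")
  obj$provenance <- list(seed = seed, config_md5 = config_md5)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
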