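# Closed-loop neurofeedback engine: z-normalisation against the preceding
# Watch block, 1-10 feedback levels, regulation success indices.

#' Z-normalize an EFP sample against the preceding Watch distribution
#'
#' `Z = (sample - mean(watch)) / sd(watch)` with the sample (n-1) standard
#' deviation. A zero Watch SD yields a flagged degenerate result instead of
#' an error.
#'
#' @param efp_sample scalar EFP estimate from a Regulate step.
#' @param watch_samples EFP samples of the immediately preceding Watch block
#'   (>= 2 values).
#' @return object of class `efp_z`: list with `value` and `degenerate`.
#' @export
z_normalize <- function(efp_sample, watch_samples) {
  if (length(watch_samples) < 2L)
    stop_param("at least 2 Watch samples are required")
  check_scalar(efp_sample, "efp_sample")
  s <- stats::sd(watch_samples)
  if (s == 0)
    return(structure(list(value = NA_real_, degenerate = TRUE),
                     class = "efp_z"))
  structure(list(value = (efp_sample - mean(watch_samples)) / s,
                 degenerate = FALSE), class = "efp_z")
}

#' Map a Z-score to the 1-10 feedback level
#'
#' `level = clamp(round(5.5 + 2 Z), 1, 10)` with round-half-up, so Z = 0 maps
#' to mid-scale (level 6) and +-2.25 SD spans the full scale. Level 10 is
#' maximal scene agitation; lower levels reward down-regulation. The mapping
#' is monotone non-decreasing in Z. Degenerate Z-scores map to mid-scale.
#'
#' @param z an [z_normalize()] result or a numeric Z value.
#' @return integer feedback level in 1..10.
#' @export
map_feedback <- function(z) {
  if (inherits(z, "efp_z")) {
    if (z$degenerate) return(6L)
    z <- z$value
  }
  if (!is.finite(z)) return(6L)
  as.integer(min(10, max(1, round_half_up(5.5 + 2 * z))))
}

#' Regulation success index
#'
#' `SI = (mean(Regulate) - mean(Watch)) / sd(Watch)`; negative values
#' indicate down-regulation relative to the active Watch baseline. The index
#' is invariant to a common positive rescaling of both sequences.
#'
#' @param regulate_samples,watch_samples numeric vectors (>= 2 values each).
#' @return numeric scalar with attribute `degenerate` (TRUE when
#'   `sd(Watch) = 0`, in which case the value is NA).
#' @export
success_index <- function(regulate_samples, watch_samples) {
  if (length(regulate_samples) < 2L || length(watch_samples) < 2L)
    stop_param("each sequence must contain at least 2 samples")
  s <- stats::sd(watch_samples)
  if (s == 0)
    return(structure(NA_real_, degenerate = TRUE))
  structure((mean(regulate_samples) - mean(watch_samples)) / s,
            degenerate = FALSE)
}

#' Mean regulation success of a session
#'
#' @param record an `efp_session` from [run_closed_loop_session()], or a
#'   numeric vector of per-block success indices.
#' @return the mean of the block success indices.
#' @export
session_success <- function(record) {
  si <- if (inherits(record, "efp_session")) record$block_success else record
  if (is.null(si) || !length(si) || anyNA(si))
    stop_param("session record has missing block success indices")
  mean(as.numeric(si))
}

# Success indices per Watch/Regulate cycle from a labelled sample table.
# A cycle with no modulation at all (constant Watch AND equal means, so the
# index is 0/0) is reported as 0; a constant Watch with a real mean shift
# stays NA (degenerate).
cycle_success_indices <- function(times, values, schedule) {
  blocks <- schedule_block_at(schedule, times)
  watch_ids <- which(schedule$label == "Watch")
  vapply(which(schedule$label == "Regulate"), function(rb) {
    wb <- max(watch_ids[watch_ids < rb])
    reg <- values[!is.na(blocks) & blocks == rb]
    wat <- values[!is.na(blocks) & blocks == wb]
    si <- success_index(reg, wat)
    if (isTRUE(attr(si, "degenerate")) && mean(reg) == mean(wat)) si <- 0
    as.numeric(si)
  }, numeric(1))
}

#' Run one closed-loop neurofeedback session
#'
#' Simulates the full loop at 3-s resolution: the agent's latent arousal
#' advances (with its Regulate drift scaled by `(11 - level) / 10`, so
#' rewarding feedback sustains regulation), EEG is synthesized from the
#' latent, the EFP estimate is computed causally from the 12 s of Pz ending
#' at the step, Regulate samples are z-normalised against the preceding
#' Watch block's samples, and a 1-10 feedback level is emitted during
#' Regulate only. All noise streams are drawn up-front from `seed`, so a
#' fixed seed reproduces the session bit for bit.
#'
#' @param agent an [agent_params()].
#' @param model a trained [efp_model()].
#' @param schedule an [nf_schedule()] with Watch/Regulate cycles (the
#'   standard protocol is `build_schedule("efp_nf")`).
#' @param session_index session number (>= 1); scales the agent's drift via
#'   its learning rate.
#' @param seed optional integer seed.
#' @param eeg_params list of [synthesize_eeg()] arguments (`couplings`,
#'   `pink_amp`, `line_amp`, `white_sd`).
#' @param agent_rate internal latent integration rate (Hz).
#' @param keep_eeg attach the synthesized recording to the record.
#' @return object of class `efp_session`: list with `session_index`,
#'   `samples` (data.frame: time, label, efp, z, feedback, ok),
#'   `block_success` (one success index per Watch/Regulate cycle),
#'   `schedule`, `latent`, and optionally `eeg`.
#' @export
run_closed_loop_session <- function(agent, model, schedule,
                                    session_index = 1, seed = NULL,
                                    eeg_params = list(), agent_rate = 4,
                                    keep_eeg = FALSE) {
  stopifnot(inherits(agent, "efp_agent"), inherits(model, "efp_model"),
            inherits(schedule, "efp_schedule"))
  if (!any(schedule$label == "Regulate") || !any(schedule$label == "Watch"))
    stop_param("schedule must contain Watch and Regulate blocks")
  total <- schedule_duration(schedule)
  if (total %% 3 != 0) stop_param("schedule duration must be a multiple of 3 s")
  rate <- 250
  step <- 3
  n_steps <- total / step
  sub <- step * agent_rate          # agent substeps per 3-s step
  spp <- step * rate                # EEG samples per 3-s step
  gain <- agent_session_gain(agent, session_index)
  decay_sub <- 1 / agent_rate

  ep <- utils::modifyList(list(couplings = default_couplings(),
                               pink_amp = 1, line_amp = 0.5,
                               white_sd = 0.2), eeg_params)

  res <- eval_with_seed(seed, function() {
    n_eeg <- total * rate
    n_lat <- total * agent_rate
    # all stochastic inputs drawn once, independent of the feedback path
    agent_noise <- if (agent$noise_sd == 0) numeric(n_lat) else
      stats::rnorm(n_lat, 0, agent$noise_sd * sqrt(1 / agent_rate))
    bg <- numeric(n_eeg)
    t_eeg <- (1:n_eeg) / rate
    if (ep$pink_amp > 0) bg <- bg + ep$pink_amp * pink_noise(n_eeg, rate)
    if (ep$line_amp > 0) bg <- bg + ep$line_amp * sin(2 * pi * 50 * t_eeg)
    if (ep$white_sd > 0) bg <- bg + stats::rnorm(n_eeg, 0, ep$white_sd)
    carriers <- lapply(ep$couplings, function(cp)
      band_carrier(n_eeg, rate, cp$f_lo, cp$f_hi))

    pz <- bg
    latent <- numeric(n_lat)
    state <- agent$baseline_arousal
    efp <- z <- rep(NA_real_, n_steps)
    fb <- rep(NA_integer_, n_steps)
    ok <- logical(n_steps)
    step_times <- (1:n_steps) * step
    step_labels <- schedule_label_at(schedule, step_times - step / 2)
    step_blocks <- schedule_block_at(schedule, step_times - step / 2)
    watch_ids <- which(schedule$label == "Watch")
    level <- 6L  # neutral until the loop's first feedback

    # the feature window only needs the trailing 12 s of Pz
    trailing_rec <- function(n_samp, end_time) {
      i0 <- n_samp - 12L * rate + 1L
      eeg_recording(matrix(pz[i0:n_samp], 1), rate = rate,
                    channel_labels = "Pz", t0 = end_time - 12)
    }

    for (k in seq_len(n_steps)) {
      lab <- step_labels[k]
      mult <- if (!is.na(lab) && lab == "Regulate") (11 - level) / 10 else 1
      sub_idx <- ((k - 1) * sub + 1):(k * sub)
      adv <- agent_advance(state, rep(lab, sub), gain * mult, agent,
                           decay_sub, agent_noise[sub_idx])
      latent[sub_idx] <- adv$values
      state <- adv$state
      # synthesize this step's EEG from the just-advanced latent
      samp_idx <- ((k - 1) * spp + 1):(k * spp)
      lat_here <- resample_linear((sub_idx - 1) / agent_rate + 1 / agent_rate,
                                  latent[sub_idx], t_eeg[samp_idx])
      for (j in seq_along(ep$couplings)) {
        cp <- ep$couplings[[j]]
        pz[samp_idx] <- pz[samp_idx] +
          pmax(0, cp$base_amp + cp$coupling * lat_here) *
            carriers[[j]][samp_idx]
      }
      tt <- step_times[k]
      if (tt >= 12) {
        fw <- extract_features(trailing_rec(k * spp, tt), model$bands, tt)
        efp[k] <- model$intercept + sum(model$weights * fw$values)
        ok[k] <- TRUE
      }
      if (!is.na(lab) && lab == "Regulate" && ok[k]) {
        wb <- watch_ids[watch_ids < step_blocks[k]]
        if (length(wb)) {
          wsamp <- efp[!is.na(step_blocks) & step_blocks == max(wb) & ok]
          if (length(wsamp) >= 2) {
            zk <- z_normalize(efp[k], wsamp)
            z[k] <- zk$value
            level <- map_feedback(zk)
            fb[k] <- level
          }
        }
      }
      if (!is.na(lab) && lab != "Regulate") level <- 6L
    }

    samples <- data.frame(time = step_times, label = step_labels,
                          efp = efp, z = z, feedback = fb, ok = ok,
                          stringsAsFactors = FALSE)
    keep <- ok & !is.na(step_blocks)
    bs <- cycle_success_indices(step_times[keep] - step / 2, efp[keep],
                                schedule)
    out <- list(session_index = session_index, samples = samples,
                block_success = bs, schedule = schedule,
                latent = latent_series(latent, agent_rate),
                strategies = NA_character_)
    if (keep_eeg) {
      mk <- data.frame(time = schedule$onset, label = schedule$label)
      out$eeg <- eeg_recording(matrix(pz, 1), rate = rate,
                               channel_labels = "Pz", markers = mk)
    }
    structure(out, class = "efp_session")
  })
  res
}

#' @export
print.efp_session <- function(x, ...) {
  cat(sprintf(
    "<efp_session> #%d: %d samples, block success %s, mean %.3f\n",
    x$session_index, nrow(x$samples),
    paste(sprintf("%.2f", x$block_success), collapse = " "),
    mean(x$block_success)))
  invisible(x)
}

#' Simulate per-session regulation success for one subject (open loop)
#'
#' Runs the agent over `n_sessions` training sessions without the EEG/EFP
#' sensing layer: the session success indices are computed directly from the
#' latent arousal sampled on the 3-s feedback grid. This is the scalable path
#' for cohort-level learning analyses; [run_closed_loop_session()] exercises
#' the full sensing loop on single sessions.
#'
#' @param agent an [agent_params()].
#' @param n_sessions number of training sessions.
#' @param schedule an [nf_schedule()].
#' @param seed optional integer seed (one stream across all sessions).
#' @return numeric vector of length `n_sessions`: mean success index per
#'   session. The per-block indices are in attribute `blocks`.
#' @export
simulate_subject_sessions <- function(agent, n_sessions = 10,
                                      schedule = build_schedule("efp_nf"),
                                      seed = NULL) {
  eval_with_seed(seed, function() {
    blocks <- matrix(NA_real_, n_sessions,
                     sum(schedule$label == "Regulate"))
    for (s in seq_len(n_sessions)) {
      lat <- simulate_regulating_agent(agent, schedule, session_index = s)
      grid <- seq(3, schedule_duration(schedule), by = 3)
      vals <- latent_at(lat, grid - 1 / lat$rate)
      blocks[s, ] <- cycle_success_indices(grid - 1.5, vals, schedule)
    }
    structure(rowMeans(blocks), blocks = blocks)
  })
}
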