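#' Parameters of a simulated regulating agent
#'
#' The agent is a latent arousal state that drifts downwards while the
#' participant is in the Regulate condition and relaxes back to baseline
#' (first-order, time constant `relax_tau`) during all other conditions.
#' Regulation skill improves linearly over sessions: in session `s` the
#' effective downward drift is `regulate_gain * (1 + learning_rate * (s - 1))`
#' units per second.
#'
#' @param baseline_arousal resting mean latent level.
#' @param regulate_gain downward drift during Regulate in session 1
#'   (units/s, >= 0).
#' @param learning_rate fractional gain increase per additional session
#'   (>= 0).
#' @param noise_sd diffusion coefficient of the state noise
#'   (units / sqrt(s), >= 0).
#' @param relax_tau time constant of the return to baseline (s, > 0).
#' @return An object of class `efp_agent`.
#' @export
agent_params <- function(baseline_arousal = 0, regulate_gain = 0.0035,
                         learning_rate = 0.1, noise_sd = 0.35,
                         relax_tau = 5) {
  check_scalar(baseline_arousal, "baseline_arousal")
  check_scalar(regulate_gain, "regulate_gain", lower = 0)
  check_scalar(learning_rate, "learning_rate", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(relax_tau, "relax_tau", lower = 0, strict_lower = TRUE)
  structure(list(baseline_arousal = baseline_arousal,
                 regulate_gain = regulate_gain,
                 learning_rate = learning_rate,
                 noise_sd = noise_sd,
                 relax_tau = relax_tau),
            class = "efp_agent")
}

agent_session_gain <- function(agent, session_index) {
  agent$regulate_gain * (1 + agent$learning_rate * (session_index - 1))
}

# One integrator shared by the open-loop and closed-loop engines.
# x: current state; labels: block label per substep; gain: effective drift
# (units/s) applied during Regulate substeps (may vary per substep in the
# closed loop); noise: pre-drawn innovations (same length as labels).
# Vectorised over runs of constant (label, gain): Regulate segments are a
# linear drift plus a random walk, all other segments decay geometrically
# towards baseline (one recursive filter per segment).
agent_advance <- function(x, labels, gain, agent, dt, noise) {
  n <- length(labels)
  gain <- rep_len(gain, n)
  decay <- exp(-dt / agent$relax_tau)
  reg <- !is.na(labels) & labels == "Regulate"
  seg_id <- cumsum(c(TRUE, reg[-1] != reg[-n] | gain[-1] != gain[-n]))
  out <- numeric(n)
  for (s in unique(seg_id)) {
    i <- which(seg_id == s)
    if (reg[i[1]]) {
      out[i] <- x - gain[i[1]] * dt * seq_along(i) + cumsum(noise[i])
    } else {
      dev <- stats::filter(noise[i], decay, method = "recursive",
                           init = x - agent$baseline_arousal)
      out[i] <- agent$baseline_arousal + as.numeric(dev)
    }
    x <- out[i[length(i)]]
  }
  list(values = out, state = x)
}

#' A high-signal "skilled learner" agent configuration
#'
#' Convenience parameter set with low state noise and a strong session-wise
#' learning effect, used for property checks of the learning machinery
#' (monotone effect of the learning rate). The [agent_params()] defaults, in
#' contrast, are calibrated to the noisy group-level regulation trajectory a
#' real cohort shows.
#'
#' @return an [agent_params()] object.
#' @export
skilled_agent <- function() {
  agent_params(regulate_gain = 0.02, learning_rate = 0.3, noise_sd = 0.1,
               relax_tau = 5)
}

#' Simulate an agent's latent arousal over one session (open loop)
#'
#' Advances the agent state across the block schedule at the internal 4-Hz
#' grid. With `noise_sd = 0` the path is piecewise deterministic: linear
#' decrease during Regulate, exponential relaxation elsewhere.
#'
#' @param agent an [agent_params()] object.
#' @param schedule an [nf_schedule()]; must contain at least one Regulate
#'   block.
#' @param session_index session number (1-based); scales the Regulate drift
#'   through the agent's learning rate.
#' @param seed optional integer seed.
#' @param rate internal integration rate (Hz).
#' @return An [latent_series()] covering the schedule duration.
#' @export
simulate_regulating_agent <- function(agent, schedule, session_index = 1,
                                      seed = NULL, rate = 4) {
  stopifnot(inherits(agent, "efp_agent"), inherits(schedule, "efp_schedule"))
  if (!any(schedule$label == "Regulate"))
    stop_param("schedule contains no Regulate blocks")
  if (session_index < 1) stop_param("`session_index` must be >= 1")
  dt <- 1 / rate
  n <- round(schedule_duration(schedule) * rate)
  times <- (seq_len(n) - 1) * dt
  labels <- schedule_label_at(schedule, times)
  gain <- agent_session_gain(agent, session_index)
  noise <- eval_with_seed(seed, function() {
    if (agent$noise_sd == 0) numeric(n) else
      stats::rnorm(n, 0, agent$noise_sd * sqrt(dt))
  })
  vals <- numeric(n)
  vals[1] <- agent$baseline_arousal + noise[1]
  if (n > 1) {
    adv <- agent_advance(vals[1], labels[-1], gain, agent, dt, noise[-1])
    vals[-1] <- adv$values
  }
  latent_series(vals, rate = rate, t0 = 0)
}
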