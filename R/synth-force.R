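# Synthetic stimulus-annotated isometric force traces.

#' Ground-truth parameters for a synthetic force session
#'
#' Describes the tetanic trace shape used by [gen_force_session()]: plateau
#' force, exponential relaxation time constant, post-tetanic residual offset,
#' additive noise, and the per-tetanus amplitude schedule of the 40-tetanus
#' fatigue train.
#'
#' @param plateau_force Tetanic plateau force, N (> 0).
#' @param relax_tau Exponential relaxation time constant, s (>= 0; 0 means
#'   instantaneous relaxation).
#' @param residual_offset Post-tetanic baseline shift, N.
#' @param noise_sd Additive Gaussian noise SD, N (>= 0).
#' @param fatigue_schedule Length-40 vector of fatigue-train plateau forces,
#'   N. Default: geometric decline `plateau_force * fatigue_ratio^(k-1)`.
#' @param fatigue_ratio Per-tetanus geometric decline ratio used when
#'   `fatigue_schedule` is `NULL`; the resulting fatigue index is
#'   `100 * fatigue_ratio^39`.
#' @return An object of class `trace_truth`.
#' @export
trace_truth <- function(plateau_force, relax_tau = 0.1, residual_offset = 0,
                        noise_sd = 0, fatigue_schedule = NULL,
                        fatigue_ratio = 1) {
  assert_scalar_num(plateau_force, "plateau_force", positive = TRUE)
  assert_scalar_num(relax_tau, "relax_tau", nonneg = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  if (is.null(fatigue_schedule)) {
    fatigue_schedule <- plateau_force * fatigue_ratio^(0:39)
  }
  if (length(fatigue_schedule) != 40 || any(fatigue_schedule < 0)) {
    stop_grmd("invalid_spec",
              "fatigue_schedule must be 40 non-negative forces")
  }
  structure(
    list(plateau_force = plateau_force, relax_tau = relax_tau,
         residual_offset = residual_offset, noise_sd = noise_sd,
         fatigue_schedule = fatigue_schedule),
    class = "trace_truth"
  )
}

#' Stimulation protocol for a force session
#'
#' Default timing follows the in-vivo protocol: six 2 s tetanic stimulations
#' at 1-minute onset spacing, followed by a 40-tetanus fatigue train at 3 s
#' onset spacing.
#'
#' @param sampling_rate Samples per second; must be >= 200 Hz so the 100 ms
#'   relaxation point is resolved.
#' @param tetanus_duration Stimulation duration, s.
#' @param tetanic_gap Onset-to-onset spacing of the six tetani, s.
#' @param fatigue_gap Onset-to-onset spacing of the fatigue train, s.
#' @param n_tetanic,n_fatigue Number of tetanic / fatigue stimulations.
#' @param lead_in Pre-stimulus baseline duration, s.
#' @param tail Recording continued after the last stimulation, s.
#' @param rise_tau Saturating onset time constant, s.
#' @return An object of class `force_protocol`.
#' @export
force_protocol <- function(sampling_rate = 1000, tetanus_duration = 2,
                           tetanic_gap = 60, fatigue_gap = 3,
                           n_tetanic = 6, n_fatigue = 40,
                           lead_in = 1, tail = 2, rise_tau = 0.03) {
  if (sampling_rate < 200) {
    stop_grmd("invalid_protocol",
              "sampling rate %.0f Hz too low: need >= 200 Hz to resolve the 100 ms relaxation point",
              sampling_rate)
  }
  if (tetanus_duration <= 0 || tetanic_gap <= tetanus_duration ||
      (n_fatigue > 0 && fatigue_gap <= tetanus_duration)) {
    stop_grmd("invalid_protocol", "stimulation gaps must exceed the tetanus duration")
  }
  structure(
    list(sampling_rate = sampling_rate, tetanus_duration = tetanus_duration,
         tetanic_gap = tetanic_gap, fatigue_gap = fatigue_gap,
         n_tetanic = n_tetanic, n_fatigue = n_fatigue,
         lead_in = lead_in, tail = tail, rise_tau = rise_tau),
    class = "force_protocol"
  )
}

#' Generate a synthetic stimulus-annotated force session
#'
#' Builds a uniformly sampled force trace containing the six tetanic epochs
#' and the 40-tetanus fatigue train. Within each epoch the force rises with a
#' saturating onset towards the epoch's plateau, then relaxes exponentially
#' with time constant `truth$relax_tau` towards `baseline +
#' residual_offset`; the residual offset is held for 1 s after stimulation
#' end and then ramps back to baseline, so the pre-stimulus baseline of the
#' next epoch is clean. Gaussian noise of SD `truth$noise_sd` is added.
#'
#' @param truth A [trace_truth()] object.
#' @param protocol A [force_protocol()] object.
#' @param body_weight Dog body weight, kg (> 0).
#' @param side `"left"` or `"right"`.
#' @param seed Integer seed (identical inputs + seed give identical traces).
#' @return An object of class `force_session`: list with `time`, `force`
#'   (numeric vectors), `epochs` (tibble `t_on`, `t_off`, `phase`, `index`),
#'   `body_weight`, `side`, `sampling_rate`, and the generating `truth`.
#' @export
gen_force_session <- function(truth, protocol = force_protocol(),
                              body_weight = 12, side = "left", seed = 1L) {
  stopifnot(inherits(truth, "trace_truth"), inherits(protocol, "force_protocol"))
  assert_scalar_num(body_weight, "body_weight", positive = TRUE)
  side <- match.arg(side, c("left", "right"))

  p <- protocol
  onsets_tet <- p$lead_in + (seq_len(p$n_tetanic) - 1) * p$tetanic_gap
  fat_start <- if (p$n_tetanic > 0) {
    max(onsets_tet) + p$tetanic_gap
  } else p$lead_in
  onsets_fat <- fat_start + (seq_len(p$n_fatigue) - 1) * p$fatigue_gap
  epochs <- tibble(
    t_on = c(onsets_tet, onsets_fat),
    t_off = c(onsets_tet, onsets_fat) + p$tetanus_duration,
    phase = c(rep("tetanic", p$n_tetanic), rep("fatigue", p$n_fatigue)),
    index = c(seq_len(p$n_tetanic), seq_len(p$n_fatigue))
  )
  total_t <- max(epochs$t_off) + p$tail
  dt <- 1 / p$sampling_rate
  time <- seq(0, total_t, by = dt)
  force <- numeric(length(time))

  amps <- c(rep(truth$plateau_force, p$n_tetanic), truth$fatigue_schedule[seq_len(p$n_fatigue)])
  off <- truth$residual_offset
  for (e in seq_len(nrow(epochs))) {
    a <- amps[e]
    t_on <- epochs$t_on[e]; t_off <- epochs$t_off[e]
    in_ep <- time >= t_on & time < t_off
    force[in_ep] <- force[in_ep] +
      a * (1 - exp(-(time[in_ep] - t_on) / p$rise_tau))
    f_end <- a * (1 - exp(-(t_off - t_on) / p$rise_tau))
    # relaxation + residual plateau (1 s), then 0.5 s linear return
    post <- time >= t_off & time < t_off + 1
    if (truth$relax_tau > 0) {
      force[post] <- force[post] + off +
        (f_end - off) * exp(-(time[post] - t_off) / truth$relax_tau)
    } else {
      force[post] <- force[post] + off
    }
    ramp <- time >= t_off + 1 & time < t_off + 1.5
    force[ramp] <- force[ramp] + off * (1 - (time[ramp] - t_off - 1) / 0.5)
  }
  if (truth$noise_sd > 0) {
    force <- with_seed(seed, force + rnorm(length(force), 0, truth$noise_sd))
  }

  structure(
    list(time = time, force = force, epochs = epochs,
         body_weight = body_weight, side = side,
         sampling_rate = p$sampling_rate, truth = truth),
    class = "force_session"
  )
}
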