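# In-vivo isometric force indices from stimulus-annotated traces.

epoch_row <- function(session, phase, index) {
  e <- session$epochs
  r <- which(e$phase == phase & e$index == index)
  if (length(r) != 1) {
    stop_grmd("bounds_error", "no %s epoch with index %d", phase, index)
  }
  r
}

window_mean <- function(session, t0, t1) {
  if (t0 < min(session$time) || t1 > max(session$time)) {
    stop_grmd("bounds_error",
              "window [%.3f, %.3f] s outside the recorded trace", t0, t1)
  }
  sel <- session$time >= t0 & session$time <= t1
  mean(session$force[sel])
}

#' Tetanic plateau force of one stimulation epoch
#'
#' Baseline-subtracted plateau force: mean force over the second half of the
#' stimulation epoch minus the mean over the 200 ms preceding stimulation
#' onset.
#'
#' @param session A `force_session`.
#' @param phase `"tetanic"` or `"fatigue"`.
#' @param index Epoch index within the phase.
#' @return Plateau force, N.
#' @export
tetanic_force <- function(session, phase = "tetanic", index = 1) {
  stopifnot(inherits(session, "force_session"))
  r <- epoch_row(session, phase, index)
  t_on <- session$epochs$t_on[r]
  t_off <- session$epochs$t_off[r]
  if (t_off - t_on < 1) {
    stop_grmd("bounds_error", "epoch shorter than 1 s cannot hold a plateau")
  }
  baseline <- window_mean(session, t_on - 0.2, t_on - 1 / session$sampling_rate)
  plateau <- window_mean(session, t_on + 0.5 * (t_off - t_on), t_off)
  plateau - baseline
}

#' Session-level force metrics over the six tetanic stimulations
#'
#' Mean tetanic force over the six tetani and the body-weight-normalized
#' relative force index (N/kg).
#'
#' @param session A `force_session` containing exactly six tetanic epochs.
#' @return Tibble with `mean_tetanic_force_n`, `relative_force_n_kg`,
#'   `body_weight_kg`, `side`.
#' @export
session_metrics <- function(session) {
  stopifnot(inherits(session, "force_session"))
  n_tet <- sum(session$epochs$phase == "tetanic")
  if (n_tet != 6) {
    stop_grmd("protocol_error",
              "expected 6 tetanic stimulations, found %d", n_tet)
  }
  forces <- vapply(1:6, function(i) tetanic_force(session, "tetanic", i),
                   numeric(1))
  mtf <- mean(forces)
  tibble(
    mean_tetanic_force_n = mtf,
    relative_force_n_kg = mtf / session$body_weight,
    body_weight_kg = session$body_weight,
    side = session$side
  )
}

#' Fatigue index over the 40-tetanus train
#'
#' Force of the last fatigue tetanus as a percentage of the first:
#' `100 * F_last / F_first`.
#'
#' @param session A `force_session` with at least two fatigue epochs.
#' @return Fatigue index, percent.
#' @export
fatigue_index <- function(session) {
  stopifnot(inherits(session, "force_session"))
  idx <- session$epochs$index[session$epochs$phase == "fatigue"]
  if (length(idx) < 2) {
    stop_grmd("protocol_error", "need >= 2 fatigue tetani, found %d",
              length(idx))
  }
  f_first <- tetanic_force(session, "fatigue", min(idx))
  f_last <- tetanic_force(session, "fatigue", max(idx))
  if (f_first <= 0) {
    stop_grmd("undefined_index",
              "first fatigue tetanus force %.3f N is not positive", f_first)
  }
  100 * f_last / f_first
}

#' Post-tetanic relaxation metrics of one epoch
#'
#' Computes, from the baseline-subtracted and 5 ms median-smoothed trace:
#' the 100 ms relaxation level `r100 = 100 * (F_plateau - f(t_off + 100 ms))
#' / F_plateau`, and the post-tetanic residual contraction `100 *
#' (baseline_after - baseline_before) / F_plateau`, where `baseline_after`
#' is the mean over a 100 ms window centred 500 ms after stimulation end.
#'
#' @param session A `force_session` extending at least 600 ms past the
#'   epoch's end.
#' @param phase,index Epoch selector as in [tetanic_force()].
#' @return Tibble with `absolute_force_n`, `r100_pct`,
#'   `residual_contraction_pct`.
#' @export
relaxation_metrics <- function(session, phase = "tetanic", index = 1) {
  stopifnot(inherits(session, "force_session"))
  r <- epoch_row(session, phase, index)
  t_on <- session$epochs$t_on[r]
  t_off <- session$epochs$t_off[r]
  if (max(session$time) < t_off + 0.6) {
    stop_grmd("bounds_error",
              "trace must extend >= 600 ms past the end of stimulation")
  }
  fs <- session$sampling_rate
  # smooth a slice around the epoch only (5 ms running median)
  sel <- session$time >= t_on - 0.3 & session$time <= t_off + 0.7
  t_s <- session$time[sel]
  k <- round(0.005 * fs)
  if (k %% 2 == 0) k <- k + 1
  f_s <- if (k >= 3) as.numeric(runmed(session$force[sel], k)) else
    session$force[sel]

  baseline_before <- mean(f_s[t_s >= t_on - 0.2 & t_s < t_on])
  plateau <- mean(f_s[t_s >= t_on + 0.5 * (t_off - t_on) & t_s <= t_off]) -
    baseline_before
  if (plateau <= 0) {
    stop_grmd("undefined_index", "non-positive plateau force in epoch")
  }
  i100 <- which.min(abs(t_s - (t_off + 0.1)))
  f100 <- f_s[i100] - baseline_before
  baseline_after <- mean(f_s[t_s >= t_off + 0.45 & t_s <= t_off + 0.55]) -
    baseline_before
  tibble(
    absolute_force_n = plateau,
    r100_pct = 100 * (plateau - f100) / plateau,
    residual_contraction_pct = 100 * baseline_after / plateau
  )
}

#' All force indices of one session
#'
#' Convenience wrapper: session metrics, fatigue index, and relaxation
#' metrics of the last tetanic epoch, in one row.
#'
#' @param session A `force_session`.
#' @return One-row tibble.
#' @export
force_session_summary <- function(session) {
  sm <- session_metrics(session)
  rx <- relaxation_metrics(session, "tetanic",
                           max(session$epochs$index[session$epochs$phase == "tetanic"]))
  dplyr::bind_cols(
    sm,
    tibble(fatigue_index_pct = fatigue_index(session)),
    rx[, c("r100_pct", "residual_contraction_pct")]
  )
}
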