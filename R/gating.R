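# Prospective respiratory-gating simulation. A pneumatic-pillow trace of an
# anesthetized mouse is emulated as an asymmetric breathing cycle: a fast
# raised-cosine inhale/exhale excursion followed by an end-expiratory plateau
# occupying most of the cycle. The acquisition scheme places one trigger near
# the end of inhale (a causal level crossing on the rising trace) and a second
# trigger delayed by ~350 ms to land in the end-expiration plateau.

#' Trigger-detection configuration
#'
#' @param level trigger level as a fraction of the running cycle amplitude,
#'   in (0, 1] (default 0.9: near end of inhale on the rising side).
#' @param delay_ms delay of the second (end-expiration) trigger (default 350).
#' @param refractory_ms minimum spacing between first triggers (default 300).
#' @return An object of class `trigger_config`.
#' @export
trigger_config <- function(level = 0.9, delay_ms = 350, refractory_ms = 300) {
  if (level <= 0 || level > 1) stop("level must lie in (0, 1]")
  if (delay_ms < 0) stop("delay_ms must be >= 0")
  if (refractory_ms < 0) stop("refractory_ms must be >= 0")
  structure(list(level = level, delay_ms = delay_ms,
                 refractory_ms = refractory_ms), class = "trigger_config")
}

#' Simulate a respiratory trace
#'
#' Each cycle consists of an active excursion of duration
#' `(1 - plateau_fraction) * period` — displacement
#' `A * (1 - cos(2*pi*tau/active)) / 2`, peaking halfway — followed by a
#' baseline plateau (end-expiration). Cycle-to-cycle period jitter and
#' additive sample noise are controlled by `seed`.
#'
#' @param period_ms nominal breathing period (default 600 ms, ~100
#'   breaths/min under isoflurane).
#' @param amplitude peak displacement (arbitrary units, default 1).
#' @param plateau_fraction fraction of the cycle spent at the end-expiratory
#'   plateau, in (0, 1) (default 0.7).
#' @param jitter relative SD of the per-cycle period (default 0).
#' @param noise additive displacement noise SD as a fraction of amplitude
#'   (default 0).
#' @param duration_ms trace length; must cover at least 3 nominal cycles.
#' @param dt_ms sampling interval (default 2 ms).
#' @param seed integer RNG seed.
#' @return An object of class `resp_trace`: sample `time_ms`/`displacement`
#'   vectors plus the generator's cycle table (start, period, active duration
#'   and peak time per cycle) used as the phase ground truth.
#' @export
simulate_trace <- function(period_ms = 600, amplitude = 1,
                           plateau_fraction = 0.7, jitter = 0, noise = 0,
                           duration_ms = 12000, dt_ms = 2, seed = 1L) {
  if (plateau_fraction <= 0 || plateau_fraction >= 1)
    stop("plateau_fraction must lie in (0, 1)")
  if (period_ms <= 0 || dt_ms <= 0) stop("period and dt must be positive")
  if (duration_ms < 3 * period_ms)
    stop("duration must cover at least 3 cycles")
  n_cycles <- ceiling(duration_ms / (period_ms * (1 - min(0.9, 2 * jitter)))) + 2L
  eps <- if (jitter > 0)
    withr::with_seed(seed, pmin(2, pmax(-2, stats::rnorm(n_cycles))))
  else rep(0, n_cycles)
  periods <- pmax(0.2 * period_ms, period_ms * (1 + jitter * eps))
  starts <- c(0, cumsum(periods))[seq_len(n_cycles)]
  keep <- starts < duration_ms
  starts <- starts[keep]; periods <- periods[keep]
  active <- (1 - plateau_fraction) * periods
  peaks <- starts + active / 2

  t <- seq(0, duration_ms, by = dt_ms)
  ci <- findInterval(t, starts)
  tau <- t - starts[ci]
  disp <- ifelse(tau < active[ci],
                 amplitude * (1 - cos(2 * pi * tau / active[ci])) / 2, 0)
  if (noise > 0) {
    dn <- withr::with_seed(seed + 1L,
                           stats::rnorm(length(t), sd = noise * amplitude))
    disp <- disp + dn
  }
  structure(
    list(time_ms = t, displacement = disp, period_ms = period_ms,
         amplitude = amplitude, plateau_fraction = plateau_fraction,
         cycles = tibble::tibble(start = starts, period = periods,
                                 active = active, peak = peaks)),
    class = "resp_trace")
}

#' Ground-truth respiratory phase at a time point
#'
#' Uses the generator's known cycle structure: `peak_inspiration` within
#' +-5\% of the cycle period around the cycle peak, `end_expiration` inside
#' the plateau, otherwise `transition`.
#'
#' @param trace a [simulate_trace()] result.
#' @param time time(s) in ms within the trace.
#' @return Character vector of phase labels.
#' @export
phase_at <- function(trace, time) {
  stopifnot(inherits(trace, "resp_trace"))
  if (any(time < 0 | time > max(trace$time_ms)))
    stop("time outside the trace")
  cyc <- trace$cycles
  ci <- findInterval(time, cyc$start)
  tau <- time - cyc$start[ci]
  out <- rep("transition", length(time))
  out[tau >= cyc$active[ci]] <- "end_expiration"
  out[abs(time - cyc$peak[ci]) <= 0.05 * cyc$period[ci]] <- "peak_inspiration"
  out
}

#' Detect end-of-inhale triggers on a trace (causal)
#'
#' Emulates a real-time monitor: a running amplitude estimate is kept as the
#' mean of the last (up to) 3 observed cycle peaks; a trigger fires at the
#' first sample where the rising displacement crosses `level * amplitude`,
#' subject to the refractory period. No triggers are emitted before the first
#' full cycle has been observed, and a flat trace yields none.
#'
#' @param trace a [simulate_trace()] result.
#' @param config a [trigger_config()].
#' @return Numeric vector of trigger times (ms).
#' @export
detect_inhale_triggers <- function(trace, config = trigger_config()) {
  stopifnot(inherits(trace, "resp_trace"), inherits(config, "trigger_config"))
  t <- trace$time_ms; d <- trace$displacement
  peaks <- numeric(0)        # last <= 3 observed cycle peak heights
  cur_max <- 0               # running max since the last recorded peak
  grmax <- 0                 # global running max (causal scale reference)
  suppress <- FALSE          # ignore the falling tail after a recorded peak
  amp <- NA_real_
  last_trig <- -Inf
  triggers <- numeric(0)
  for (i in seq_along(t)) {
    di <- d[i]
    if (di > grmax) grmax <- di
    if (suppress) {
      # wait for return near baseline before re-arming the peak tracker
      if (di < 0.15 * peaks[length(peaks)]) suppress <- FALSE
    } else {
      if (di > cur_max) cur_max <- di
      if (grmax > 0 && cur_max > 0.5 * grmax && di < 0.3 * cur_max) {
        # excursion over: record its peak, update the running amplitude
        peaks <- c(peaks, cur_max)
        if (length(peaks) > 3L) peaks <- peaks[-1L]
        amp <- mean(peaks)
        cur_max <- 0
        suppress <- TRUE
      }
    }
    if (!is.na(amp) && amp > 0 && i > 1L &&
        di >= config$level * amp && d[i - 1L] < config$level * amp &&
        di > d[i - 1L] && t[i] - last_trig >= config$refractory_ms) {
      triggers <- c(triggers, t[i])
      last_trig <- t[i]
    }
  }
  triggers
}

#' Delayed (end-expiration) triggers
#'
#' Each first trigger shifted by `delay_ms`; delayed times falling beyond the
#' trace end are dropped with a message.
#'
#' @param triggers sorted first-trigger times (ms).
#' @param delay_ms trigger delay (default 350 ms).
#' @param trace_end_ms end of the trace; defaults to `Inf` (keep all).
#' @return Numeric vector of second-trigger times.
#' @export
delayed_triggers <- function(triggers, delay_ms = 350, trace_end_ms = Inf) {
  stopifnot(!is.unsorted(triggers), delay_ms >= 0)
  out <- triggers + delay_ms
  drop <- out > trace_end_ms
  if (any(drop))
    message(sum(drop), " delayed trigger(s) beyond trace end dropped")
  out[!drop]
}

#' Score a gating configuration against the ground-truth phases
#'
#' Runs detection, applies the delayed trigger, and reports the fraction of
#' first triggers landing in the peak-inspiration window and of second
#' triggers landing in the end-expiration plateau.
#'
#' @inheritParams detect_inhale_triggers
#' @return A list: `first_trigger_accuracy`, `second_trigger_accuracy`,
#'   `n_first`, `n_second`.
#' @export
score_gating <- function(trace, config = trigger_config()) {
  t1 <- detect_inhale_triggers(trace, config)
  t2 <- suppressMessages(
    delayed_triggers(t1, config$delay_ms, max(trace$time_ms)))
  list(
    first_trigger_accuracy =
      if (length(t1)) mean(phase_at(trace, t1) == "peak_inspiration") else NA_real_,
    second_trigger_accuracy =
      if (length(t2)) mean(phase_at(trace, t2) == "end_expiration") else NA_real_,
    n_first = length(t1), n_second = length(t2))
}
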