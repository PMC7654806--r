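# Streaming particle-counting algorithms.
#
# All three detectors operate on the occlusion deviation (baseline minus
# sample): larvae block light, so a deeper dip is a larger deviation and
# "above threshold" means deeper occlusion.

#' Smoothed z-score detector parameters
#'
#' The device's adaptive algorithm: a moving-window baseline mean and SD are
#' maintained over the last `lag` samples; a sample is flagged when its
#' occlusion deviation exceeds `z_start` baseline standard deviations; a count
#' fires after `n_above` consecutive flagged samples. After a count the
#' detector is disarmed until the re-arm rule is met, which is what separates
#' clustered individuals: either the deviation drops by at least
#' `decline_amount` units from its running peak (default), or `n_decline`
#' consecutive declining deviations are seen. Exactly one of the two re-arm
#' rules is active. Flagged samples enter the baseline with weight
#' `influence`; the default 0 excludes passing larvae from the baseline so a
#' pulse cannot inflate the SD, while still tracking slow drift.
#'
#' @param z_start Standard deviations needed to begin recording a particle.
#' @param n_above Consecutive flagged samples required to register a count.
#' @param decline_amount Absolute deviation drop (sensor units) from the
#'   running peak that re-arms the detector. Default 50, half the default
#'   pulse amplitude, so genuine pulse boundaries re-arm while plateau noise
#'   does not.
#' @param n_decline Alternative re-arm rule: consecutive declining deviations.
#'   Supply `n_decline` *instead of* `decline_amount`.
#' @param lag Baseline window length in samples (default 500 = 50 msec at the
#'   default sampling rate: long against a ~2 msec pulse, short against drift).
#' @param influence Weight of flagged samples in the baseline update, in [0,1].
#' @param sigma_floor Lower clamp on the baseline SD so z stays computable on
#'   noiseless traces.
#' @return An object of class `szs_params`.
#' @export
szs_params <- function(z_start = 3.5, n_above = 3, decline_amount = 50,
                       n_decline = NULL, lag = 500, influence = 0,
                       sigma_floor = 1e-6) {
  if (!is.null(n_decline) && !missing(decline_amount))
    stop("supply exactly one of decline_amount / n_decline")
  if (!is.null(n_decline)) decline_amount <- NULL
  if (z_start <= 0) stop("z_start must be positive")
  if (n_above < 1) stop("n_above must be >= 1")
  if (lag < 2) stop("lag must be >= 2")
  if (influence < 0 || influence > 1) stop("influence must be in [0,1]")
  if (!is.null(decline_amount) && decline_amount <= 0)
    stop("decline_amount must be positive")
  if (!is.null(n_decline) && n_decline < 1) stop("n_decline must be >= 1")
  structure(list(z_start = z_start, n_above = as.integer(n_above),
                 decline_amount = decline_amount,
                 n_decline = if (is.null(n_decline)) NULL else as.integer(n_decline),
                 lag = as.integer(lag), influence = influence,
                 sigma_floor = sigma_floor),
            class = "szs_params")
}

#' Threshold-reset detector parameters
#'
#' Counts a particle after `n_above` consecutive samples above a fixed
#' deviation threshold and re-arms only after `n_below` consecutive samples
#' below it, so merged pulses that never return below threshold count once.
#'
#' @param threshold Occlusion deviation threshold, sensor units.
#' @param n_above Consecutive samples above threshold to count.
#' @param n_below Consecutive samples below threshold to re-arm.
#' @param baseline Fixed baseline intensity; `NA` (default) uses the trace
#'   median.
#' @export
threshold_reset_params <- function(threshold = 50, n_above = 3, n_below = 3,
                                   baseline = NA_real_) {
  if (threshold <= 0 || n_above < 1 || n_below < 1)
    stop("threshold, n_above and n_below must be positive")
  structure(list(threshold = threshold, n_above = as.integer(n_above),
                 n_below = as.integer(n_below), baseline = baseline),
            class = "threshold_reset_params")
}

#' Refractory-period detector parameters
#'
#' Counts at each upward threshold crossing of the occlusion deviation,
#' ignoring crossings within `refractory` msec of the previous count.
#'
#' @inheritParams threshold_reset_params
#' @param refractory Minimum time between counts, msec.
#' @export
refractory_params <- function(threshold = 50, refractory = 5,
                              baseline = NA_real_) {
  if (threshold <= 0) stop("threshold must be positive")
  if (refractory < 0) stop("refractory must be non-negative")
  structure(list(threshold = threshold, refractory = refractory,
                 baseline = baseline),
            class = "refractory_params")
}

count_events_df <- function(idx, dev, sampling_rate) {
  data.frame(sample_index = as.integer(idx),
             time_msec = (as.integer(idx) - 1L) / sampling_rate,
             peak_deviation = dev)
}

#' Streaming smoothed z-score counting
#'
#' Single sample-by-sample pass, as the device performs in real time. The
#' first `lag` samples initialise the baseline and cannot emit counts (the
#' device is calibrated before dispensing begins). A count fires on the
#' `n_above`-th consecutive flagged sample, so a pulse truncated by the end of
#' the trace that has already satisfied `n_above` still counts.
#'
#' @param trace A `sensor_trace` (or plain numeric intensity vector).
#' @param params [szs_params()].
#' @param frozen Optional `list(mu =, sigma =)` freezing the baseline
#'   statistics (no adaptation, no warm-up); used for threshold-monotonicity
#'   analysis.
#' @return data.frame of count events (`sample_index`, `time_msec`,
#'   `peak_deviation`) with attribute `"flagged"`, the per-sample flag vector.
#' @export
smoothed_zscore_count <- function(trace, params = szs_params(), frozen = NULL) {
  stopifnot(inherits(params, "szs_params"))
  y <- if (inherits(trace, "sensor_trace")) trace$intensity else as.numeric(trace)
  sr <- if (inherits(trace, "sensor_trace")) trace$sampling_rate else 10
  n <- length(y)
  lag <- params$lag
  use_drop <- !is.null(params$decline_amount)
  flagged <- rep(FALSE, n)
  ev_idx <- integer(0)
  ev_dev <- numeric(0)
  if (is.null(frozen)) {
    if (n <= lag) stop("trace must be longer than lag")
    filt <- numeric(n)
    filt[1:lag] <- y[1:lag]
    s <- sum(filt[1:lag])
    s2 <- sum(filt[1:lag]^2)
    start <- lag + 1L
  } else {
    mu_f <- frozen$mu
    sig_f <- max(frozen$sigma, params$sigma_floor)
    start <- 1L
  }
  armed <- TRUE
  run_flag <- 0L
  run_peak <- -Inf       # peak deviation of current flagged run
  rearm_peak <- -Inf     # running peak deviation since last count
  decline_run <- 0L
  prev_dev <- NA_real_
  for (i in start:n) {
    if (is.null(frozen)) {
      mu <- s / lag
      sig <- sqrt(max((s2 - s * s / lag) / (lag - 1), 0))
      if (sig < params$sigma_floor) sig <- params$sigma_floor
    } else {
      mu <- mu_f
      sig <- sig_f
    }
    dev <- mu - y[i]
    fl <- dev > params$z_start * sig
    flagged[i] <- fl
    if (fl) {
      run_flag <- run_flag + 1L
      if (dev > run_peak) run_peak <- dev
    } else {
      run_flag <- 0L
      run_peak <- -Inf
    }
    if (!armed) {
      if (use_drop) {
        if (dev > rearm_peak) rearm_peak <- dev
        if (rearm_peak - dev >= params$decline_amount) armed <- TRUE
      } else {
        if (!is.na(prev_dev) && dev < prev_dev) decline_run <- decline_run + 1L
        else decline_run <- 0L
        if (decline_run >= params$n_decline) armed <- TRUE
      }
      if (armed) {          # a fresh run of n_above is required after re-arm
        run_flag <- 0L
        run_peak <- -Inf
      }
    }
    if (armed && fl && run_flag >= params$n_above) {
      ev_idx <- c(ev_idx, i)
      ev_dev <- c(ev_dev, run_peak)
      armed <- FALSE
      rearm_peak <- dev
      decline_run <- 0L
      run_flag <- 0L
      run_peak <- -Inf
    }
    prev_dev <- dev
    if (is.null(frozen)) {
      filt[i] <- if (fl) params$influence * y[i] + (1 - params$influence) * filt[i - 1L]
                 else y[i]
      s <- s + filt[i] - filt[i - lag]
      s2 <- s2 + filt[i]^2 - filt[i - lag]^2
    }
  }
  structure(count_events_df(ev_idx, ev_dev, sr), flagged = flagged)
}

resolve_baseline <- function(y, baseline) {
  if (is.na(baseline)) stats::median(y) else baseline
}

#' Streaming threshold-reset counting
#'
#' @param trace A `sensor_trace` or numeric vector.
#' @param params [threshold_reset_params()].
#' @return data.frame of count events with attribute `"flagged"`.
#' @export
threshold_reset_count <- function(trace, params = threshold_reset_params()) {
  stopifnot(inherits(params, "threshold_reset_params"))
  y <- if (inherits(trace, "sensor_trace")) trace$intensity else as.numeric(trace)
  sr <- if (inherits(trace, "sensor_trace")) trace$sampling_rate else 10
  if (length(y) == 0) stop("trace must be nonempty")
  base <- resolve_baseline(y, params$baseline)
  armed <- TRUE
  run_above <- 0L
  run_below <- 0L
  run_peak <- -Inf
  ev_idx <- integer(0)
  ev_dev <- numeric(0)
  flagged <- rep(FALSE, length(y))
  for (i in seq_along(y)) {
    dev <- base - y[i]
    if (dev > params$threshold) {
      flagged[i] <- TRUE
      run_above <- run_above + 1L
      run_below <- 0L
      if (dev > run_peak) run_peak <- dev
    } else {
      run_above <- 0L
      run_peak <- -Inf
      run_below <- run_below + 1L
      if (!armed && run_below >= params$n_below) armed <- TRUE
    }
    if (armed && run_above >= params$n_above) {
      ev_idx <- c(ev_idx, i)
      ev_dev <- c(ev_dev, run_peak)
      armed <- FALSE
    }
  }
  structure(count_events_df(ev_idx, ev_dev, sr), flagged = flagged)
}

#' Streaming refractory-period counting
#'
#' @param trace A `sensor_trace` or numeric vector.
#' @param params [refractory_params()].
#' @return data.frame of count events with attribute `"flagged"`.
#' @export
refractory_count <- function(trace, params = refractory_params()) {
  stopifnot(inherits(params, "refractory_params"))
  y <- if (inherits(trace, "sensor_trace")) trace$intensity else as.numeric(trace)
  sr <- if (inherits(trace, "sensor_trace")) trace$sampling_rate else 10
  if (length(y) == 0) stop("trace must be nonempty")
  base <- resolve_baseline(y, params$baseline)
  ev_idx <- integer(0)
  ev_dev <- numeric(0)
  flagged <- rep(FALSE, length(y))
  prev_above <- FALSE
  last_count_ms <- -Inf
  for (i in seq_along(y)) {
    dev <- base - y[i]
    above <- dev > params$threshold
    flagged[i] <- above
    if (above && !prev_above) {
      t_ms <- (i - 1L) / sr
      if (t_ms - last_count_ms >= params$refractory) {
        ev_idx <- c(ev_idx, i)
        ev_dev <- c(ev_dev, dev)
        last_count_ms <- t_ms
      }
    }
    prev_above <- above
  }
  structure(count_events_df(ev_idx, ev_dev, sr), flagged = flagged)
}

#' Dispatch a detector by name
#'
#' @param trace A `sensor_trace`.
#' @param params One of [szs_params()], [threshold_reset_params()],
#'   [refractory_params()].
#' @return Count-event data.frame.
#' @export
detect <- function(trace, params) {
  switch(class(params)[1],
         szs_params = smoothed_zscore_count(trace, params),
         threshold_reset_params = threshold_reset_count(trace, params),
         refractory_params = refractory_count(trace, params),
         stop("unknown detector parameter class: ", class(params)[1]))
}
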