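# Synthetic larva arrivals and sensor traces.
#
# Stream-splitting: each run uses one root seed; independent sub-seeds are
# derived arithmetically for arrivals (1), amplitudes (2), contaminants (3)
# and sensor noise (4), so each component is reproducible in isolation.

subseed <- function(seed, k) {
  as.integer((as.double(seed) %% 65011 * 7919 + k * 104729) %% 2147483629)
}

#' Larva arrival model
#'
#' @param lps Mean larvae per second passing the sensor (>= 0).
#' @param mode `"fixed"`: homogeneous Poisson arrivals at rate `lps`
#'   (reservoir held at constant level, the routine operating condition);
#'   `"depletion"`: inhomogeneous arrivals with instantaneous rate
#'   concentration x flow(t) as the reservoir drains.
#' @param duration Length of the simulated stream, seconds.
#' @param seed Root seed for the run.
#' @return An object of class `arrival_model`.
#' @export
arrival_model <- function(lps = 25, mode = c("fixed", "depletion"),
                          duration = 10, seed = 1) {
  mode <- match.arg(mode)
  if (lps < 0) stop("lps must be non-negative")
  if (duration < 0) stop("duration must be non-negative")
  structure(list(lps = lps, mode = mode, duration = duration, seed = seed),
            class = "arrival_model")
}

#' Sensor noise and baseline model
#'
#' The device reads raw light-intensity units; larvae occlude light so appear
#' as dips below the baseline. Calibration on the physical device requires the
#' baseline standard deviation to fall below the calibration limit (18 units).
#'
#' @param baseline Mean unobstructed intensity, sensor units.
#' @param noise_std Gaussian noise standard deviation, sensor units.
#' @param drift_rate Slow baseline drift, units/second.
#' @param calibration_limit Maximum baseline SD considered calibrated.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(baseline = 600, noise_std = 6, drift_rate = 0,
                        calibration_limit = 18) {
  if (noise_std < 0) stop("noise_std must be non-negative")
  structure(list(baseline = baseline, noise_std = noise_std,
                 drift_rate = drift_rate,
                 calibration_limit = calibration_limit),
            class = "noise_model")
}

#' Contaminant particle model
#'
#' Food particles, eggshells and electronic spikes: short, mostly shallow
#' occlusions with exponentially distributed amplitude.
#'
#' @param rate Contaminant events per second.
#' @param amp_mean Mean occlusion amplitude, sensor units.
#' @param width_msec Occlusion duration, msec (shorter than a larva transit).
#' @return An object of class `contaminant_model`.
#' @export
contaminant_model <- function(rate = 2, amp_mean = 20, width_msec = 0.4) {
  if (rate < 0 || amp_mean <= 0 || width_msec <= 0)
    stop("invalid contaminant model")
  structure(list(rate = rate, amp_mean = amp_mean, width_msec = width_msec),
            class = "contaminant_model")
}

#' Generate ground-truth larva arrival events
#'
#' Fixed-rate mode draws a homogeneous Poisson process at `lps`. Depletion
#' mode holds the reservoir concentration constant (larvae are well stirred)
#' and couples the arrival rate to the declining flow as the reservoir drains.
#' Pulse amplitudes are truncated-normal; body lengths default to 1 mm
#' (first-instar larva).
#'
#' @param model An [arrival_model()].
#' @param hydraulic A [hydraulic_state()]; required for depletion mode.
#' @param amplitude_mean,amplitude_sd,amplitude_floor Truncated-normal
#'   amplitude distribution, sensor units.
#' @param body_length Larva body length in mm.
#' @return A data.frame with columns `arrival_time` (s, sorted), `amplitude`
#'   and `body_length`.
#' @export
generate_arrivals <- function(model, hydraulic = NULL,
                              amplitude_mean = 100, amplitude_sd = 20,
                              amplitude_floor = 10, body_length = 1) {
  stopifnot(inherits(model, "arrival_model"))
  if (model$mode == "fixed") {
    set.seed(subseed(model$seed, 1))
    n <- stats::rpois(1, model$lps * model$duration)
    times <- sort(stats::runif(n, 0, model$duration))
  } else {
    if (is.null(hydraulic)) stop("depletion mode requires a hydraulic state")
    q0 <- state_flow(hydraulic)
    if (q0 <= 0) stop("depletion mode requires positive initial flow")
    conc <- model$lps / q0  # larvae/ml, constant while well-stirred
    set.seed(subseed(model$seed, 1))
    dt <- 0.05
    t0 <- 0
    times <- numeric(0)
    state <- hydraulic
    while (t0 < model$duration) {
      q <- state_flow(state)
      if (q <= 0) break
      step <- min(dt, model$duration - t0)
      k <- stats::rpois(1, conc * q * step)
      if (k > 0) times <- c(times, t0 + sort(stats::runif(k, 0, step)))
      state <- drain_step(state, step)
      t0 <- t0 + step
    }
    n <- length(times)
  }
  set.seed(subseed(model$seed, 2))
  amp <- rtruncnorm(n, amplitude_mean, amplitude_sd, amplitude_floor)
  data.frame(arrival_time = times, amplitude = amp,
             body_length = rep(body_length, n))
}

# truncated normal by rejection; vectorised resampling of rejects
rtruncnorm <- function(n, mean, sd, lower) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Synthesize the sampled light-intensity trace
#'
#' Builds `intensity(t) = baseline + drift * t + noise - occlusion(t)`, clipped
#' below at zero (full occlusion). Each larva contributes a rectangular dip of
#' depth `amplitude` lasting `(sensor_window + body_length) / velocity`;
#' simultaneous larvae superimpose additively. Contaminants add shorter,
#' exponentially distributed dips.
#'
#' @param events Arrival data.frame from [generate_arrivals()] (sorted by time).
#' @param noise A [noise_model()].
#' @param geometry A [capillary_geometry()].
#' @param velocity Stream velocity in mm/s (must be positive when events are
#'   present).
#' @param duration Trace duration in seconds.
#' @param sampling_rate Samples per msec (default 10, i.e. 10 kHz).
#' @param contaminants Optional [contaminant_model()].
#' @param seed Root seed (noise and contaminants are drawn from sub-streams).
#' @param ramp If `TRUE`, soften each dip with a 1-sample half-amplitude ramp.
#' @return An object of class `sensor_trace`: list with `intensity`,
#'   `sampling_rate` (samples/msec), `baseline`, `velocity`, `duration`,
#'   `truth` and `contaminant_truth` data.frames, and the models used.
#' @export
synthesize_trace <- function(events, noise = noise_model(),
                             geometry = capillary_geometry(),
                             velocity = stream_velocity(0.77, 1.0),
                             duration = NULL, sampling_rate = 10,
                             contaminants = NULL, seed = 1, ramp = FALSE) {
  stopifnot(inherits(noise, "noise_model"), inherits(geometry, "capillary_geometry"))
  if (nrow(events) > 0 && is.unsorted(events$arrival_time))
    stop("events must be sorted by arrival_time")
  if (nrow(events) > 0 && velocity <= 0)
    stop("zero velocity with nonempty events")
  if (is.null(duration)) {
    duration <- if (nrow(events)) max(events$arrival_time) + 0.1 else 1
  }
  sps <- sampling_rate * 1000          # samples per second
  n <- as.integer(round(duration * sps))
  tt <- (seq_len(n) - 1) / sps
  set.seed(subseed(seed, 4))
  base <- noise$baseline + noise$drift_rate * tt +
    stats::rnorm(n, 0, noise$noise_std)
  occl <- numeric(n)
  add_dip <- function(occl, t0, width_samples, amp) {
    i0 <- as.integer(floor(t0 * sps)) + 1L
    if (i0 > n) return(occl)
    i1 <- min(n, i0 + width_samples - 1L)
    occl[i0:i1] <- occl[i0:i1] + amp
    if (ramp) {
      if (i0 > 1) occl[i0 - 1L] <- occl[i0 - 1L] + amp / 2
      if (i1 < n) occl[i1 + 1L] <- occl[i1 + 1L] + amp / 2
    }
    occl
  }
  if (nrow(events) > 0) {
    for (j in seq_len(nrow(events))) {
      w <- max(1L, as.integer(round(
        (geometry$sensor_window + events$body_length[j]) / velocity * sps)))
      occl <- add_dip(occl, events$arrival_time[j], w, events$amplitude[j])
    }
  }
  contaminant_truth <- data.frame(arrival_time = numeric(0),
                                  amplitude = numeric(0))
  if (!is.null(contaminants) && contaminants$rate > 0) {
    set.seed(subseed(seed, 3))
    nc <- stats::rpois(1, contaminants$rate * duration)
    if (nc > 0) {
      ct <- sort(stats::runif(nc, 0, duration))
      ca <- stats::rexp(nc, 1 / contaminants$amp_mean)
      wc <- max(1L, as.integer(round(contaminants$width_msec * sampling_rate)))
      for (j in seq_len(nc)) occl <- add_dip(occl, ct[j], wc, ca[j])
      contaminant_truth <- data.frame(arrival_time = ct, amplitude = ca)
    }
  }
  structure(list(intensity = pmax(base - occl, 0),
                 sampling_rate = sampling_rate,
                 baseline = noise$baseline,
                 velocity = velocity,
                 duration = duration,
                 truth = events,
                 contaminant_truth = contaminant_truth,
                 noise = noise, geometry = geometry, seed = seed),
            class = "sensor_trace")
}

#' One-call trace simulation
#'
#' Convenience wrapper: arrivals plus trace from a single configuration.
#'
#' @inheritParams generate_arrivals
#' @inheritParams synthesize_trace
#' @param lps Mean larvae per second.
#' @param mode Arrival mode, see [arrival_model()].
#' @param hydraulic A [hydraulic_state()] used for velocity (and depletion).
#' @export
simulate_trace <- function(lps = 25, duration = 5, seed = 1,
                           mode = "fixed",
                           noise = noise_model(),
                           geometry = capillary_geometry(),
                           hydraulic = hydraulic_state(),
                           contaminants = NULL, sampling_rate = 10,
                           amplitude_mean = 100, amplitude_sd = 20,
                           amplitude_floor = 10, body_length = 1,
                           ramp = FALSE) {
  model <- arrival_model(lps = lps, mode = mode, duration = duration, seed = seed)
  ev <- generate_arrivals(model, hydraulic = hydraulic,
                          amplitude_mean = amplitude_mean,
                          amplitude_sd = amplitude_sd,
                          amplitude_floor = amplitude_floor,
                          body_length = body_length)
  v <- stream_velocity(state_flow(hydraulic), geometry$inner_diameter)
  synthesize_trace(ev, noise = noise, geometry = geometry, velocity = v,
                   duration = duration, sampling_rate = sampling_rate,
                   contaminants = contaminants, seed = seed, ramp = ramp)
}

#' Sample times of a trace, in seconds
#' @param trace A `sensor_trace`.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$intensity) - 1) / (trace$sampling_rate * 1000)
}

#' Estimated larvae-per-second from ground truth
#' @param trace A `sensor_trace`.
#' @export
truth_lps <- function(trace) nrow(trace$truth) / trace$duration

#' Calibration check on the quiescent baseline
#'
#' Rolling-window standard deviation of the intensity outside larva and
#' contaminant pulses; the trace passes when every window SD is below the
#' noise model's calibration limit.
#'
#' @param trace A `sensor_trace`.
#' @param window Rolling window length in samples.
#' @return Logical; attribute `"max_sd"` carries the worst window SD.
#' @export
is_calibrated <- function(trace, window = 200) {
  y <- trace$intensity
  n <- length(y)
  sps <- trace$sampling_rate * 1000
  inpulse <- rep(FALSE, n)
  mark <- function(t0, w) {
    i0 <- as.integer(floor(t0 * sps)) + 1L
    if (i0 <= n) inpulse[i0:min(n, i0 + w)] <<- TRUE
  }
  if (nrow(trace$truth)) {
    for (j in seq_len(nrow(trace$truth))) {
      w <- as.integer(round((trace$geometry$sensor_window +
                             trace$truth$body_length[j]) / trace$velocity * sps)) + 2L
      mark(trace$truth$arrival_time[j], w)
    }
  }
  if (nrow(trace$contaminant_truth)) {
    for (t0 in trace$contaminant_truth$arrival_time) mark(t0, 10L)
  }
  quiet <- y[!inpulse]
  m <- length(quiet)
  if (m < window) return(structure(TRUE, max_sd = NA_real_))
  cs <- cumsum(quiet)
  cs2 <- cumsum(quiet^2)
  i <- window:m
  s <- cs[i] - c(0, cs)[i - window + 1]
  s2 <- cs2[i] - c(0, cs2)[i - window + 1]
  v <- (s2 - s^2 / window) / (window - 1)
  mx <- sqrt(max(pmax(v, 0)))
  structure(mx < trace$noise$calibration_limit, max_sd = mx)
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf(paste0("sensor trace: %.2f s at %g samples/msec (%d samples), ",
                     "%d larvae (%.1f LPS), %d contaminants\n"),
              x$duration, x$sampling_rate, length(x$intensity),
              nrow(x$truth), truth_lps(x), nrow(x$contaminant_truth)))
  invisible(x)
}
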