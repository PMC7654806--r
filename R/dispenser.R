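# Closed-loop dispensing simulation.
#
# The pinch valve sits upstream of the sensor, so closing it stops the whole
# water column: larvae between the sensor and the outlet (the dead segment)
# stay in place, counted but not dispensed, and are flushed out -- dispensed
# but not counted -- at the start of the next run.

#' Pinch-valve model
#'
#' @param closure_lag Time between the controller reaching the target count
#'   and full flow stoppage, msec. Default 0 (instantaneous closure).
#' @export
valve_model <- function(closure_lag = 0) {
  if (closure_lag < 0) stop("closure_lag must be non-negative")
  structure(list(closure_lag = closure_lag), class = "valve_model")
}

#' Expected larvae in the dead segment at closure
#'
#' Under instantaneous closure, the expected number of larvae that have passed
#' the sensor but not yet left the capillary is the arrival rate times the
#' dead-segment transit time.
#'
#' @param lps Larvae per second.
#' @param dead_length Dead-segment length, cm.
#' @param velocity Stream velocity, mm/s (positive).
#' @return Expected larvae below the sensor.
#' @examples
#' residual_below_sensor(25, 1.5, 980)  # ~0.38
#' @export
residual_below_sensor <- function(lps, dead_length = 1.5, velocity) {
  if (any(velocity <= 0)) stop("velocity must be positive")
  if (any(lps < 0)) stop("lps must be non-negative")
  lps * (dead_length * 10 / velocity)
}

#' Residual contribution to between-run deviation
#'
#' @param mean_residual Mean larvae left below the sensor per run.
#' @param target Target count per run.
#' @return Percent contribution to between-run deviation from the target.
#' @examples
#' residual_contribution(1.4, 100)  # 1.4
#' @export
residual_contribution <- function(mean_residual, target) {
  if (any(target < 1)) stop("target must be >= 1")
  100 * mean_residual / target
}

#' Simulate one dispensing run
#'
#' Simulates larva arrivals (and, unless `detector = "truth"`, the sensor
#' trace and streaming detection), closes the valve when the detector count
#' reaches `target`, lets flow continue for the valve closure lag, then
#' resolves which larvae were dispensed, which remain in the dead segment
#' (`residual_out`) and how many uncounted carryover larvae from the previous
#' run were flushed into this one's tally.
#'
#' With `detector = "truth"` detection is perfect: every ground-truth arrival
#' is counted, and the conservation identity
#' `dispensed = counted - residual_out + carryover_in` holds exactly.
#'
#' @param target Target number of larvae (>= 1).
#' @param lps Mean larvae per second.
#' @param detector `"truth"` or detector parameters ([szs_params()],
#'   [threshold_reset_params()], [refractory_params()]).
#' @param valve A [valve_model()].
#' @param carryover_in Uncounted larvae flushed in from the previous run.
#' @param seed Root seed for the run.
#' @param noise,geometry,contaminants,sampling_rate Trace synthesis settings,
#'   see [synthesize_trace()].
#' @param hydraulic A [hydraulic_state()]; sets flow and velocity. In
#'   `mode = "depletion"` the reservoir drains during the run and the run is
#'   marked incomplete if it empties before the target is reached.
#' @param mode `"fixed"` (constant level, the routine condition) or
#'   `"depletion"`.
#' @param amplitude_mean,amplitude_sd,amplitude_floor,body_length Pulse
#'   amplitude and size settings, see [generate_arrivals()].
#' @param max_horizon Simulation cap in seconds before declaring the run
#'   incomplete.
#' @return An object of class `dispense_run`: target, counted, dispensed,
#'   residual_out, carryover_in, duration (s), mean_lps, complete, detector
#'   label and settings.
#' @export
run_dispense <- function(target, lps = 25, detector = "truth",
                         valve = valve_model(), carryover_in = 0, seed = 1,
                         noise = noise_model(),
                         geometry = capillary_geometry(),
                         hydraulic = hydraulic_state(),
                         contaminants = NULL, sampling_rate = 10,
                         mode = c("fixed", "depletion"),
                         amplitude_mean = 100, amplitude_sd = 20,
                         amplitude_floor = 10, body_length = 1,
                         max_horizon = NULL) {
  mode <- match.arg(mode)
  if (target < 1) stop("target must be >= 1")
  if (lps <= 0) stop("lps must be positive")
  q0 <- state_flow(hydraulic)
  velocity <- stream_velocity(q0, geometry$inner_diameter)
  if (velocity <= 0) stop("no flow: open the valve / fill the reservoir")
  dead_time <- geometry$dead_length * 10 / velocity   # seconds
  lag_s <- valve$closure_lag / 1000
  if (is.null(max_horizon)) max_horizon <- 8 * target / lps + 30
  if (mode == "depletion") {
    # reservoir can only drain for as long as it holds water
    max_horizon <- min(max_horizon, hydraulic$volume / max(q0, 1e-9) + 1)
  }
  is_truth <- identical(detector, "truth")
  detector_label <- if (is_truth) "truth" else
    switch(class(detector)[1],
           szs_params = "smoothed_zscore",
           threshold_reset_params = "threshold_reset",
           refractory_params = "refractory",
           stop("unknown detector"))

  horizon <- min(max_horizon, 3 * target / lps + 2)
  repeat {
    model <- arrival_model(lps = lps, mode = mode, duration = horizon,
                           seed = seed)
    ev <- generate_arrivals(model, hydraulic = hydraulic,
                            amplitude_mean = amplitude_mean,
                            amplitude_sd = amplitude_sd,
                            amplitude_floor = amplitude_floor,
                            body_length = body_length)
    if (is_truth) {
      count_times <- ev$arrival_time
    } else {
      trace <- synthesize_trace(ev, noise = noise, geometry = geometry,
                                velocity = velocity, duration = horizon,
                                sampling_rate = sampling_rate,
                                contaminants = contaminants, seed = seed)
      counts <- detect(trace, detector)
      count_times <- counts$time_msec / 1000
    }
    if (length(count_times) >= target || horizon >= max_horizon) break
    horizon <- min(max_horizon, horizon * 2)
  }

  complete <- length(count_times) >= target
  t_close <- if (complete) count_times[target] + lag_s
             else if (length(count_times)) max(count_times) else horizon
  counted <- sum(count_times <= t_close)
  passed <- sum(ev$arrival_time <= t_close)
  dispensed_truth <- sum(ev$arrival_time <= t_close - dead_time)
  residual_out <- passed - dispensed_truth
  duration <- t_close
  structure(list(target = as.integer(target),
                 counted = as.integer(counted),
                 dispensed = as.integer(dispensed_truth + carryover_in),
                 residual_out = as.integer(residual_out),
                 carryover_in = as.integer(carryover_in),
                 duration = duration,
                 mean_lps = counted / duration,
                 complete = complete,
                 detector = detector_label,
                 detector_params = if (is_truth) NULL else unclass(detector),
                 lps_setting = lps,
                 seed = seed),
            class = "dispense_run")
}

#' Simulate a chain of consecutive dispensing runs
#'
#' Residual larvae left below the sensor at each valve closure are flushed
#' into the next run as uncounted carryover (no flushing between runs).
#'
#' @param n_runs Number of runs.
#' @param target Target per run.
#' @param seed Root seed; run `k` uses sub-seed `k` of this root.
#' @param carryover_in Carryover entering the first run.
#' @param ... Passed to [run_dispense()].
#' @return List of `dispense_run` objects (class `dispense_chain`).
#' @export
run_chain <- function(n_runs, target, seed = 1, carryover_in = 0, ...) {
  runs <- vector("list", n_runs)
  carry <- carryover_in
  for (k in seq_len(n_runs)) {
    runs[[k]] <- run_dispense(target, carryover_in = carry,
                              seed = subseed(seed, 100 + k), ...)
    carry <- runs[[k]]$residual_out
  }
  structure(runs, class = "dispense_chain")
}

#' Tabulate dispensing runs
#'
#' @param x A `dispense_run`, `dispense_chain`, or list of runs.
#' @param ... Unused.
#' @return data.frame with one row per run.
#' @export
runs_table <- function(x, ...) {
  runs <- if (inherits(x, "dispense_run")) list(x) else x
  if (length(runs) == 0) {
    return(data.frame(run_id = integer(0), target = integer(0),
                      counted = integer(0), dispensed = integer(0),
                      residual_out = integer(0), carryover_in = integer(0),
                      duration = numeric(0), mean_lps = numeric(0),
                      complete = logical(0), detector = character(0),
                      lps_setting = numeric(0), seed = integer(0)))
  }
  do.call(rbind, lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    data.frame(run_id = k, target = r$target, counted = r$counted,
               dispensed = r$dispensed, residual_out = r$residual_out,
               carryover_in = r$carryover_in, duration = r$duration,
               mean_lps = r$mean_lps, complete = r$complete,
               detector = r$detector, lps_setting = r$lps_setting,
               seed = r$seed)
  }))
}

#' @export
print.dispense_run <- function(x, ...) {
  cat(sprintf(paste0("dispense run [%s]: target %d, counted %d, dispensed %d ",
                     "(residual %d, carryover %d), %.2f s at %.1f LPS%s\n"),
              x$detector, x$target, x$counted, x$dispensed, x$residual_out,
              x$carryover_in, x$duration, x$mean_lps,
              if (x$complete) "" else " [INCOMPLETE]"))
  invisible(x)
}

#' @export
print.dispense_chain <- function(x, ...) {
  tab <- runs_table(x)
  cat(sprintf("chain of %d dispensing runs: mean dispensed %.2f (target %d)\n",
              nrow(tab), mean(tab$dispensed), tab$target[1]))
  invisible(x)
}
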