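#' Capillary geometry of the counting head
#'
#' Physical configuration of the glass capillary that carries the larva stream
#' past the optical sensor.
#'
#' @param inner_diameter Capillary internal diameter in mm (default 1.0, the
#'   standard capillary supplied with the device).
#' @param sensor_window Length of the optical sensing window in mm (default 2.0).
#' @param dead_length Length of capillary below the sensor in cm (default 1.5).
#'   Larvae in this "dead segment" at valve closure have been counted but not
#'   yet dispensed.
#' @return An object of class `capillary_geometry`.
#' @examples
#' geom <- capillary_geometry()
#' capillary_area(geom)  # mm^2
#' @export
capillary_geometry <- function(inner_diameter = 1.0, sensor_window = 2.0,
                               dead_length = 1.5) {
  if (inner_diameter <= 0 || sensor_window <= 0 || dead_length <= 0)
    stop("all geometry dimensions must be strictly positive")
  structure(list(inner_diameter = inner_diameter,
                 sensor_window = sensor_window,
                 dead_length = dead_length,
                 dead_length_mm = dead_length * 10),
            class = "capillary_geometry")
}

#' @rdname capillary_geometry
#' @param geometry A `capillary_geometry` object.
#' @export
capillary_area <- function(geometry) {
  pi * (geometry$inner_diameter / 2)^2
}

#' Empirical head-flow calibration
#'
#' The gravity-fed flow rate is an empirical function of the water column
#' height (head) above the outlet. The default two-point calibration is the
#' device's measured 0.48 ml/s at 24 cm and 0.77 ml/s at 31 cm; users may
#' supply more points.
#'
#' @param head Numeric vector of heads in cm, strictly increasing.
#' @param flow Numeric vector of flow rates in ml/s, non-negative and
#'   non-decreasing, same length as `head`.
#' @return An object of class `flow_calibration`.
#' @export
flow_calibration <- function(head = c(24, 31), flow = c(0.48, 0.77)) {
  if (length(head) < 2 || length(flow) != length(head))
    stop("calibration requires at least two (head, flow) points")
  if (any(diff(head) <= 0)) stop("calibration heads must be strictly increasing")
  if (any(flow < 0) || any(diff(flow) < 0))
    stop("calibration flows must be non-negative and non-decreasing")
  structure(list(head = as.numeric(head), flow = as.numeric(flow)),
            class = "flow_calibration")
}

#' Gravity flow rate at a given head
#'
#' Piecewise-linear interpolation through the calibration points, with linear
#' extrapolation beyond the endpoints clamped at zero flow.
#'
#' @param head Water column height above the outlet, cm (vectorised).
#' @param calibration A [flow_calibration()] object.
#' @return Flow rate in ml/s.
#' @examples
#' flow_rate(31, flow_calibration())  # 0.77
#' flow_rate(24, flow_calibration())  # 0.48
#' @export
flow_rate <- function(head, calibration = flow_calibration()) {
  stopifnot(inherits(calibration, "flow_calibration"))
  if (any(head < 0)) stop("head must be non-negative")
  h <- calibration$head
  q <- calibration$flow
  k <- length(h)
  out <- stats::approx(h, q, xout = head, rule = 2)$y
  lo <- head < h[1]
  hi <- head > h[k]
  if (any(lo)) {
    s <- (q[2] - q[1]) / (h[2] - h[1])
    out[lo] <- q[1] + s * (head[lo] - h[1])
  }
  if (any(hi)) {
    s <- (q[k] - q[k - 1]) / (h[k] - h[k - 1])
    out[hi] <- q[k] + s * (head[hi] - h[k])
  }
  pmax(out, 0)
}

#' Head at which extrapolated flow reaches zero
#'
#' @inheritParams flow_rate
#' @return Head in cm below which the (clamped) calibrated flow is zero.
#' @export
zero_flow_head <- function(calibration = flow_calibration()) {
  h <- calibration$head
  q <- calibration$flow
  s <- (q[2] - q[1]) / (h[2] - h[1])
  if (s <= 0) return(0)
  max(0, h[1] - q[1] / s)
}

#' Mean stream velocity in the capillary
#'
#' Plug-flow velocity `Q / A`. Hydrodynamic focusing aligns larvae with the
#' faster central flow in a narrow tube; the mean velocity reproduces the
#' transit speed observed on the device, so no parabolic-profile correction is
#' applied.
#'
#' @param flow Volumetric flow in ml/s (vectorised).
#' @param inner_diameter Capillary internal diameter in mm.
#' @return Velocity in mm/s.
#' @examples
#' stream_velocity(0.77, 1.0)  # ~980 mm/s
#' @export
stream_velocity <- function(flow, inner_diameter = 1.0) {
  if (inner_diameter <= 0) stop("inner_diameter must be positive")
  if (any(flow < 0)) stop("flow must be non-negative")
  # ml/s == 1000 mm^3/s; area in mm^2
  1000 * flow / (pi * (inner_diameter / 2)^2)
}

#' Transit time of a particle across the sensor window
#'
#' @param window Sensor window length in mm.
#' @param velocity Stream velocity in mm/s (must be positive).
#' @return Transit time in msec.
#' @examples
#' transit_time(2, 980)  # ~2 msec
#' @export
transit_time <- function(window, velocity) {
  if (any(velocity <= 0)) stop("velocity must be positive: particle never passes")
  if (any(window < 0)) stop("window must be non-negative")
  1000 * window / velocity
}

#' Larva concentration in the feed reservoir
#'
#' Back-calculates reservoir density from the larvae-per-second throughput and
#' the volumetric flow. The raw value is returned; round to the nearest integer
#' for display, per the device's reporting convention.
#'
#' @param lps Larvae per second passing the sensor.
#' @param flow Volumetric flow in ml/s (must be positive).
#' @return Concentration in larvae/ml.
#' @examples
#' round(reservoir_concentration(10, 0.77))  # 13
#' round(reservoir_concentration(30, 0.77))  # 39
#' @export
reservoir_concentration <- function(lps, flow) {
  if (any(flow <= 0)) stop("flow must be positive")
  if (any(lps < 0)) stop("lps must be non-negative")
  lps / flow
}

#' Time-varying hydraulic state of the reservoir
#'
#' @param head Water column height above the outlet, cm.
#' @param volume Water remaining in the reservoir, ml (default 250, the
#'   standard reservoir).
#' @param reservoir_cross_section Reservoir cross-sectional area in cm^2.
#'   The default 100/7 cm^2 is inferred from the calibration protocol: the
#'   100 ml added to reach the "high" level spans the 31 - 24 = 7 cm between
#'   the high and low marks.
#' @param calibration A [flow_calibration()].
#' @param valve_open Logical; flow is zero while the pinch valve is closed.
#' @return An object of class `hydraulic_state`.
#' @export
hydraulic_state <- function(head = 31, volume = 250,
                            reservoir_cross_section = 100 / 7,
                            calibration = flow_calibration(),
                            valve_open = TRUE) {
  if (volume < 0) stop("volume must be non-negative")
  if (head < 0) stop("head must be non-negative")
  structure(list(head = head, volume = volume,
                 reservoir_cross_section = reservoir_cross_section,
                 calibration = calibration,
                 valve_open = valve_open),
            class = "hydraulic_state")
}

#' Instantaneous flow of a hydraulic state
#'
#' @param state A [hydraulic_state()].
#' @return Flow in ml/s; zero when the valve is closed or the head is at or
#'   below the zero-flow head.
#' @export
state_flow <- function(state) {
  stopifnot(inherits(state, "hydraulic_state"))
  if (!state$valve_open || state$volume <= 0) return(0)
  flow_rate(state$head, state$calibration)
}

#' Advance the reservoir by draining for `dt` seconds
#'
#' Explicit small-step update: the volume decreases by the integrated flow, the
#' head falls according to the reservoir cross-section, and the flow is
#' recomputed. The volume never goes negative and the flow clamps to zero at
#' the zero-flow head.
#'
#' @param state A [hydraulic_state()].
#' @param dt Time step in seconds (non-negative).
#' @param max_substep Internal integration substep in seconds.
#' @return The updated `hydraulic_state`.
#' @export
drain_step <- function(state, dt, max_substep = 0.1) {
  stopifnot(inherits(state, "hydraulic_state"))
  if (dt < 0) stop("dt must be non-negative")
  if (dt == 0) return(state)
  n <- max(1L, ceiling(dt / max_substep))
  h_dt <- dt / n
  for (i in seq_len(n)) {
    q <- state_flow(state)
    if (q <= 0) break
    dv <- min(q * h_dt, state$volume)
    state$volume <- state$volume - dv
    state$head <- max(0, state$head - dv / state$reservoir_cross_section)
  }
  state
}

#' @export
print.hydraulic_state <- function(x, ...) {
  cat(sprintf("hydraulic state: head %.2f cm, volume %.1f ml, flow %.3f ml/s (valve %s)\n",
              x$head, x$volume, state_flow(x), if (x$valve_open) "open" else "closed"))
  invisible(x)
}

#' @export
print.capillary_geometry <- function(x, ...) {
  cat(sprintf("capillary: ID %.2f mm, sensor window %.1f mm, dead length %.1f cm\n",
              x$inner_diameter, x$sensor_window, x$dead_length))
  invisible(x)
}
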