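# Offline brute-force counting oracle.
#
# Non-streaming re-derivations of each algorithm's semantics over the whole
# series, written independently of the single-pass implementations (window
# statistics recomputed from scratch with mean()/sd(); run-length encoding for
# the fixed-threshold detectors). Used to cross-check the streaming code on
# every input.

#' Offline brute-force count
#'
#' Recomputes the count a detector should produce from the full trace using a
#' deliberately naive, non-streaming formulation. Must equal the number of
#' events emitted by the corresponding streaming function on every input.
#'
#' @param trace A `sensor_trace` or numeric intensity vector.
#' @param params Parameters of any of the three detectors.
#' @param frozen Optional frozen baseline for the smoothed z-score variant.
#' @return Integer count.
#' @export
offline_oracle_count <- function(trace, params, frozen = NULL) {
  y <- if (inherits(trace, "sensor_trace")) trace$intensity else as.numeric(trace)
  if (length(y) == 0) return(0L)
  switch(class(params)[1],
         szs_params = oracle_szs(y, params, frozen),
         threshold_reset_params = oracle_threshold_reset(y, params),
         refractory_params = oracle_refractory(
           y, params,
           if (inherits(trace, "sensor_trace")) trace$sampling_rate else 10),
         stop("unknown detector parameter class"))
}

oracle_szs <- function(y, p, frozen = NULL) {
  n <- length(y)
  lag <- p$lag
  use_drop <- !is.null(p$decline_amount)
  if (is.null(frozen) && n <= lag) stop("trace must be longer than lag")
  filt <- y
  st <- list(armed = TRUE, count = 0L, flag_run = 0L,
             rearm_peak = -Inf, decline_run = 0L, prev_dev = NA_real_)
  first <- if (is.null(frozen)) lag + 1L else 1L
  for (i in first:n) {
    if (is.null(frozen)) {
      win <- filt[(i - lag):(i - 1L)]
      mu <- mean(win)
      sig <- max(stats::sd(win), p$sigma_floor)
    } else {
      mu <- frozen$mu
      sig <- max(frozen$sigma, p$sigma_floor)
    }
    dev <- mu - y[i]
    fl <- dev > p$z_start * sig
    st$flag_run <- if (fl) st$flag_run + 1L else 0L
    if (!st$armed) {
      if (use_drop) {
        st$rearm_peak <- max(st$rearm_peak, dev)
        if (st$rearm_peak - dev >= p$decline_amount) st$armed <- TRUE
      } else {
        st$decline_run <- if (!is.na(st$prev_dev) && dev < st$prev_dev)
          st$decline_run + 1L else 0L
        if (st$decline_run >= p$n_decline) st$armed <- TRUE
      }
      if (st$armed) st$flag_run <- 0L
    }
    if (st$armed && fl && st$flag_run >= p$n_above) {
      st$count <- st$count + 1L
      st$armed <- FALSE
      st$rearm_peak <- dev
      st$decline_run <- 0L
      st$flag_run <- 0L
    }
    st$prev_dev <- dev
    if (is.null(frozen) && fl)
      filt[i] <- p$influence * y[i] + (1 - p$influence) * filt[i - 1L]
  }
  st$count
}

oracle_threshold_reset <- function(y, p) {
  base <- resolve_baseline(y, p$baseline)
  above <- (base - y) > p$threshold
  r <- rle(above)
  armed <- TRUE
  count <- 0L
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) {
      if (armed && r$lengths[j] >= p$n_above) {
        count <- count + 1L
        armed <- FALSE
      }
    } else if (r$lengths[j] >= p$n_below) {
      armed <- TRUE
    }
  }
  count
}

oracle_refractory <- function(y, p, sampling_rate) {
  base <- resolve_baseline(y, p$baseline)
  above <- (base - y) > p$threshold
  edges <- which(above & !c(FALSE, above[-length(above)]))
  if (length(edges) == 0) return(0L)
  t_ms <- (edges - 1) / sampling_rate
  count <- 0L
  last <- -Inf
  for (t in t_ms) {
    if (t - last >= p$refractory) {
      count <- count + 1L
      last <- t
    }
  }
  count
}
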