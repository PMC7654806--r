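# Constructed traces and randomized trace/parameter generators shared by the
# detection tests.

# Intensity vector with rectangular dips at given start samples.
pulse_vector <- function(n, starts, width = 20, amplitude = 100,
                         baseline = 600, noise_std = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rep(baseline, n) + if (noise_std > 0) stats::rnorm(n, 0, noise_std) else 0
  for (s in starts) {
    idx <- s:min(n, s + width - 1)
    y[idx] <- y[idx] - amplitude
  }
  y
}

# A sensor_trace built from explicit events (exercises synthesize_trace).
event_trace <- function(times, amplitude = 100, duration = NULL,
                        noise_std = 6, seed = 1, velocity = 980,
                        contaminants = NULL, drift = 0) {
  ev <- data.frame(arrival_time = times,
                   amplitude = rep_len(amplitude, length(times)),
                   body_length = rep_len(1, length(times)))
  synthesize_trace(ev,
                   noise = noise_model(noise_std = noise_std, drift_rate = drift),
                   geometry = capillary_geometry(),
                   velocity = velocity,
                   duration = duration,
                   contaminants = contaminants,
                   seed = seed)
}

# Randomized trace + parameters for streaming/oracle equivalence checks.
random_trace_case <- function(seed) {
  set.seed(seed)
  n <- sample(200:400, 1)
  k <- sample(0:6, 1)
  starts <- if (k > 0) sort(sample(60:(n - 10), k)) else integer(0)
  y <- pulse_vector(n, starts,
                    width = sample(5:40, 1),
                    amplitude = stats::runif(1, 20, 150),
                    noise_std = stats::runif(1, 1, 12))
  list(y = y, n = n, seed = seed)
}

random_szs_params <- function(seed) {
  set.seed(seed + 7)
  if (stats::runif(1) < 0.5)
    szs_params(z_start = stats::runif(1, 1.5, 8),
               n_above = sample(1:4, 1),
               decline_amount = stats::runif(1, 10, 80),
               lag = sample(30:80, 1),
               influence = sample(c(0, 0.1, 0.5), 1))
  else
    szs_params(z_start = stats::runif(1, 1.5, 8),
               n_above = sample(1:4, 1),
               n_decline = sample(1:4, 1),
               lag = sample(30:80, 1),
               influence = sample(c(0, 0.25), 1))
}
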