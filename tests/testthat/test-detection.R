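test_that("a flat trace yields no counts under any algorithm", {
  y <- rep(600, 1000)
  p <- szs_params(lag = 50)
  expect_equal(nrow(smoothed_zscore_count(y, p)), 0)
  expect_equal(nrow(threshold_reset_count(y, threshold_reset_params())), 0)
  expect_equal(nrow(refractory_count(y, refractory_params())), 0)
  expect_equal(offline_oracle_count(y, p), 0)
})

test_that("well-separated pulses are counted exactly across z settings", {
  starts <- c(800, 1600, 2400, 3200, 4000)
  y <- pulse_vector(5000, starts, width = 20, amplitude = 100,
                    noise_std = 6, seed = 1)
  for (z in c(2.5, 4, 6)) {
    p <- szs_params(z_start = z)
    ev <- smoothed_zscore_count(y, p)
    expect_equal(nrow(ev), 5)
    expect_equal(nrow(ev), offline_oracle_count(y, p))
  }
  # fixed-threshold detectors agree with their oracles too
  ptr <- threshold_reset_params(threshold = 50)
  expect_equal(nrow(threshold_reset_count(y, ptr)), 5)
  expect_equal(offline_oracle_count(y, ptr), 5)
  prf <- refractory_params(threshold = 50, refractory = 5)
  expect_equal(nrow(refractory_count(y, prf)), 5)
  expect_equal(offline_oracle_count(y, prf), 5)
})

test_that("a z threshold above the signal yields zero counts", {
  y <- pulse_vector(3000, c(1000, 2000), amplitude = 100, noise_std = 6,
                    seed = 2)
  expect_equal(nrow(smoothed_zscore_count(y, szs_params(z_start = 30))), 0)
})

test_that("clustered pulses separated by a re-arm decline count individually", {
  # two larvae in close succession: the combined dip has a partial valley
  # deep enough to satisfy the decline_amount re-arm rule
  y <- rep(600, 800)
  y[300:320] <- 500          # first larva
  y[321:324] <- 570          # brief partial clearing (deviation drops by 70)
  y[325:345] <- 500          # second larva
  p <- szs_params(z_start = 3, decline_amount = 50, lag = 100)
  expect_equal(nrow(smoothed_zscore_count(y, p)), 2)
  expect_equal(offline_oracle_count(y, p), 2)
  # without a sufficient decline the pair merges into one count
  y2 <- rep(600, 800)
  y2[300:345] <- 500
  expect_equal(nrow(smoothed_zscore_count(y2, p)), 1)
})

test_that("the n_decline re-arm variant splits on consecutive declining values", {
  y <- rep(600, 800)
  y[300:320] <- 480                       # first larva
  y[321:324] <- c(500, 520, 540, 560)     # 4 declining deviations
  y[325:345] <- 480                       # second larva
  p3 <- szs_params(z_start = 3, n_decline = 3, lag = 100)
  expect_equal(nrow(smoothed_zscore_count(y, p3)), 2)
  expect_equal(offline_oracle_count(y, p3), 2)
  # requiring a longer decline than the valley provides merges the pair
  p9 <- szs_params(z_start = 3, n_decline = 9, lag = 100)
  expect_equal(nrow(smoothed_zscore_count(y, p9)), 1)
  expect_equal(offline_oracle_count(y, p9), 1)
})

test_that("threshold-reset merges pulses that never return below threshold", {
  y <- rep(600, 400)
  y[100:130] <- 500
  y[133:160] <- 480  # only 2 samples between pulses, n_below = 3 not met
  p <- threshold_reset_params(threshold = 50, n_above = 3, n_below = 3)
  expect_equal(nrow(threshold_reset_count(y, p)), 1)
  expect_equal(offline_oracle_count(y, p), 1)
  y[131:132] <- 600  # widen the gap to satisfy n_below... still only 2 below
  expect_equal(nrow(threshold_reset_count(y, p)), 1)
  y2 <- rep(600, 400)
  y2[100:130] <- 500
  y2[134:160] <- 480  # 3 samples below threshold re-arm the detector
  expect_equal(nrow(threshold_reset_count(y2, p)), 2)
  expect_equal(offline_oracle_count(y2, p), 2)
})

test_that("refractory period suppresses closely spaced counts", {
  # two pulses 3 msec apart (30 samples at 10 samples/msec)
  y <- pulse_vector(600, c(200, 230), width = 10, amplitude = 100)
  close_p <- refractory_params(threshold = 50, refractory = 5)
  expect_equal(nrow(refractory_count(y, close_p)), 1)
  expect_equal(offline_oracle_count(y, close_p), 1)
  far_p <- refractory_params(threshold = 50, refractory = 2)
  expect_equal(nrow(refractory_count(y, far_p)), 2)
  expect_equal(offline_oracle_count(y, far_p), 2)
})

test_that("a single pulse counts once under all algorithms at default settings", {
  y <- pulse_vector(2000, 1000, width = 20, amplitude = 100, noise_std = 6,
                    seed = 3)
  expect_equal(nrow(smoothed_zscore_count(y, szs_params())), 1)
  expect_equal(nrow(threshold_reset_count(y, threshold_reset_params())), 1)
  expect_equal(nrow(refractory_count(y, refractory_params())), 1)
})

test_that("a pulse truncated by end-of-trace still counts once n_above is met", {
  y <- c(rep(600, 500), rep(500, 4))  # 4 flagged samples, pulse never ends
  p <- szs_params(z_start = 3, lag = 200, n_above = 3)
  expect_equal(nrow(smoothed_zscore_count(y, p)), 1)
  expect_equal(offline_oracle_count(y, p), 1)
})

test_that("detection is deterministic bit-for-bit", {
  tr <- simulate_trace(lps = 20, duration = 1.5, seed = 77)
  p <- szs_params()
  expect_identical(smoothed_zscore_count(tr, p), smoothed_zscore_count(tr, p))
  expect_identical(refractory_count(tr, refractory_params()),
                   refractory_count(tr, refractory_params()))
})

test_that("streaming and offline counts agree on randomized traces", {
  for (s in 1:60) {
    case <- random_trace_case(s)
    p <- random_szs_params(s)
    expect_equal(nrow(smoothed_zscore_count(case$y, p)),
                 offline_oracle_count(case$y, p),
                 info = sprintf("szs seed %d", s))
  }
  for (s in 1:25) {
    case <- random_trace_case(1000 + s)
    set.seed(s)
    ptr <- threshold_reset_params(threshold = runif(1, 20, 90),
                                  n_above = sample(1:4, 1),
                                  n_below = sample(1:5, 1))
    prf <- refractory_params(threshold = runif(1, 20, 90),
                             refractory = runif(1, 0, 8))
    expect_equal(nrow(threshold_reset_count(case$y, ptr)),
                 offline_oracle_count(case$y, ptr))
    expect_equal(nrow(refractory_count(case$y, prf)),
                 offline_oracle_count(case$y, prf))
  }
})

test_that("with a frozen baseline the count is non-increasing in z_start", {
  for (s in 1:20) {
    case <- random_trace_case(2000 + s)
    counts <- vapply(c(1.5, 2.5, 3.5, 5, 7, 9), function(z) {
      nrow(smoothed_zscore_count(case$y,
                                 szs_params(z_start = z, lag = 50),
                                 frozen = list(mu = 600, sigma = 6)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = sprintf("seed %d", s))
  }
})

test_that("count events carry increasing indices and flagged samples", {
  tr <- simulate_trace(lps = 20, duration = 2, seed = 12)
  ev <- smoothed_zscore_count(tr, szs_params())
  expect_true(all(diff(ev$sample_index) > 0))
  fl <- attr(ev, "flagged")
  expect_true(all(fl[ev$sample_index]))  # counts land on flagged samples
})

test_that("parameter validation enforces the re-arm exclusivity rule", {
  expect_error(szs_params(decline_amount = 50, n_decline = 3), "exactly one")
  expect_error(szs_params(z_start = 0), "positive")
  expect_error(szs_params(lag = 1), "lag")
  expect_error(smoothed_zscore_count(rep(600, 10), szs_params(lag = 50)),
               "longer than lag")
})
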