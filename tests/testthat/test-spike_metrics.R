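test_that("spike detection recovers injected events and respects tail bounds", {
  set.seed(14)
  inj <- sort(runif(20, 0.2, 9.8))
  inj <- inj[c(TRUE, diff(inj) > 0.01)]      # keep well-separated injections
  tr <- make_spike_trace(inj, 10, amplitude_sd_units = 8, noise_sd = 1,
                         rng_seed = 14)
  got4 <- detect_spikes(tr, 1e4, threshold_sd = 4)
  # every injected spike is found within one sample of its peak time
  for (t in inj) expect_true(any(abs(got4 - t) <= 2e-4 + 1.1e-3))
  # at a threshold where the Gaussian tail makes noise crossings negligible
  # (P(|z| > 5.5) * 1e5 ~ 4e-3) the detections are exactly the injections
  got55 <- detect_spikes(tr, 1e4, threshold_sd = 5.5)
  expect_length(got55, length(inj))
  # pure noise at 8 SD over 10 s: zero detections (tail bound ~1e-10)
  noise <- make_spike_trace(numeric(0), 10, rng_seed = 2)
  expect_length(detect_spikes(noise, 1e4, threshold_sd = 8), 0L)
  # flat trace: empty with a warning
  expect_warning(out <- detect_spikes(rep(0, 1000), 1e4), "flat trace")
  expect_length(out, 0L)
})

test_that("binned counts follow the half-open convention and conserve spikes", {
  b <- bin_rates(c(1, 16, 31), 15)
  expect_equal(b$count, c(1, 1, 1))
  # a spike exactly on the edge falls into the later bin
  b2 <- bin_rates(c(1, 15), 15, t_max = 30)
  expect_equal(b2$count, c(1, 1))
  # conservation across random trains
  set.seed(6)
  for (i in 1:10) {
    s <- sort(runif(rpois(1, 80), 0, 300))
    expect_equal(sum(bin_rates(s, 15, t_max = 300)$count), length(s))
  }
  # homogeneous Poisson at 1.5 Hz: mean count per 15-s bin near 22.5
  means <- vapply(1:30, function(seed) {
    sim <- make_spike_experiment(depth = 0, baseline_s = 150, agonist_s = 150,
                                 rng_seed = seed)
    mean(bin_rates(sim$experiment$spike_times, 15, t_max = 300)$count)
  }, numeric(1))
  expect_equal(mean(means), 22.5, tolerance = 0.05)
  expect_error(bin_rates(1:3, 0), "bin_seconds")
})

test_that("percent inhibition implements the baseline/early-window ratio", {
  # baseline 1.5 Hz then silence: 100%
  ex <- spike_experiment(regular_spikes(1.5, 0, 120), 120, 360)
  expect_equal(as.numeric(percent_inhibition(ex)), 100)
  # baseline 2 Hz, agonist 1 Hz: 50%
  ex2 <- spike_experiment(c(regular_spikes(2, 0, 120),
                            regular_spikes(1, 120, 360)), 120, 360)
  expect_equal(as.numeric(percent_inhibition(ex2)), 50)
  # rebound above baseline clamps to 0 and is flagged
  ex3 <- spike_experiment(c(regular_spikes(1, 0, 120),
                            regular_spikes(3, 120, 360)), 120, 360)
  pi3 <- percent_inhibition(ex3)
  expect_equal(as.numeric(pi3), 0)
  expect_true(attr(pi3, "rebound"))
  # silent baseline excludes the cell
  ex4 <- spike_experiment(regular_spikes(1, 130, 240), 120, 360)
  expect_error(percent_inhibition(ex4), "zero baseline")
  # short baseline violates the steady-firing precondition
  ex5 <- spike_experiment(regular_spikes(2, 0, 30), 30, 300)
  expect_error(percent_inhibition(ex5), "baseline epoch")
})

test_that("percent inhibition is invariant under time rescaling", {
  sp <- c(regular_spikes(2, 0, 120), regular_spikes(0.5, 120, 360))
  ex <- spike_experiment(sp, 120, 360)
  for (f in c(2, 3)) {
    exf <- spike_experiment(sp * f, 120 * f, 360 * f)
    expect_equal(as.numeric(percent_inhibition(exf, window_s = c(60, 120) * f)),
                 as.numeric(percent_inhibition(ex)))
  }
})

test_that("desensitization is the early-minus-late inhibition difference", {
  # full suppression held through 5 min: 100% inhibition, 0% desensitization
  ex <- spike_experiment(regular_spikes(1.5, 0, 120), 120, 480)
  expect_equal(as.numeric(percent_desensitization(ex)), 0)
  expect_equal(attr(percent_desensitization(ex), "inhibition_early"), 100)
  # early 100%, recovered to 80% of baseline at 5 min: 80 points
  sp <- c(regular_spikes(2, 0, 120), regular_spikes(1.6, 320, 480))
  ex2 <- spike_experiment(sp, 120, 480)
  d2 <- percent_desensitization(ex2)
  expect_equal(as.numeric(d2), 80)
  expect_equal(attr(d2, "inhibition_late"), 20)
  # fully recovered train: desensitization equals the early inhibition
  sp3 <- c(regular_spikes(2, 0, 120), regular_spikes(2, 300, 480))
  ex3 <- spike_experiment(sp3, 120, 480)
  d3 <- percent_desensitization(ex3)
  expect_equal(as.numeric(d3), attr(d3, "inhibition_early"))
  # normalized variant rescales by the early inhibition
  sp4 <- c(regular_spikes(2, 0, 120), regular_spikes(1, 120, 240),
           regular_spikes(1.5, 380, 480))
  ex4 <- spike_experiment(sp4, 120, 480)
  raw <- percent_desensitization(ex4)
  norm <- percent_desensitization(ex4, normalized = TRUE)
  expect_equal(as.numeric(norm),
               100 * as.numeric(raw) / attr(raw, "inhibition_early"))
  # agonist epoch shorter than 5 min is an error
  exs <- spike_experiment(regular_spikes(1.5, 0, 120), 120, 300)
  expect_error(percent_desensitization(exs), "shorter than 5 min")
})

test_that("the metrics recover programmed phantom values", {
  pr <- solve_firing_params(80, 40)
  vals <- vapply(1:40, function(seed) {
    sim <- make_spike_experiment(depth = pr$depth, recovery = pr$recovery,
                                 rng_seed = seed)
    c(as.numeric(percent_inhibition(sim$experiment)),
      as.numeric(percent_desensitization(sim$experiment)))
  }, numeric(2))
  expect_equal(mean(vals[1, ]), 80, tolerance = 0.05)
  expect_equal(mean(vals[2, ]), 40, tolerance = 0.13)
})
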