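egm_tl <- function() protocol_timeline(list(baseline_pre = c(0, 12),
                                            lad_pre = c(12, 24)))

test_that("noise-free beats place the derivative extrema at true AT/RT", {
  cfg <- synth_egm_config(n_electrodes = 1, at_ms = 40, rt_ms = 340,
                          noise_sd_mv = 0, seed = 1)
  sim <- gen_electrograms(cfg, egm_tl())
  beat <- sim$egm$samples[1, 1:600]
  n <- length(beat) # central-difference slope, aligned with the sample grid
  d <- (beat[3:n] - beat[1:(n - 2)]) / 2 * 1000
  expect_equal(which.min(d) / 1000, 0.040, tolerance = 1.1e-3)
  twin <- 200:590
  expect_equal(twin[which.max(d[twin])] / 1000, 0.340, tolerance = 1.1e-3)
})

test_that("generated electrograms are deterministic under a seed", {
  cfg <- synth_egm_config(n_electrodes = 4, seed = 42)
  a <- gen_electrograms(cfg, egm_tl())
  b <- gen_electrograms(cfg, egm_tl())
  expect_identical(a$egm$samples, b$egm$samples)
  expect_identical(a$truth, b$truth)
})

test_that("ischemic electrodes carry the configured ST shift", {
  cfg <- synth_egm_config(n_electrodes = 4, ischemic_mask = 1:2,
                          st_shift_mv = 0.2, noise_sd_mv = 0.01, seed = 7)
  sim <- gen_electrograms(cfg, egm_tl())
  # segment-mean oracle: mean over the held ST plateau, ischemic beats only
  st_of <- function(e, beat) {
    i0 <- (beat - 1) * 600
    seg <- sim$egm$samples[e, (i0 + 96):(i0 + 160)]
    mean(seg)
  }
  isch_beats <- 21:40 # onsets in [12, 24)
  d <- mean(sapply(isch_beats, function(b) st_of(1, b))) -
       mean(sapply(isch_beats, function(b) st_of(3, b)))
  expect_equal(d, 0.2, tolerance = 0.02)
  # and the truth table says so
  tr <- sim$truth
  expect_true(all(tr$st_mv[tr$electrode_id == 1 & tr$ischemic] == 0.2))
  expect_true(all(tr$st_mv[tr$electrode_id == 3] == 0))
})

test_that("config validation rejects impossible templates", {
  expect_error(synth_egm_config(fs = 250), ">= 500")
  expect_error(synth_egm_config(rr_interval_s = 0.3), "too short")
  expect_error(synth_egm_config(at_ms = 400, rt_ms = 350), "precede")
})

test_that("homogeneous population recovers its configured rate", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(n_neurons = 5, baseline_rate_hz = 5, seed = 3)
  pop <- gen_spike_population(cfg, tl)
  dur <- max(tl$epochs$end)
  for (id in unique(pop$spikes$neuron_id)) {
    n <- sum(pop$spikes$neuron_id == id)
    rate <- n / dur
    se <- sqrt(5 * dur) / dur
    expect_lt(abs(rate - 5), 3 * se)
  }
})

test_that("epoch gains scale the rate where configured", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(n_neurons = 1, baseline_rate_hz = 2,
                            ischemia_gain = 3, post_scs_gain = 1.2, seed = 9)
  pop <- gen_spike_population(cfg, tl)
  t <- pop$spikes$t
  r_lad <- count_in_epoch(t, epoch_window(tl, "lad_pre")) / 180
  r_post <- count_in_epoch(t, epoch_window(tl, "lad_post")) / 180
  expect_lt(abs(r_lad - 6), 3 * sqrt(6 * 180) / 180)
  expect_lt(abs(r_post - 2.4), 3 * sqrt(2.4 * 180) / 180)
})

test_that("perfectly following antidromic unit fires at pulse + latency", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(
    n_neurons = 1, baseline_rate_hz = 0,
    antidromic = data.frame(neuron = 1, latency_ms = 20,
                            latency_jitter_ms = 0, follow_prob = 1),
    seed = 5)
  pop <- gen_spike_population(cfg, tl)
  expect_equal(pop$spikes$t, tl$stim_pulses$t2 + 0.020, tolerance = 1e-12)
  expect_true(pop$truth$is_iml[1])
})

test_that("spike generation is deterministic and respects refractoriness", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(n_neurons = 3, baseline_rate_hz = 10, seed = 11)
  a <- gen_spike_population(cfg, tl)
  b <- gen_spike_population(cfg, tl)
  expect_identical(a$spikes, b$spikes)
  gaps <- unlist(tapply(a$spikes$t, a$spikes$neuron_id, diff))
  expect_true(all(gaps >= 0.001))
})

test_that("injected common drive yields the expected coincidences", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(
    n_neurons = 2, baseline_rate_hz = 1,
    sync_pairs = data.frame(a = 1, b = 2, injection_rate_hz = 1,
                            max_lag_ms = 10),
    duration_s = 300, seed = 13)
  pop <- gen_spike_population(cfg, tl)
  t1 <- pop$spikes$t[pop$spikes$neuron_id == pop$truth$neuron_id[1]]
  t2 <- pop$spikes$t[pop$spikes$neuron_id == pop$truth$neuron_id[2]]
  c_obs <- count_coincidences(t1, t2, window_ms = 10)
  expect_gte(c_obs, 1 * 300 * 0.8) # >= injection_rate * duration * (1 - tol)
  expect_equal(pop$sync_truth$a_id, pop$truth$neuron_id[1])
})

test_that("invalid spike configs are rejected", {
  expect_error(synth_spike_config(baseline_rate_hz = -1), ">= 0")
  expect_error(synth_spike_config(
    antidromic = data.frame(neuron = 1, latency_ms = 20,
                            latency_jitter_ms = 0, follow_prob = 1.5)),
    "follow_prob")
})
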