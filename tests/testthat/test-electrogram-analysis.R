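egm_tl2 <- function() protocol_timeline(list(baseline_pre = c(0, 12),
                                             lad_pre = c(12, 24)))

test_that("detectors recover noise-free truth within one sample", {
  cfg <- synth_egm_config(n_electrodes = 6, noise_sd_mv = 0, seed = 21)
  sim <- gen_electrograms(cfg, egm_tl2())
  beats <- measure_beats(sim$egm)
  expect_true(all(beats$valid))
  expect_lte(max(abs(beats$at_s - sim$truth$at_s)), 1 / sim$egm$fs + 1e-9)
  expect_lte(max(abs(beats$rt_s - sim$truth$rt_s)), 1 / sim$egm$fs + 1e-9)
})

test_that("inverted T waves still yield the true repolarization time", {
  cfg <- synth_egm_config(n_electrodes = 2, t_polarity = -1,
                          noise_sd_mv = 0, seed = 22)
  sim <- gen_electrograms(cfg, egm_tl2())
  beats <- measure_beats(sim$egm)
  expect_lte(max(abs(beats$rt_s - sim$truth$rt_s)), 1 / sim$egm$fs + 1e-9)
})

test_that("activation detector tie-breaks early and gates on amplitude", {
  # constant-slope ramp: derivative ties everywhere -> earliest sample
  ramp <- seq(0, -1, length.out = 200)
  expect_equal(detect_activation_time(ramp, 1000), 0)
  # flat, sub-noise-floor segment is flagged undefined
  expect_true(is.na(detect_activation_time(rep(0, 200), 1000)))
  expect_true(is.na(detect_repolarization_time(rep(0, 200), 1000,
                                               t_window = c(0.05, 0.15))))
})

test_that("repolarization detector validates its window", {
  x <- sin(seq(0, 2 * pi, length.out = 500))
  expect_error(detect_repolarization_time(x, 1000, t_window = c(0.2, 0.2)),
               "non-empty")
  expect_error(detect_repolarization_time(x, 1000, t_window = c(5, 6)),
               "outside")
})

test_that("ARI maps average valid beats and drop dead electrodes", {
  beats <- tibble::tibble(
    electrode_id = c(1, 1, 2, 2),
    beat_index = c(1, 2, 1, 2), onset_s = c(0, 1, 0, 1),
    at_s = c(0.04, 0.04, 0.04, 0.04),
    rt_s = c(0.34, 0.35, NA, NA),
    ari_ms = c(300, 310, NA, NA), st_mv = 0,
    valid = c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_warning(map <- compute_ari(beats), "excluded")
  expect_equal(nrow(map), 1)
  expect_equal(map$ari_ms, 305)
})

test_that("ST measurement honours sign and window contracts", {
  tl <- egm_tl2()
  cfg <- synth_egm_config(n_electrodes = 1, ischemic_mask = 1,
                          st_shift_mv = -0.1, noise_sd_mv = 0, seed = 23)
  sim <- gen_electrograms(cfg, tl)
  beats <- measure_beats(sim$egm)
  isch <- beats[beats$onset_s >= 12, ]
  expect_equal(mean(isch$st_mv), -0.1, tolerance = 0.01) # depression, signed
  base <- beats[beats$onset_s < 12, ]
  expect_lt(abs(mean(base$st_mv)), 0.01) # no shift at baseline
  expect_error(measure_st_elevation(sim$egm$samples[1, 1:600], 1000,
                                    st_window = c(0.01, 0.1),
                                    iso_window = c(0.05, 0.08)),
               "overlap")
})

test_that("ischemic zone thresholding follows the ST rule", {
  st <- tibble::tibble(electrode_id = 1:3, st_mv = c(0.3, 0.0, 0.15))
  expect_equal(define_ischemic_zone(st, 0.1), c(1L, 3L))
  expect_warning(m <- define_ischemic_zone(st, 0.5), "empty")
  expect_length(m, 0)
  # threshold 0 keeps strictly positive ST only
  expect_equal(define_ischemic_zone(st, 0), c(1L, 3L))
})

test_that("ARI shortening is a masked mean difference", {
  base <- tibble::tibble(electrode_id = 1:3, ari_ms = c(310, 310, 310))
  isch <- tibble::tibble(electrode_id = 1:3, ari_ms = c(210, 210, 300))
  expect_equal(ari_shortening(base, isch, 1:2), -100)
  expect_equal(ari_shortening(base, base, 1:3), 0)
  expect_error(ari_shortening(base, isch, integer(0)), "empty")
})

test_that("configured ARI shortening is recovered end to end", {
  cfg <- synth_egm_config(n_electrodes = 8, ischemic_mask = 1:3,
                          ari_shortening_ms = 100, noise_sd_mv = 0, seed = 24)
  sim <- gen_electrograms(cfg, egm_tl2())
  beats <- measure_beats(sim$egm)
  mb <- compute_ari(beats, c(0, 12))
  ml <- compute_ari(beats, c(12, 24))
  st <- beats[beats$onset_s >= 12, ] |>
    dplyr::group_by(electrode_id) |>
    dplyr::summarise(st_mv = mean(st_mv))
  mask <- define_ischemic_zone(st)
  expect_setequal(mask, 1:3)
  expect_equal(ari_shortening(mb, ml, mask), -100, tolerance = 2)
})

test_that("dispersion of repolarization is a sample variance", {
  mk <- function(rts) tibble::tibble(
    electrode_id = seq_along(rts), beat_index = 1, onset_s = 0,
    at_s = 0.04, rt_s = rts / 1000, ari_ms = rts - 40, st_mv = 0, valid = TRUE)
  expect_equal(compute_dor(mk(c(250, 250, 250)))$dor_ms2, 0)
  expect_equal(compute_dor(mk(c(200, 210, 220, 230)))$dor_ms2, 500 / 3,
               tolerance = 1e-9)
  expect_error(compute_dor(mk(300)), "2 electrodes")
})

test_that("DOR is shift-invariant and scales quadratically", {
  rts <- c(220, 260, 235, 280)
  mk <- function(rts) tibble::tibble(
    electrode_id = seq_along(rts), beat_index = 1, onset_s = 0,
    at_s = 0.04, rt_s = rts / 1000, ari_ms = rts - 40, st_mv = 0, valid = TRUE)
  d0 <- compute_dor(mk(rts))$dor_ms2
  expect_equal(compute_dor(mk(rts + 50))$dor_ms2, d0)
  expect_equal(compute_dor(mk(rts * 2))$dor_ms2, 4 * d0)
  # the ARI metric variant uses the ARI column
  expect_equal(compute_dor(mk(rts), metric = "ari")$dor_ms2, d0)
})
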