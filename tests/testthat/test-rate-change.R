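test_that("Skellam pmf matches the Poisson convolution oracle", {
  # oracle: P(K = k) = sum_n Pois(n + k; mu1) Pois(n; mu2)
  conv <- function(k, mu1, mu2) {
    n <- 0:80
    sum(dpois(n + k, mu1) * dpois(n, mu2))
  }
  expect_equal(dskellam(0, 1, 1), conv(0, 1, 1), tolerance = 1e-10)
  for (k in c(-3, 0, 2, 7)) for (mu in list(c(1, 1), c(4, 2.5), c(12, 20)))
    expect_equal(dskellam(k, mu[1], mu[2]), conv(k, mu[1], mu[2]),
                 tolerance = 1e-10)
})

test_that("Skellam pmf is symmetric, normalized and handles zero means", {
  k <- -30:30
  expect_equal(dskellam(k, 3, 3), dskellam(-k, 3, 3))
  for (mu in c(0.5, 2, 10, 25)) {
    s <- sum(dskellam(-200:200, mu, mu))
    expect_lt(abs(s - 1), 1e-9)
  }
  expect_equal(dskellam(0, 0, 0), 1)
  expect_equal(dskellam(2, 0, 0), 0)
  expect_equal(dskellam(3, 2, 0), dpois(3, 2)) # degenerate Poisson
  expect_error(dskellam(0, -1, 1), ">= 0")
})

test_that("Skellam distribution function accumulates the pmf", {
  for (k in c(-5, 0, 4)) {
    expect_equal(pskellam(k, 3, 5), sum(dskellam(-200:k, 3, 5)),
                 tolerance = 1e-10)
    expect_equal(pskellam(k, 3, 5, lower.tail = FALSE),
                 sum(dskellam(k:200, 3, 5)), tolerance = 1e-10)
  }
})

test_that("rate-change test flags clear changes and not equal rates", {
  up <- skellam_test(10, 60, 60, 60)
  expect_lt(up$p_two_sided, 0.001)
  expect_identical(up$direction, "increase")

  eq <- skellam_test(120, 60, 360, 180) # both 2 Hz
  expect_gt(eq$p_two_sided, 0.9)
  expect_identical(eq$direction, "none")
  expect_equal(eq$delta_hz, 0)

  zero <- skellam_test(0, 60, 0, 180)
  expect_equal(zero$p_two_sided, 1)
  expect_identical(zero$direction, "none")
})

test_that("all test variants agree on strong effects", {
  for (m in c("exact", "plugin", "scaled")) {
    r <- skellam_test(10, 60, 60, 60, method = m)
    expect_lt(r$p_two_sided, 1e-3)
    expect_identical(r$direction, "increase")
  }
})

test_that("swapping windows flips direction and preserves p", {
  a <- skellam_test(20, 60, 120, 180)
  b <- skellam_test(120, 180, 20, 60)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
  expect_identical(a$direction, "increase")
  expect_identical(b$direction, "decrease")
  expect_equal(a$delta_hz, -b$delta_hz)
})

test_that("tidy and glance methods expose the key fields", {
  r <- skellam_test(10, 60, 60, 60)
  td <- generics::tidy(r)
  expect_equal(td$delta_hz, 5 / 6)
  expect_named(generics::glance(r), c("p_value", "direction", "alpha", "method"))
})

test_that("ischemia-sensitivity screen recovers generator truth", {
  tl <- default_study_timeline()
  cfg <- synth_spike_config(n_neurons = 12, baseline_rate_hz = 2,
                            ischemia_gain = c(rep(3, 4), rep(1, 8)), seed = 19)
  pop <- gen_spike_population(cfg, tl)
  res <- classify_ischemia_sensitive(pop$spikes, tl)
  hit <- res$neuron_id[res$is_sensitive]
  expect_true(all(pop$truth$neuron_id[1:4] %in% hit))
  expect_lte(sum(!hit %in% pop$truth$neuron_id[1:4]), 1)
})

test_that("the screen's false-positive rate sits near alpha/2", {
  set.seed(23)
  reps <- 400
  cr <- rpois(reps, 2 * 60)
  ct <- rpois(reps, 2 * 180)
  res <- mapply(function(a, b) {
    s <- skellam_test(a, 60, b, 180)
    s$direction == "increase"
  }, cr, ct)
  rate <- mean(res)
  se <- sqrt(0.025 * 0.975 / reps)
  expect_lt(rate, 0.025 + 3 * se)
})

test_that("response deltas subtract the matched baseline", {
  tl <- default_study_timeline()
  sp <- tibble::tibble(neuron_id = "a", electrode_id = 1L,
                       t = c(seq(480, 539.75, by = 0.5), # 2 Hz baseline tail
                             seq(540, 719.8, by = 0.2))) # 5 Hz during LAD
  d <- response_delta(sp, tl, "lad_pre", "baseline_pre")
  expect_equal(d$delta_hz, 3, tolerance = 0.05)
  # identical epochs give exactly zero
  d0 <- response_delta(sp, tl, "lad_pre", "lad_pre", baseline_s = NULL)
  expect_equal(d0$delta_hz, 0)
  # a neuron silent in both windows scores zero
  sp2 <- tibble::tibble(neuron_id = "b", electrode_id = 1L, t = 2000)
  expect_equal(response_delta(sp2, tl, "lad_pre")$delta_hz, 0)
})
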