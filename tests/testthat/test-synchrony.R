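test_that("coincidence counting follows greedy one-to-one matching", {
  expect_equal(count_coincidences(c(0, 0.1, 0.2), c(0.5), 40), 0)
  expect_equal(count_coincidences(c(0, 0.03), c(0.035), 40), 1)
  t <- sort(runif(50, 0, 10))
  expect_equal(count_coincidences(t, t, 40), 50) # identical trains self-match
})

test_that("compiled matcher agrees with the reference matcher", {
  set.seed(51)
  for (rep in 1:20) {
    a <- sort(runif(rpois(1, 60), 0, 20))
    b <- sort(runif(rpois(1, 60), 0, 20))
    w <- sample(c(0.005, 0.04, 0.2), 1)
    expect_equal(count_coincidences(a, b, w * 1000),
                 count_coincidences_ref(a, b, w))
  }
})

test_that("jitter null is seeded, sane and warns on short epochs", {
  set.seed(52)
  a <- sort(runif(300, 0, 100))
  b <- sort(runif(300, 0, 100))
  n1 <- jitter_null(a, b, n_surrogates = 100, seed = 9, epoch = c(0, 100))
  n2 <- jitter_null(a, b, n_surrogates = 100, seed = 9, epoch = c(0, 100))
  expect_identical(n1$counts, n2$counts)
  expect_gt(n1$null_mean, 0)
  expect_error(jitter_null(a, b, n_surrogates = 10), "100")
  expect_warning(jitter_null(a[a < 0.3], b[b < 0.3], n_surrogates = 100,
                             epoch = c(0, 0.3)), "jitter")
  # empty target: chance level is zero
  nn <- jitter_null(a, numeric(0), n_surrogates = 100, seed = 1,
                    epoch = c(0, 100))
  expect_equal(nn$null_mean, 0)
})

test_that("synchrony index conventions hold at the edges", {
  # both trains firing but never within the window, null also zero
  r <- synchrony_index(1, 500, window_ms = 40, n_surrogates = 100,
                       seed = 3, epoch = c(0, 1000))
  expect_equal(r$c_obs, 0)
  expect_equal(r$si, 0) # 0/0 convention
  # empty train in epoch: undefined, flagged
  r2 <- synchrony_index(numeric(0), c(1, 2), n_surrogates = 100, seed = 3,
                        epoch = c(0, 10))
  expect_false(r2$defined)
  expect_true(is.na(r2$si))
})

test_that("injected common drive is detected, independence is not", {
  tl <- default_study_timeline()
  sig <- 0; indep_p <- numeric(6)
  for (s in 1:6) {
    pop <- gen_spike_population(synth_spike_config(
      n_neurons = 3, baseline_rate_hz = 5,
      sync_pairs = data.frame(a = 1, b = 2, injection_rate_hz = 1,
                              max_lag_ms = 10),
      duration_s = 300, seed = 60 + s), tl)
    tr <- split(pop$spikes$t, pop$spikes$neuron_id)
    r <- synchrony_index(tr[[1]], tr[[2]], n_surrogates = 200,
                         seed = s, epoch = c(0, 300))
    sig <- sig + r$significant
    expect_gt(r$si, 0)
    ri <- synchrony_index(tr[[1]], tr[[3]], n_surrogates = 200,
                          seed = s, epoch = c(0, 300))
    indep_p[s] <- ri$p_value
  }
  expect_equal(sig, 6) # strong common drive: every seed significant
  expect_gt(mean(indep_p), 0.2) # independent pair p-values are not small
})

test_that("doubling independent rates leaves the index near zero", {
  set.seed(55)
  si <- sapply(c(5, 10), function(rate) {
    a <- sort(runif(rate * 300, 0, 300))
    b <- sort(runif(rate * 300, 0, 300))
    synchrony_index(a, b, n_surrogates = 150, seed = rate,
                    epoch = c(0, 300))$si
  })
  expect_true(all(abs(si) < 0.06))
})

test_that("pairwise synchrony enumerates DH-DH and DH-IML pairs", {
  tl <- default_study_timeline()
  pop <- gen_spike_population(synth_spike_config(
    n_neurons = 4, baseline_rate_hz = 3, seed = 57), tl)
  regions <- tibble::tibble(neuron_id = pop$truth$neuron_id,
                            region = c("DH", "DH", "DH", "IML"))
  res <- pairwise_synchrony(pop$spikes, regions, tl,
                            epochs = "lad_pre", n_surrogates = 100, seed = 5)
  expect_equal(sum(res$category == "DH-DH"), 3)
  expect_equal(sum(res$category == "DH-IML"), 3)
  smry <- synchrony_summary(res)
  expect_setequal(smry$category, c("DH-DH", "DH-IML"))
  expect_true(all(smry$n_pairs == 3))
  # reproducible under the same seed
  res2 <- pairwise_synchrony(pop$spikes, regions, tl,
                             epochs = "lad_pre", n_surrogates = 100, seed = 5)
  expect_identical(res$p_value, res2$p_value)
})
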