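test_that("spike tables parse, sort and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("neuron_id,electrode_id,t_seconds",
               "a,1,0.300000", "a,1,0.100000", "a,1,0.200000"), path)
  sp <- read_spike_table(path)
  expect_equal(nrow(sp), 3)
  expect_equal(sp$t, c(0.1, 0.2, 0.3)) # shuffled input comes back sorted
  expect_identical(unique(sp$neuron_id), "a")

  out <- withr::local_tempfile(fileext = ".csv")
  write_spike_table(sp, out)
  expect_equal(read_spike_table(out), sp, tolerance = 1e-9)
})

test_that("spike table reader reports format problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("neuron_id,t_seconds", "a,0.1"), path)
  expect_error(read_spike_table(path), "electrode_id")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("neuron_id,electrode_id,t_seconds",
               "a,1,0.1", "a,1,0.1", "b,2,-0.5"), path2)
  expect_warning(expect_warning(sp <- read_spike_table(path2), "malformed"),
                 "duplicate")
  expect_equal(nrow(sp), 1)
})

test_that("reader output does not depend on row order", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  rows <- c("a,1,0.5", "b,2,0.1", "a,1,0.2", "b,2,0.9")
  writeLines(c("neuron_id,electrode_id,t_seconds", rows), p1)
  writeLines(c("neuron_id,electrode_id,t_seconds", rev(rows)), p2)
  expect_equal(read_spike_table(p1), read_spike_table(p2))
})

test_that("adjacency maps round-trip and grids are symmetric", {
  adj <- grid_adjacency(3, 3)
  expect_length(adj, 9)
  expect_setequal(adj[["5"]], c(2, 4, 6, 8)) # centre of a 3x3 grid
  for (e in names(adj)) for (nb in adj[[e]])
    expect_true(as.integer(e) %in% adj[[as.character(nb)]])
  path <- withr::local_tempfile(fileext = ".json")
  write_adjacency(adj, path)
  expect_equal(read_adjacency(path), adj)
})

test_that("electrogram CSV representation round-trips", {
  m <- matrix(sin(seq(0, 6, length.out = 200)), nrow = 2)
  egm <- egm_set(m, fs = 1000, beat_marks = c(0, 0.05))
  expect_equal(ncol(egm$samples) / egm$fs, 0.1) # 2 x 100, 0.1 s
  path <- withr::local_tempfile(fileext = ".csv")
  write_electrograms(egm, path)
  back <- read_electrograms(path)
  expect_equal(back$fs, 1000)
  expect_equal(back$electrode_ids, 1:2)
  expect_equal(back$beat_marks, c(0, 0.05), tolerance = 1e-6)
  expect_equal(back$samples, egm$samples, tolerance = 1e-6)
})

test_that("electrogram reader names missing or bad fs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("electrode_id,s1", "1,0.0"), path)
  expect_error(read_electrograms(path), "fs")
  expect_error(egm_set(matrix(0, 1, 2), fs = -5), "fs")
})

test_that("timelines validate epochs and serialize", {
  tl <- protocol_timeline(list(baseline_pre = c(0, 60), lad_pre = c(60, 240)),
                          stim_pulses = list(t2 = seq(1, 60)))
  expect_equal(epoch_window(tl, "lad_pre"), c(60, 240))
  expect_length(tl$stim_pulses$t2, 60)

  expect_error(protocol_timeline(list(a = c(10, 5))), "end > start")
  expect_error(protocol_timeline(list(baseline_pre = c(0, 100),
                                      lad_pre = c(50, 200))), "overlap")
  expect_warning(protocol_timeline(list(lad_pre = c(0, 5))), "shorter")
  # stimulus epochs are allowed inside a baseline
  expect_silent(protocol_timeline(list(baseline_pre = c(0, 100),
                                       touch_rv = c(10, 25))))

  path <- withr::local_tempfile(fileext = ".json")
  write_timeline(tl, path)
  back <- read_timeline(path)
  expect_equal(back$epochs, tl$epochs)
  expect_equal(back$stim_pulses$t2, tl$stim_pulses$t2)
})

test_that("result tables enforce vocabulary and round-trip", {
  rt <- result_table(c("n1", "n2"), "lad_pre", "delta_hz", c(1.25, -0.5),
                     p_value = c(0.01, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_result_table(rt, path)
  back <- read_result_table(path)
  expect_equal(back$value, rt$value, tolerance = 1e-6)
  expect_equal(back$metric, rt$metric)
  expect_error(result_table("x", "e", "not_a_metric", 1), "unregistered")
})
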