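test_that("synthesize_call honours duration, amplitude and the Nyquist bound", {
  expect_length(synthesize_call(tone_prototype(3000, 0.1), 19000), 1900)
  silent <- call_prototype(c(3000, 3000), 0.1, amplitude = 0)
  expect_true(all(synthesize_call(silent, 19000) == 0))
  loud <- call_prototype(c(4000, 4000), 0.1, harmonics = 3L)
  expect_error(synthesize_call(loud, 19000), "Nyquist.*12000")
})

test_that("a constant-contour call is dominated by its fundamental", {
  w <- synthesize_call(tone_prototype(3000, 0.2, harmonics = 3L), 19000)
  s <- vocalflock:::stft_mag(w, 19000)
  dom <- s$freq[apply(s$mag, 2, which.max)]
  expect_true(all(abs(dom - 3000) <= FREQ_BIN))
})

test_that("flock call simulation is reproducible and static without dynamics", {
  profs <- dynamics_profiles(convergence_rate = 0, drift_rate = 0)
  a <- simulate_flock_calls(profs, blocks = 5, sessions_per_block = 1,
                            seed = 42, calls_per_session = 5)
  b <- simulate_flock_calls(profs, blocks = 5, sessions_per_block = 1,
                            seed = 42, calls_per_session = 5)
  expect_identical(a$calls$contour, b$calls$contour)
  # no dynamics: the truth distance is flat across blocks
  flat <- tidyr::pivot_wider(a$truth, names_from = "block",
                             values_from = "contour_dist")
  expect_equal(flat[["5"]], flat[["1"]], tolerance = 1e-12)
})

test_that("convergence without drift contracts contour distances every block", {
  profs <- dynamics_profiles(convergence_rate = 0.3, drift_rate = 0, seed = 2)
  fc <- simulate_flock_calls(profs, blocks = 5, sessions_per_block = 1,
                             seed = 1, calls_per_session = 3)
  for (ind in unique(fc$truth$individual)) {
    d <- fc$truth$contour_dist[fc$truth$individual == ind]
    expect_true(all(diff(d) < 0))
  }
})

test_that("age presets shift duration, frequency and FM in the right direction", {
  young <- age_preset("young"); old <- age_preset("old")
  expect_lt(old$duration_s, young$duration_s)
  expect_gt(old$base_freq_hz, young$base_freq_hz)
  expect_lt(old$fm_depth_hz, young$fm_depth_hz)
  # realized calls inherit the preset direction; averaged over several
  # flocks because each bird also carries a random frequency signature
  sim_stats <- function(age, seed) {
    stats <- purrr::map(1:6, function(k) {
      profs <- with_seed(seed + k, flock_profiles("f", age))
      fc <- simulate_flock_calls(profs, blocks = 2, sessions_per_block = 2,
                                 seed = seed + k, calls_per_session = 15)
      fm <- vapply(fc$calls$contour, function(ct) diff(range(ct)), numeric(1))
      c(dur = mean(fc$calls$duration),
        freq = mean(vapply(fc$calls$contour, mean, numeric(1))),
        fm = mean(fm))
    })
    Reduce(`+`, stats) / length(stats)
  }
  y <- sim_stats("young", 7); o <- sim_stats("old", 8)
  expect_lt(o["dur"], y["dur"])
  expect_gt(o["freq"], y["freq"])
  expect_lt(o["fm"], y["fm"])
})

test_that("interaction counts have the programmed mean and rates of zero are empty", {
  birds <- paste0("b", 1:4)
  none <- simulate_interactions(birds, list(affiliative = 0, agonistic = 0),
                                sessions = 10, seed = 1)
  expect_equal(nrow(none), 0)
  # Monte-Carlo mean for one dyad at rate 5
  counts <- vapply(1:300, function(i) {
    ev <- simulate_interactions(c("a", "b"), list(affiliative = 5,
                                                  agonistic = 0),
                                sessions = 10, seed = i)
    nrow(ev) / 10
  }, numeric(1))
  expect_equal(mean(counts), 5, tolerance = 0.1)
})

test_that("proximity snapshots respect affinity, absence and the design size", {
  birds <- paste0("b", 1:4)
  all_close <- simulate_proximity(birds, affinity = 1, snapshots = 11,
                                  absence_prob = 0, seed = 1)
  expect_true(all(all_close$distance_cm <= 10))
  expect_equal(nrow(all_close), 11 * 6)
  default_n <- simulate_proximity(birds, affinity = 0.3, seed = 1)
  expect_equal(length(unique(default_n$snapshot)), 88)
  big <- simulate_proximity(c("a", "b"), affinity = 0.3, snapshots = 10000,
                            absence_prob = 0, seed = 3)
  expect_equal(mean(big$distance_cm <= 10), 0.3, tolerance = 0.03)
})

test_that("rendered sessions tile ground-truth selections exactly", {
  profs <- dynamics_profiles(seed = 5)
  fc <- simulate_flock_calls(profs[1:2], blocks = 2, sessions_per_block = 1,
                             seed = 3, calls_per_session = 4)
  dir <- withr::local_tempdir()
  man <- render_sessions(fc, dir, sample_rate = 19000, seed = 9)
  w <- read_wav(man$wav[1])
  sel <- read_selection_table(man$selections[1])
  expect_equal(nrow(sel), man$n_calls[1])
  # each annotated interval contains signal well above the background
  for (i in seq_len(nrow(sel))) {
    seg <- w$samples[(round(sel$start[i] * 19000) + 1):round(sel$end[i] * 19000)]
    expect_gt(sd(seg), 10 * 0.003)
  }
  # intervals are disjoint and sorted
  expect_true(all(diff(sel$start) > 0))
  expect_true(all(head(sel$end, -1) <= tail(sel$start, -1) + 1e-9))
})
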