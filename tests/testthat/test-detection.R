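test_that("an all-zero waveform gives no detections, not an error", {
  expect_equal(nrow(energy_detect(numeric(1000), 19000)), 0)
})

test_that("a single call is localized and detection is gain-invariant", {
  proto <- tone_prototype(3000, 0.15)
  sess <- make_session(list(proto), gap = 1.0, noise = 0.01, seed = 2)
  det <- energy_detect(sess$wave, 19000, detector_params())
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$start - sess$truth$start), 0.02)
  expect_lt(abs((det$end - det$start) - 0.15), 0.04)
  det_scaled <- energy_detect(sess$wave * 7.3, 19000, detector_params())
  expect_equal(det_scaled$start, det$start)
  expect_equal(det_scaled$end, det$end)
})

test_that("calls separated by less than the hold time merge into one", {
  proto <- tone_prototype(3000, 0.1)
  w <- synthesize_call(proto, 19000)
  gap <- numeric(round(0.03 * 19000))
  wave <- c(numeric(1900), w, gap, w, numeric(1900))
  p <- detector_params(hold_time = 0.05, max_duration = 0.4)
  expect_equal(nrow(energy_detect(wave, 19000, p)), 1)
  p2 <- detector_params(hold_time = 0.005, max_duration = 0.4)
  expect_equal(nrow(energy_detect(wave, 19000, p2)), 2)
})

test_that("optimizer equals brute force and finds a perfect setting when one exists", {
  protos <- lapply(c(2500, 3200, 2800, 3500), tone_prototype, duration = 0.15)
  sess <- make_session(protos, gap = 0.6, noise = 0.01, seed = 3)
  grid <- tidyr::expand_grid(amplitude_threshold = c(0.05, 0.2, 0.5),
                             hold_time = c(0.02, 0.05))
  opt <- optimize_detector(sess$wave, sess$sample_rate, sess$truth, grid)
  expect_equal(opt$diagnostics$f_score, 1.0)
  # brute force: re-evaluate every grid point independently
  f_brute <- vapply(seq_len(nrow(grid)), function(i) {
    p <- detector_params(amplitude_threshold = grid$amplitude_threshold[i],
                         hold_time = grid$hold_time[i])
    detection_diagnostics(energy_detect(sess$wave, sess$sample_rate, p),
                          sess$truth)$f_score
  }, numeric(1))
  expect_equal(opt$diagnostics$f_score, max(f_brute))
  best_brute <- which(f_brute == max(f_brute))
  got <- which(grid$amplitude_threshold == opt$params$amplitude_threshold &
                 grid$hold_time == opt$params$hold_time)
  expect_true(got %in% best_brute)
})

test_that("an absurd grid scores zero and empty truth is an error", {
  sess <- make_session(list(tone_prototype()), gap = 0.5, seed = 4)
  grid <- tibble::tibble(min_duration = 10, max_duration = 20)
  opt <- optimize_detector(sess$wave, sess$sample_rate, sess$truth, grid)
  expect_equal(opt$diagnostics$recall, 0)
  expect_equal(opt$diagnostics$f_score, 0)
  expect_error(optimize_detector(sess$wave, sess$sample_rate,
                                 sess$truth[0, ], grid), "non-empty")
})

test_that("end-to-end recall stays high over many noisy sessions", {
  profs <- dynamics_profiles(seed = 11)
  fc <- simulate_flock_calls(profs, blocks = 5, sessions_per_block = 1,
                             seed = 12, calls_per_session = 5)
  dir <- withr::local_tempdir()
  man <- render_sessions(fc, dir, sample_rate = 19000, noise_level = 0.005,
                         seed = 13)
  diag <- purrr::map_dfr(seq_len(nrow(man)), function(i) {
    w <- read_wav(man$wav[i])
    detection_diagnostics(energy_detect(w$samples, w$sample_rate,
                                        detector_params()),
                          read_selection_table(man$selections[i]))
  })
  recall <- sum(diag$true_positives) /
    (sum(diag$true_positives) + sum(diag$false_negatives))
  expect_gte(recall, 0.9)
})

test_that("the signal/noise classifier separates well-separated classes", {
  with_seed(21, {
    train <- rbind(matrix(rnorm(500 * 5), 500), matrix(rnorm(500 * 5) + 5, 500))
    labels <- rep(c("noise", "signal"), each = 500)
    test <- rbind(matrix(rnorm(100 * 5), 100), matrix(rnorm(100 * 5) + 5, 100))
  })
  colnames(train) <- colnames(test) <- paste0("f", 1:5)
  pred <- classify_selections(as.data.frame(train), labels,
                              as.data.frame(test), seed = 3)
  truth <- rep(c("noise", "signal"), each = 100)
  expect_gte(mean(pred$label == truth), 0.99)
  expect_equal(pred$prob_signal + pred$prob_noise, rep(1, 200),
               tolerance = 1e-12)
  # deterministic given seed
  pred2 <- classify_selections(as.data.frame(train), labels,
                               as.data.frame(test), seed = 3)
  expect_identical(pred$prob_signal, pred2$prob_signal)
  expect_error(classify_selections(as.data.frame(train),
                                   rep("signal", 1000),
                                   as.data.frame(test)), "two classes")
})
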