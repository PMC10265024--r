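#' Construct energy-detector parameters
#'
#' The detector works on the band-limited amplitude envelope: calls are
#' contiguous runs where the envelope exceeds a threshold expressed as a
#' fraction of the envelope maximum, merged across short gaps and filtered
#' by duration. Because the threshold is relative, detection is invariant to
#' uniform gain scaling of the recording.
#'
#' @param amplitude_threshold Fraction of the maximum envelope, in (0, 1).
#' @param min_duration,max_duration Admissible call durations, s.
#' @param bandpass Length-2 numeric, Hz: band considered by the detector.
#' @param hold_time Gap-merge window, s: supra-threshold runs separated by
#'   less than this are merged.
#' @return Object of class `detector_params`.
#' @export
detector_params <- function(amplitude_threshold = 0.1, min_duration = 0.05,
                            max_duration = 0.4, bandpass = c(500, 8000),
                            hold_time = 0.05) {
  stopifnot(amplitude_threshold > 0, amplitude_threshold < 1,
            min_duration < max_duration, length(bandpass) == 2,
            bandpass[1] < bandpass[2], hold_time >= 0)
  structure(list(amplitude_threshold = amplitude_threshold,
                 min_duration = min_duration, max_duration = max_duration,
                 bandpass = as.numeric(bandpass), hold_time = hold_time),
            class = "detector_params")
}

# Band-limited, rectified, 5 ms moving-average envelope.
detection_envelope <- function(waveform, sample_rate, bandpass) {
  ny <- sample_rate / 2
  w <- c(max(bandpass[1], 1) / ny, min(bandpass[2], ny * 0.99) / ny)
  bf <- signal::butter(4, w, type = "pass")
  x <- signal::filtfilt(bf, waveform)
  k <- max(1L, round(0.005 * sample_rate))
  env <- stats::filter(abs(x), rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  as.numeric(env)
}

#' Detect candidate calls by envelope thresholding
#'
#' Bandpass-filters the waveform, forms a smoothed amplitude envelope, and
#' returns the supra-threshold runs after gap merging and duration
#' filtering, as half-open `[start, end)` intervals in seconds, sorted and
#' non-overlapping.
#'
#' @param waveform Numeric amplitude series.
#' @param sample_rate Sampling rate, Hz.
#' @param params A [detector_params()] object.
#' @return Tibble with `start`, `end` (s) and `peak_amp` (envelope peak per
#'   detection). Zero rows when nothing exceeds threshold.
#' @export
energy_detect <- function(waveform, sample_rate, params = detector_params()) {
  stopifnot(length(waveform) > 0, inherits(params, "detector_params"))
  empty <- tibble(start = numeric(0), end = numeric(0), peak_amp = numeric(0))
  if (all(waveform == 0)) return(empty)
  env <- detection_envelope(waveform, sample_rate, params$bandpass)
  thr <- params$amplitude_threshold * max(env)
  above <- env >= thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  # merge runs separated by < hold_time
  hold <- params$hold_time * sample_rate
  merged <- runs[1, ]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] < hold)
        merged$end[nrow(merged)] <- runs$end[i]
      else merged <- rbind(merged, runs[i, ])
    }
  }
  dur <- (merged$end - merged$start) / sample_rate
  keep <- dur >= params$min_duration & dur <= params$max_duration
  merged <- merged[keep, , drop = FALSE]
  tibble(
    start = (merged$start - 1L) / sample_rate,
    end = (merged$end - 1L) / sample_rate,
    peak_amp = vapply(seq_len(nrow(merged)), function(i)
      max(env[merged$start[i]:(merged$end[i] - 1L)]), numeric(1))
  )
}

#' Score detections against ground truth
#'
#' A detection is a true positive when it overlaps an annotated call by at
#' least half of that call's duration; each annotation can be credited at
#' most once.
#'
#' @param detections,truth Tibbles with `start` and `end` columns (s).
#' @param min_overlap Fraction of the truth duration that must be covered.
#' @return One-row tibble: `true_positives`, `false_positives`,
#'   `false_negatives`, `recall`, `precision`, `f_score`.
#' @export
detection_diagnostics <- function(detections, truth, min_overlap = 0.5) {
  stopifnot(nrow(truth) > 0)
  matched_truth <- rep(FALSE, nrow(truth))
  tp <- 0L
  if (nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      ov <- pmin(detections$end[i], truth$end) -
        pmax(detections$start[i], truth$start)
      cand <- which(!matched_truth &
                      ov >= min_overlap * (truth$end - truth$start))
      if (length(cand) > 0) {
        matched_truth[cand[which.max(ov[cand])]] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- nrow(detections) - tp
  fn <- sum(!matched_truth)
  recall <- tp / nrow(truth)
  precision <- if (nrow(detections) == 0) 0 else tp / nrow(detections)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(true_positives = tp, false_positives = fp, false_negatives = fn,
         recall = recall, precision = precision, f_score = f)
}

#' Optimize detector parameters on an annotated fixture
#'
#' Exhaustively evaluates a grid of candidate detector settings against
#' ground-truth annotations and returns the setting maximizing the F-score,
#' breaking ties by higher recall and then by lower amplitude threshold.
#'
#' @param waveform,sample_rate The annotated recording.
#' @param truth Tibble of annotated calls (`start`, `end`); must be
#'   non-empty.
#' @param grid Data frame of candidate parameter values, one candidate per
#'   row; columns among `amplitude_threshold`, `min_duration`,
#'   `max_duration`, `hold_time`, `bandpass_low`, `bandpass_high` (missing
#'   columns take [detector_params()] defaults).
#' @return List with `params` (the winning [detector_params()]),
#'   `diagnostics` (its [detection_diagnostics()] row) and `results` (the
#'   full grid with diagnostics per row).
#' @export
optimize_detector <- function(waveform, sample_rate, truth, grid) {
  if (is.null(truth) || nrow(truth) == 0)
    stop("truth selections must be non-empty")
  stopifnot(nrow(grid) > 0)
  as_params <- function(row) {
    d <- detector_params()
    detector_params(
      amplitude_threshold = row$amplitude_threshold %||% d$amplitude_threshold,
      min_duration = row$min_duration %||% d$min_duration,
      max_duration = row$max_duration %||% d$max_duration,
      bandpass = c(row$bandpass_low %||% d$bandpass[1],
                   row$bandpass_high %||% d$bandpass[2]),
      hold_time = row$hold_time %||% d$hold_time)
  }
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- as_params(as.list(grid[i, , drop = FALSE]))
    detection_diagnostics(energy_detect(waveform, sample_rate, p), truth)
  })
  results <- dplyr::bind_cols(as_tibble(grid), dplyr::bind_rows(rows))
  thr <- if ("amplitude_threshold" %in% names(results))
    results$amplitude_threshold else seq_len(nrow(results))
  ord <- order(-results$f_score, -results$recall, thr)
  best <- ord[1]
  list(params = as_params(as.list(grid[best, , drop = FALSE])),
       diagnostics = results[best, setdiff(names(results), names(grid))],
       results = results)
}

#' Classify detections as signal or noise
#'
#' Random-forest filter separating contact calls from cage noise and other
#' sound events, trained on manually sorted detections. Probabilities are
#' per-class and sum to one per row; results are deterministic given the
#' seed.
#'
#' @param train_features Data frame of per-detection features (numeric).
#' @param train_labels Factor or character vector with at least two classes
#'   (typically `"signal"` / `"noise"`).
#' @param test_features Data frame with the same columns as
#'   `train_features`.
#' @param num_trees Number of trees.
#' @param seed Integer seed.
#' @return Tibble: `label` (predicted class) and one probability column per
#'   class, named `prob_<class>`.
#' @export
classify_selections <- function(train_features, train_labels, test_features,
                                num_trees = 500, seed = 1L) {
  train_labels <- as.factor(train_labels)
  if (nlevels(droplevels(train_labels)) < 2)
    stop("training labels must contain at least two classes")
  fit <- ranger::ranger(
    y = droplevels(train_labels), x = as.data.frame(train_features),
    probability = TRUE, num.trees = num_trees, seed = seed)
  prob <- predict(fit, as.data.frame(test_features))$predictions
  out <- as_tibble(as.data.frame(prob))
  names(out) <- paste0("prob_", names(out))
  out$label <- colnames(prob)[max.col(prob, ties.method = "first")]
  dplyr::relocate(out, "label")
}
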