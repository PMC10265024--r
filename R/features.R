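#' Names of the 17 per-call acoustic features
#'
#' Duration; frequency statistics of the time-aggregated magnitude spectrum
#' (mean, sd, median, quartiles); its standardized skewness and kurtosis;
#' four (bounded) entropy/flatness measures; the dominant-frequency-track
#' statistics (mean, min, max, range); and the modulation index. The
#' inter-quartile range, being exactly `q75 - q25`, travels with extracted
#' tables as a convenience column but is not part of the canonical
#' 17-dimensional set used for scaling and embedding.
#'
#' @return Character vector of length 17.
#' @export
acoustic_feature_names <- function() {
  c("duration", "mean_freq", "sd_freq", "median_freq", "q25_freq",
    "q75_freq", "spectral_skewness", "spectral_kurtosis",
    "spectral_entropy", "temporal_entropy", "overall_entropy",
    "spectral_flatness", "mean_dom_freq", "min_dom_freq", "max_dom_freq",
    "dom_freq_range", "modulation_index")
}
all_feature_names <- acoustic_feature_names

#' Downsample and band-limit a recording for analysis
#'
#' Anti-aliased resampling to the 19 kHz analysis rate followed by a
#' zero-phase 0.5-8.0 kHz bandpass (the band containing budgerigar contact
#' calls).
#'
#' @param waveform Numeric amplitude series.
#' @param sample_rate Input sampling rate, Hz; must be at least 16 kHz so
#'   the 8 kHz band edge is representable.
#' @param target_rate Analysis rate, Hz.
#' @param bandpass Length-2 numeric, Hz.
#' @return List with `samples` (length ~ `length(waveform) *
#'   target_rate/sample_rate`) and `sample_rate = target_rate`.
#' @export
preprocess_audio <- function(waveform, sample_rate, target_rate = 19000,
                             bandpass = c(500, 8000)) {
  if (sample_rate < 16000)
    stop("sample_rate must be at least 16 kHz to represent the 8 kHz band edge")
  x <- waveform
  if (sample_rate != target_rate) {
    g <- gcd_int(target_rate, sample_rate)
    x <- as.numeric(signal::resample(x, target_rate / g, sample_rate / g))
    n_out <- round(length(waveform) * target_rate / sample_rate)
    if (length(x) > n_out) x <- x[seq_len(n_out)]
    if (length(x) < n_out) x <- c(x, numeric(n_out - length(x)))
  }
  ny <- target_rate / 2
  bf <- signal::butter(4, c(bandpass[1] / ny, min(bandpass[2] / ny, 0.99)),
                       type = "pass")
  list(samples = as.numeric(signal::filtfilt(bf, x)),
       sample_rate = target_rate)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Short-time magnitude spectrum: Hann window, given window length and
# overlap. Returns bins x frames magnitudes and the bin frequencies.
stft_mag <- function(x, sample_rate, window = 150L, overlap = 0.5) {
  hop <- max(1L, round(window * (1 - overlap)))
  n_frames <- 1L + (length(x) - window) %/% hop
  w <- 0.5 * (1 - cos(2 * pi * seq_len(window) / (window + 1)))
  frames <- vapply(seq_len(n_frames), function(i)
    x[(i - 1L) * hop + seq_len(window)] * w, numeric(window))
  spec <- stats::mvfft(frames)
  n_bins <- window %/% 2L + 1L
  list(mag = abs(spec[seq_len(n_bins), , drop = FALSE]),
       freq = (seq_len(n_bins) - 1L) * sample_rate / window,
       n_frames = n_frames)
}

weighted_quantile <- function(f, p, q) {
  cum <- cumsum(p)
  f[which(cum >= q)[1]]
}

#' Extract the 17-dimensional acoustic feature vector for one call
#'
#' Computes a 150-sample Hann spectrogram (50% overlap) of the call segment
#' and derives: duration; mean, sd, median, quartiles and IQR of the
#' time-aggregated magnitude spectrum restricted to the analysis band;
#' standardized spectral skewness and kurtosis; normalized spectral,
#' temporal and overall entropies and spectral flatness; and the per-frame
#' dominant-frequency track statistics (mean, min, max, range) with the
#' modulation index `sum(|diff(track)|) / range` (defined as 1 when the
#' range is 0).
#'
#' @param waveform Analysis-rate waveform (see [preprocess_audio()]).
#' @param sample_rate Sampling rate, Hz.
#' @param start,end Optional selection bounds in seconds (half-open); the
#'   whole waveform is used when omitted.
#' @param window Spectrogram window length, samples.
#' @param bandpass Length-2 numeric, Hz: band to which frequency statistics
#'   are restricted.
#' @return One-row tibble with 17 feature columns.
#' @export
extract_features <- function(waveform, sample_rate, start = NULL, end = NULL,
                             window = 150L, bandpass = c(500, 8000)) {
  if (!is.null(start) || !is.null(end)) {
    i0 <- max(1L, floor((start %||% 0) * sample_rate) + 1L)
    i1 <- min(length(waveform), ceiling((end %||% (length(waveform) / sample_rate)) * sample_rate))
    waveform <- waveform[i0:i1]
  }
  min_dur <- 2 * window / sample_rate
  if (length(waveform) < 2 * window)
    stop(sprintf("selection too short: need at least %.4f s (2 windows of %d samples)",
                 min_dur, window))
  s <- stft_mag(waveform, sample_rate, window)
  band <- which(s$freq >= bandpass[1] & s$freq <= bandpass[2])
  mag <- s$mag[band, , drop = FALSE]
  f <- s$freq[band]
  agg <- rowMeans(mag)
  if (sum(agg) == 0) agg <- rep(1, length(agg))
  p <- agg / sum(agg)
  mu <- sum(p * f)
  sigma <- sqrt(sum(p * (f - mu)^2))
  q25 <- weighted_quantile(f, p, 0.25)
  q50 <- weighted_quantile(f, p, 0.50)
  q75 <- weighted_quantile(f, p, 0.75)
  z <- (f - mu) / max(sigma, 1e-12)
  ent <- function(q) {
    q <- q[q > 0]
    if (length(q) <= 1) return(0)
    -sum(q * log(q)) / log(length(q))
  }
  pow <- rowMeans(mag^2)
  flat <- exp(mean(log(pow + 1e-300))) / mean(pow + 1e-300)
  frame_env <- sqrt(colMeans(mag^2))
  pt <- frame_env / max(sum(frame_env), 1e-300)
  h_s <- ent(p)
  # temporal entropy uses the full frame count as its normalizer
  h_t <- if (s$n_frames <= 1) 0 else
    -sum(pt[pt > 0] * log(pt[pt > 0])) / log(s$n_frames)
  dom <- f[apply(mag, 2, which.max)]
  dom_range <- max(dom) - min(dom)
  tibble(
    duration = length(waveform) / sample_rate,
    mean_freq = mu, sd_freq = sigma, median_freq = q50, q25_freq = q25,
    q75_freq = q75, iqr_freq = q75 - q25,
    spectral_skewness = sum(p * z^3), spectral_kurtosis = sum(p * z^4),
    spectral_entropy = h_s, temporal_entropy = h_t,
    overall_entropy = h_s * h_t, spectral_flatness = flat,
    mean_dom_freq = mean(dom), min_dom_freq = min(dom),
    max_dom_freq = max(dom), dom_freq_range = dom_range,
    modulation_index = if (dom_range == 0) 1 else
      sum(abs(diff(dom))) / dom_range
  )
}

#' Extract features for a table of rendered calls
#'
#' Maps [extract_features()] over a call table carrying a `waveform`
#' list-column (see [synthesize_call_table()]), keeping the metadata columns
#' in front.
#'
#' @param calls Tibble with a `waveform` list-column and metadata columns.
#' @param sample_rate Sampling rate of the waveforms, Hz.
#' @param ... Passed to [extract_features()].
#' @return Feature table: metadata columns, then the 17 features and the
#'   modulation index companion column.
#' @export
extract_features_table <- function(calls, sample_rate = 19000, ...) {
  stopifnot("waveform" %in% names(calls))
  feats <- purrr::map(calls$waveform, extract_features,
                      sample_rate = sample_rate, ...)
  meta <- intersect(c("call_id", "individual", "flock", "age_class", "block",
                      "session"), names(calls))
  dplyr::bind_cols(calls[meta], dplyr::bind_rows(feats))
}

#' Z-scale a feature table
#'
#' Centers each feature column to mean 0 and scales to unit variance using
#' the population-SD convention (`sqrt(mean((x - mean(x))^2))`). Scaling
#' constants are recorded in the `"scaling"` attribute; applying the
#' function to an already scaled table is a no-op up to numerical error.
#'
#' @param table Feature table (>= 2 rows, no missing values in the scaled
#'   columns).
#' @param cols Columns to scale; defaults to the feature columns present.
#' @return The table with scaled columns and a `"scaling"` attribute
#'   (tibble of column, center, scale).
#' @export
scale_features <- function(table, cols = intersect(all_feature_names(),
                                                   names(table))) {
  stopifnot(nrow(table) >= 2, length(cols) > 0)
  if (anyNA(table[cols])) stop("feature table contains missing values")
  centers <- vapply(table[cols], mean, numeric(1))
  scales <- vapply(cols, function(cn) {
    x <- table[[cn]]
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  bad <- cols[scales == 0]
  if (length(bad) > 0)
    stop("zero-variance feature column(s): ", paste(bad, collapse = ", "))
  for (i in seq_along(cols))
    table[[cols[i]]] <- (table[[cols[i]]] - centers[i]) / scales[i]
  attr(table, "scaling") <- tibble(column = cols, center = centers,
                                   scale = scales)
  table
}
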