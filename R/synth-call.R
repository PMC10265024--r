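#' Construct a contact-call prototype
#'
#' A prototype is the template for one call type in an individual's
#' repertoire: a frequency-modulation contour given as anchor frequencies
#' (interpolated smoothly at synthesis time), a duration, a relative
#' amplitude and a harmonic count. Budgerigar contact calls are short
#' (tens to hundreds of milliseconds) frequency-modulated tones whose
#' contour shape identifies the call type.
#'
#' @param contour_anchor_freqs Numeric vector (length >= 2) of anchor
#'   frequencies, Hz; all within \[500, 8000\].
#' @param duration Call duration in seconds, within \[0.05, 0.4\].
#' @param amplitude Relative peak amplitude in \[0, 1\].
#' @param harmonics Number of harmonic partials (fundamental included),
#'   amplitudes decaying as 1/k.
#' @return An object of class `call_prototype`.
#' @examples
#' p <- call_prototype(c(2500, 3200, 2800), duration = 0.15)
#' @export
call_prototype <- function(contour_anchor_freqs, duration,
                           amplitude = 0.8, harmonics = 3L) {
  stopifnot(length(contour_anchor_freqs) >= 2)
  if (any(contour_anchor_freqs < 500 | contour_anchor_freqs > 8000))
    stop("anchor frequencies must lie within [500, 8000] Hz")
  if (duration < 0.05 || duration > 0.4)
    stop("duration must lie within [0.05, 0.4] s")
  stopifnot(amplitude >= 0, amplitude <= 1, harmonics >= 1)
  structure(
    list(contour_anchor_freqs = as.numeric(contour_anchor_freqs),
         duration = as.numeric(duration),
         amplitude = as.numeric(amplitude),
         harmonics = as.integer(harmonics)),
    class = "call_prototype"
  )
}

#' Age-class generation presets
#'
#' Parameter presets for the two adult age classes. Relative to young
#' adults, older adults produce calls that are shorter, higher in frequency
#' and less frequency-modulated; they also interact affiliatively at a much
#' lower rate, prune part of their repertoire after the baseline block, and
#' call slightly more often per session. Interaction rates are calibrated so
#' that six flocks observed for eight sessions have expected affiliative /
#' agonistic totals of 316/202 (young) and 116/134 (old).
#'
#' @param age_class `"young"` or `"old"`.
#' @return A named list of generation parameters: `duration_s`,
#'   `base_freq_hz`, `fm_depth_hz`, `harmonics`, `call_rate` (expected calls
#'   per recording session), `drift_rate` (per-block anchor jitter sd, Hz),
#'   `convergence_rate` (fractional per-block pull toward the flock-mean
#'   contour), `prune_fraction` (fraction of prototypes dropped after block
#'   1), `repertoire_size`, `call_jitter_hz`, `affiliative_rate` and
#'   `agonistic_rate` (expected interactions per flock per session) and
#'   `interaction_dispersion` (negative-binomial size).
#' @export
age_preset <- function(age_class = c("young", "old")) {
  age_class <- match.arg(age_class)
  young <- list(
    age_class = "young",
    duration_s = 0.18, base_freq_hz = 2800, fm_depth_hz = 700,
    harmonics = 3L, call_rate = 48, repertoire_size = 3L,
    drift_rate = 15, convergence_rate = 0.25, prune_fraction = 0,
    call_jitter_hz = 40, duration_jitter = 0.08,
    affiliative_rate = 316 / (6 * 8), agonistic_rate = 202 / (6 * 8),
    interaction_dispersion = 2
  )
  if (age_class == "young") return(young)
  old <- young
  old$age_class <- "old"
  old$duration_s <- young$duration_s * 0.8
  old$base_freq_hz <- young$base_freq_hz * 1.15
  old$fm_depth_hz <- young$fm_depth_hz * 0.6
  old$call_rate <- 58
  old$prune_fraction <- 0.5
  old$affiliative_rate <- 116 / (6 * 8)
  old$agonistic_rate <- 134 / (6 * 8)
  old
}

#' Draw a random call repertoire for one individual
#'
#' Generates `n` prototypes around an age preset: the bird gets an
#' individual base-frequency signature (lognormal, sd 0.12 around the
#' preset base), and each contour adds a smooth random FM shape of depth
#' `fm_depth_hz` on a per-prototype frequency (lognormal, sd 0.05 around
#' the signature), clamped to the valid band. The individual signature
#' makes baseline repertoires of different birds acoustically distinct, as
#' they are for birds drawn from separate source populations.
#'
#' @param preset An [age_preset()] list.
#' @param n Number of call types; defaults to the preset's repertoire size.
#' @param n_anchors Anchor points per contour.
#' @return List of [call_prototype()] objects.
#' @export
random_repertoire <- function(preset, n = preset$repertoire_size,
                              n_anchors = 5L) {
  signature <- preset$base_freq_hz * exp(rnorm(1, 0, 0.12))
  purrr::map(seq_len(n), function(i) {
    base <- signature * exp(rnorm(1, 0, 0.05))
    shape <- rnorm(n_anchors, 0, 1)
    shape <- shape - mean(shape)
    shape <- shape / max(abs(shape), 1e-9)
    contour <- pmin(7800, pmax(700, base + preset$fm_depth_hz * shape))
    dur <- min(0.4, max(0.05, preset$duration_s * exp(rnorm(1, 0, 0.1))))
    call_prototype(contour, dur, amplitude = runif(1, 0.6, 0.95),
                   harmonics = preset$harmonics)
  })
}

# Smooth instantaneous-frequency contour: cubic (spline) interpolation of the
# anchor frequencies across the call duration, evaluated per sample.
contour_track <- function(anchor_freqs, n_samples) {
  if (n_samples == 1) return(anchor_freqs[1])
  anchors_t <- seq(0, 1, length.out = length(anchor_freqs))
  if (length(anchor_freqs) > 2 && stats::var(anchor_freqs) > 0) {
    stats::spline(anchors_t, anchor_freqs, method = "natural",
                  xout = seq(0, 1, length.out = n_samples))$y
  } else {
    approx(anchors_t, anchor_freqs, xout = seq(0, 1, length.out = n_samples))$y
  }
}

#' Synthesize a single contact call
#'
#' Renders a prototype as a harmonic stack (fundamental plus integer
#' harmonics with 1/k amplitude decay) whose instantaneous frequency follows
#' a smooth interpolation of the anchor contour, with optional additive
#' broadband noise. A 5 ms raised-cosine onset/offset ramp suppresses edge
#' clicks.
#'
#' @param prototype A [call_prototype()].
#' @param sample_rate Sampling rate, Hz; must be at least twice the highest
#'   harmonic frequency.
#' @param noise_level Relative sd of additive white noise (0 disables).
#' @param seed Optional integer seed for the noise draw.
#' @return Numeric waveform of `round(duration * sample_rate)` samples.
#' @examples
#' w <- synthesize_call(call_prototype(c(3000, 3000), 0.1), 19000)
#' length(w)  # 1900
#' @export
synthesize_call <- function(prototype, sample_rate, noise_level = 0,
                            seed = NULL) {
  stopifnot(inherits(prototype, "call_prototype"))
  f_top <- max(prototype$contour_anchor_freqs) * prototype$harmonics
  if (sample_rate < 2 * f_top)
    stop(sprintf(
      "Nyquist violation: harmonic %d reaches %.0f Hz but sample rate %.0f Hz only represents %.0f Hz",
      prototype$harmonics, f_top, sample_rate, sample_rate / 2))
  n <- round(prototype$duration * sample_rate)
  if (n == 0) return(numeric(0))
  if (prototype$amplitude == 0 && noise_level == 0) return(numeric(n) * 0)
  f <- contour_track(prototype$contour_anchor_freqs, n)
  phase <- 2 * pi * cumsum(f) / sample_rate
  w <- numeric(n)
  for (k in seq_len(prototype$harmonics)) w <- w + sin(k * phase) / k
  if (max(abs(w)) > 0) w <- w / max(abs(w))
  ramp_n <- min(n %/% 2, round(0.005 * sample_rate))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    w[seq_len(ramp_n)] <- w[seq_len(ramp_n)] * ramp
    w[n + 1 - seq_len(ramp_n)] <- w[n + 1 - seq_len(ramp_n)] * rev(ramp)
  }
  w <- w * prototype$amplitude
  if (noise_level > 0) {
    w <- if (is.null(seed)) w + rnorm(n, 0, noise_level)
         else with_seed(seed, w + rnorm(n, 0, noise_level))
  }
  w
}
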