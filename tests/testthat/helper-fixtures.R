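# Shared fixtures: all synthetic, generated in code at test time.

FREQ_BIN <- 19000 / 150  # spectrogram bin width at the analysis rate

tone_prototype <- function(freq = 3000, duration = 0.15, harmonics = 1L) {
  call_prototype(c(freq, freq), duration, amplitude = 0.9,
                 harmonics = harmonics)
}

sweep_prototype <- function(f0 = 2000, f1 = 4000, duration = 0.2) {
  call_prototype(c(f0, f1), duration, amplitude = 0.9, harmonics = 1L)
}

# One session waveform with calls at known positions (fixed gaps).
make_session <- function(protos, sample_rate = 19000, gap = 0.5,
                         noise = 0.01, seed = 1) {
  waves <- lapply(protos, synthesize_call, sample_rate = sample_rate)
  gap_n <- round(gap * sample_rate)
  starts <- cumsum(c(gap_n, head(lengths(waves), -1) + gap_n))
  total <- starts[length(starts)] + length(waves[[length(waves)]]) + gap_n
  wave <- with_seed(seed, rnorm(total, 0, noise))
  for (i in seq_along(waves)) {
    idx <- starts[i] + seq_along(waves[[i]])
    wave[idx] <- wave[idx] + waves[[i]]
  }
  list(wave = wave, sample_rate = sample_rate,
       truth = tibble::tibble(start = starts / sample_rate,
                              end = (starts + lengths(waves)) / sample_rate))
}

with_seed <- vocalflock:::with_seed

# Four-bird flock with explicit dynamics, built on the young preset.
dynamics_profiles <- function(convergence_rate = 0, drift_rate = 0,
                              prune_fraction = 0, seed = 1,
                              flock_id = "fx") {
  preset <- age_preset("young")
  with_seed(seed, {
    lapply(1:4, function(i) {
      individual_profile(
        sprintf("%s_b%d", flock_id, i), "young",
        repertoire = random_repertoire(preset),
        drift_rate = drift_rate, convergence_rate = convergence_rate,
        prune_fraction = prune_fraction,
        call_jitter_hz = preset$call_jitter_hz,
        duration_jitter = preset$duration_jitter)
    })
  })
}

# Feature table drawn from k well-separated 17-D Gaussian clusters.
cluster_features <- function(n_per = 100, k = 3, sep = 10, seed = 1) {
  X <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(k), function(j) {
      matrix(rnorm(n_per * 17), n_per) + (j - (k + 1) / 2) * sep
    }))
  })
  tab <- tibble::as_tibble(as.data.frame(X))
  names(tab) <- acoustic_feature_names()
  tab$cluster <- rep(seq_len(k), each = n_per)
  tab
}

# Independent fine-grid oracle: evaluates a Gaussian-mixture KDE by direct
# summation on its own grid and integrates numerically. Used to check
# kde_space/overlap against a second, simpler code path.
oracle_kde <- function(p, bw, grid_n = 800, lims) {
  gx <- seq(lims[1], lims[2], length.out = grid_n)
  gy <- seq(lims[3], lims[4], length.out = grid_n)
  dz <- matrix(0, length(gx), length(gy))
  for (k in seq_len(nrow(p)))
    dz <- dz + outer(dnorm(gx, p[k, 1], bw[1]), dnorm(gy, p[k, 2], bw[2]))
  dz <- dz / nrow(p)
  cell <- diff(gx[1:2]) * diff(gy[1:2])
  dz <- dz / (sum(dz) * cell)
  list(x = gx, y = gy, z = dz, cell = cell)
}

oracle_hdr <- function(o, level) {
  ord <- order(o$z, decreasing = TRUE)
  n_in <- which(cumsum(o$z[ord] * o$cell) >= level)[1]
  mask <- array(FALSE, dim(o$z)); mask[ord[seq_len(n_in)]] <- TRUE
  list(mask = mask, area = n_in * o$cell)
}

# Simulate a vocal-metrics-shaped table: 12 flocks x 4 birds x blocks 2-5,
# with planted age/block effects on the model's linear-predictor scale.
sim_metrics <- function(beta_age = 0, beta_block = 0, beta_inter = 0,
                        family = "gaussian", sd_ind = 0.3, sd_flock = 0.2,
                        sd_res = 0.5, intercept = 0, nb_size = 5) {
  flocks <- tidyr::expand_grid(age_class = c("young", "old"), rep = 1:6)
  flocks$flock <- paste0(substr(flocks$age_class, 1, 1), flocks$rep)
  d <- tidyr::expand_grid(flock_i = seq_len(nrow(flocks)), bird = 1:4,
                          block = 2:5)
  d$flock <- flocks$flock[d$flock_i]
  d$age_class <- flocks$age_class[d$flock_i]
  d$individual <- paste0(d$flock, "_b", d$bird)
  re_f <- rnorm(nrow(flocks), 0, sd_flock)
  ind_ids <- unique(d$individual)
  re_i <- setNames(rnorm(length(ind_ids), 0, sd_ind), ind_ids)
  young <- as.numeric(d$age_class == "young")
  eta <- intercept + beta_age * young + beta_block * d$block +
    beta_inter * young * d$block + re_f[d$flock_i] + re_i[d$individual]
  d$y <- switch(family,
                gaussian = eta + rnorm(nrow(d), 0, sd_res),
                nb = rnbinom(nrow(d), mu = exp(eta), size = nb_size),
                beta = {
                  mu <- stats::plogis(eta)
                  phi <- 20
                  rbeta(nrow(d), mu * phi, (1 - mu) * phi)
                })
  d
}

# One replicate of the convergence parameter-recovery experiment: a spaced
# benchmark flock run through the full audio -> features -> embedding ->
# spaces -> convergence chain; returns the fitted block-slope.
convergence_slope <- function(rate, seed, calls_per_session = 12) {
  profs <- spaced_profiles(convergence_rate = rate, drift_rate = 0,
                           seed = seed)
  fc <- simulate_flock_calls(profs, blocks = 5, sessions_per_block = 2,
                             seed = seed + 1000,
                             calls_per_session = calls_per_session)
  calls <- synthesize_call_table(fc$calls, 19000, noise_level = 0.003,
                                 seed = seed + 2000)
  sc <- scale_features(extract_features_table(calls))
  emb <- embed_features(sc, perplexity = 25, iterations = 500,
                        seed = seed + 3000)
  spaces <- build_acoustic_spaces(emb, grid_resolution = 120)
  cv <- convergence(spaces)
  cv <- cv[cv$block >= 2, ]
  unname(coef(lm(convergence ~ block, cv))[2])
}

# Small embedded call table built directly from 2-D coordinates, bypassing
# audio, for space/metric tests: one row per call.
coords_as_emb <- function(coords, individual, block, flock = "f1",
                          age_class = "young") {
  tibble::tibble(individual = individual, flock = flock,
                 age_class = age_class, block = block,
                 dim1 = coords[, 1], dim2 = coords[, 2])
}
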