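default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_flocks_per_age = 1L, blocks = 5L,
                    sessions_per_block = 4L, video_sessions = 8L,
                    snapshots = 88L, calls_per_session = 25L),
    audio = list(sample_rate = 19000, noise_level = 0.004, gap_mean = 0.35),
    detect = list(
      grid = list(amplitude_threshold = c(0.05, 0.1, 0.2),
                  hold_time = c(0.03, 0.05))),
    features = list(window = 150L, bandpass = c(500, 8000)),
    embedding = list(perplexity = 30, iterations = 1000),
    space = list(hdr_level = 0.95, grid_resolution = 200L, min_calls = 5L),
    network = list(period = "all"),
    models = list(alpha = 0.05)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      merge_config(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

#' Assemble a pipeline configuration
#'
#' Starts from the package defaults and overrides them with a user list or
#' a YAML file. Every stochastic stage derives its seed deterministically
#' from the single master `seed`, so a rerun with the same configuration is
#' reproducible.
#'
#' @param config Named list of overrides, or a path to a YAML file.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(default_config(), config)
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Executes the stages in order — simulate, detect, features, space,
#' metrics, network, models — writing stage outputs (CSV) and a JSON
#' manifest (parameters, seeds, file hashes) into `dir`. Detection is
#' optimized on the first rendered session against its ground-truth
#' annotations, then applied to every session; features are extracted from
#' the detected calls, scaled, jointly embedded, and turned into acoustic
#' spaces and vocal metrics; interaction and proximity logs become social
#' networks; both metric sets feed the model battery.
#'
#' @param config A [pipeline_config()] (list or YAML path accepted).
#' @param dir Output run directory (created; must not already contain a
#'   manifest).
#' @return List with `manifest`, `experiment`, `detections`, `features`,
#'   `embedding`, `metrics`, `networks`, `models`, `dir`, invisibly.
#' @export
run_pipeline <- function(config = list(), dir = tempfile("vocalflock_run_")) {
  cfg <- pipeline_config(if (is.character(config)) config else config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  seed <- cfg$seed

  # --- simulate ---------------------------------------------------------
  exp <- do.call(simulate_experiment,
                 c(cfg$simulate, list(seed = stage_seed(seed, "simulate"))))
  readr::write_csv(exp$events, file.path(dir, "events.csv"))
  readr::write_csv(exp$snapshots, file.path(dir, "snapshots.csv"))
  readr::write_csv(exp$truth, file.path(dir, "contour_truth.csv"))
  stages <- c(stages, "simulate")

  # --- detect -----------------------------------------------------------
  audio_dir <- file.path(dir, "audio")
  manifest_audio <- dplyr::bind_rows(purrr::map(
    split(exp$calls, exp$calls$flock), function(calls_f) {
      fc <- structure(list(calls = calls_f, flock_id = calls_f$flock[1]),
                      class = "flock_calls")
      render_sessions(fc, audio_dir, sample_rate = cfg$audio$sample_rate,
                      noise_level = cfg$audio$noise_level,
                      gap_mean = cfg$audio$gap_mean,
                      seed = stage_seed(seed, paste0("render_",
                                                     calls_f$flock[1])))
    }))
  probe <- read_wav(manifest_audio$wav[1])
  probe_truth <- read_selection_table(manifest_audio$selections[1])
  opt <- optimize_detector(probe$samples, probe$sample_rate, probe_truth,
                           tidyr::expand_grid(!!!cfg$detect$grid))
  detections <- purrr::map_dfr(seq_len(nrow(manifest_audio)), function(i) {
    w <- read_wav(manifest_audio$wav[i])
    det <- energy_detect(w$samples, w$sample_rate, opt$params)
    if (nrow(det) == 0) return(tibble())
    dplyr::bind_cols(manifest_audio[i, c("individual", "flock", "age_class",
                                         "block", "session")][
                                           rep(1, nrow(det)), ], det)
  })
  readr::write_csv(detections, file.path(dir, "detections.csv"))
  jsonlite::write_json(as.list(opt$diagnostics),
                       file.path(dir, "detector_diagnostics.json"),
                       auto_unbox = TRUE)
  stages <- c(stages, "detect")

  # --- features ---------------------------------------------------------
  feats <- purrr::map_dfr(seq_len(nrow(manifest_audio)), function(i) {
    det <- detections[detections$individual == manifest_audio$individual[i] &
                        detections$block == manifest_audio$block[i] &
                        detections$session == manifest_audio$session[i], ]
    if (nrow(det) == 0) return(tibble())
    w <- read_wav(manifest_audio$wav[i])
    pre <- preprocess_audio(w$samples, w$sample_rate,
                            bandpass = cfg$features$bandpass)
    ratio <- pre$sample_rate / w$sample_rate
    purrr::map_dfr(seq_len(nrow(det)), function(j) {
      fv <- try(extract_features(pre$samples, pre$sample_rate,
                                 start = det$start[j], end = det$end[j],
                                 window = cfg$features$window,
                                 bandpass = cfg$features$bandpass),
                silent = TRUE)
      if (inherits(fv, "try-error")) return(tibble())
      dplyr::bind_cols(det[j, c("individual", "flock", "age_class", "block",
                                "session", "start", "end")], fv)
    })
  })
  scaled <- scale_features(feats)
  readr::write_csv(feats, file.path(dir, "features.csv"))
  stages <- c(stages, "features")

  # --- space ------------------------------------------------------------
  perp <- min(cfg$embedding$perplexity, floor((nrow(scaled) - 1) / 3))
  emb <- embed_features(scaled, perplexity = perp,
                        iterations = cfg$embedding$iterations,
                        seed = stage_seed(seed, "embedding"))
  readr::write_csv(
    emb[c("individual", "flock", "age_class", "block", "dim1", "dim2")],
    file.path(dir, "embedding.csv"))
  spaces <- build_acoustic_spaces(emb, hdr_level = cfg$space$hdr_level,
                                  grid_resolution = cfg$space$grid_resolution,
                                  min_calls = cfg$space$min_calls)
  stages <- c(stages, "space")

  # --- metrics ----------------------------------------------------------
  metrics <- vocal_metrics(emb, spaces = spaces)
  readr::write_csv(metrics, file.path(dir, "vocal_metrics.csv"))
  stages <- c(stages, "metrics")

  # --- network ----------------------------------------------------------
  networks <- network_metrics(exp$events, exp$snapshots, exp$flocks,
                              period = cfg$network$period)
  readr::write_csv(networks$density, file.path(dir, "network_density.csv"))
  readr::write_csv(networks$strength, file.path(dir, "network_strength.csv"))
  stages <- c(stages, "network")

  # --- models -----------------------------------------------------------
  battery <- fit_model_battery(metrics, networks, alpha = cfg$models$alpha)
  readr::write_csv(battery$table, file.path(dir, "model_table.csv"))
  stages <- c(stages, "models")

  outputs <- list.files(dir, pattern = "\\.csv$|\\.json$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vocalflock")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = seed, stages = stages, config = cfg,
    hashes = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, experiment = exp,
                 detections = detections, features = feats, embedding = emb,
                 spaces = spaces, metrics = metrics, networks = networks,
                 models = battery, dir = dir))
}
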