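#' Construct an individual simulation profile
#'
#' Bundles everything the generator needs for one bird: its identity and age
#' class, its baseline call-type repertoire, and the dynamics of that
#' repertoire across recording blocks (random drift, convergence toward the
#' flock-mean contour, optional pruning after the baseline block).
#'
#' @param individual_id Character id.
#' @param age_class `"young"` or `"old"`.
#' @param repertoire Non-empty list of [call_prototype()] objects.
#' @param drift_rate Per-block anchor jitter sd, Hz (>= 0).
#' @param convergence_rate Fraction in \[0, 1\]: per-block pull of each
#'   contour toward the flock-mean contour.
#' @param call_rate Expected calls per recording session.
#' @param prune_fraction Fraction of prototypes dropped after block 1.
#' @param call_jitter_hz Per-call anchor jitter sd, Hz.
#' @param duration_jitter Per-call lognormal duration jitter sd.
#' @return An object of class `individual_profile`.
#' @export
individual_profile <- function(individual_id, age_class, repertoire,
                               drift_rate = 0, convergence_rate = 0,
                               call_rate = 48, prune_fraction = 0,
                               call_jitter_hz = 40, duration_jitter = 0.08) {
  stopifnot(length(repertoire) >= 1,
            all(vapply(repertoire, inherits, logical(1), "call_prototype")),
            drift_rate >= 0, convergence_rate >= 0, convergence_rate <= 1,
            call_rate >= 0, prune_fraction >= 0, prune_fraction < 1)
  structure(
    list(individual_id = as.character(individual_id),
         age_class = match.arg(age_class, c("young", "old")),
         repertoire = repertoire, drift_rate = drift_rate,
         convergence_rate = convergence_rate, call_rate = call_rate,
         prune_fraction = prune_fraction, call_jitter_hz = call_jitter_hz,
         duration_jitter = duration_jitter),
    class = "individual_profile"
  )
}

#' Build four profiles for one same-age flock
#'
#' @param flock_id Character flock id.
#' @param age_class `"young"` or `"old"`.
#' @param preset Generation preset; defaults to [age_preset()] for the class.
#' @param n_birds Flock size (the study design uses 4).
#' @return List of [individual_profile()] objects.
#' @export
flock_profiles <- function(flock_id, age_class, preset = age_preset(age_class),
                           n_birds = 4L) {
  purrr::map(seq_len(n_birds), function(i) {
    individual_profile(
      individual_id = sprintf("%s_b%d", flock_id, i),
      age_class = age_class,
      repertoire = random_repertoire(preset),
      drift_rate = preset$drift_rate,
      convergence_rate = preset$convergence_rate,
      call_rate = preset$call_rate,
      prune_fraction = preset$prune_fraction,
      call_jitter_hz = preset$call_jitter_hz,
      duration_jitter = preset$duration_jitter
    )
  })
}

#' Build a benchmark flock with well-separated baseline repertoires
#'
#' Four birds whose call types occupy distinct frequency regions, so that
#' baseline acoustic spaces overlap little and planted convergence or drift
#' dynamics are identifiable. Used for parameter-recovery studies of the
#' convergence statistic.
#'
#' @param flock_id Flock label.
#' @param convergence_rate,drift_rate Repertoire dynamics (see
#'   [individual_profile()]).
#' @param base_freqs One base frequency per bird, Hz.
#' @param fm_depth FM contour depth, Hz.
#' @param n_prototypes Call types per bird.
#' @param seed Integer seed for the repertoire draw.
#' @return List of [individual_profile()] objects.
#' @export
spaced_profiles <- function(flock_id = "rx", convergence_rate = 0,
                            drift_rate = 0,
                            base_freqs = c(2000, 2600, 3200, 3800),
                            fm_depth = 400, n_prototypes = 2L, seed = 1L) {
  with_seed(seed, {
    purrr::map(seq_along(base_freqs), function(i) {
      rep <- purrr::map(seq_len(n_prototypes), function(j) {
        shape <- rnorm(5); shape <- shape - mean(shape)
        shape <- shape / max(abs(shape), 1e-9)
        call_prototype(
          pmin(pmax(base_freqs[i] + fm_depth * shape, 700), 7800),
          duration = min(0.4, max(0.05, 0.18 * exp(rnorm(1, 0, 0.1)))),
          amplitude = 0.85, harmonics = 2L)
      })
      individual_profile(sprintf("%s_b%d", flock_id, i), "young", rep,
                         drift_rate = drift_rate,
                         convergence_rate = convergence_rate,
                         call_jitter_hz = 40, duration_jitter = 0.08)
    })
  })
}

# Resample every prototype contour to a fixed anchor count so contours can be
# averaged and compared across birds.
anchors_matrix <- function(repertoire, n_anchors = 5L) {
  t(vapply(repertoire,
           function(p) contour_track(p$contour_anchor_freqs, n_anchors),
           numeric(n_anchors)))
}

#' Simulate contact-call production for one flock across recording blocks
#'
#' Block 1 draws calls from each bird's baseline repertoire (the pre-flock
#' recordings). From block 2 on, every contour moves a fraction
#' `convergence_rate` toward the flock-mean baseline contour and is jittered
#' with sd `drift_rate` Hz, emulating imitation of flockmates after novel
#' flock formation; birds with a positive `prune_fraction` drop that share of
#' their call types after block 1. Each realized call adds per-call contour
#' and duration jitter around the block's prototype.
#'
#' @param profiles List of [individual_profile()] (one flock, typically 4).
#' @param blocks Number of recording blocks (>= 2; block 1 is baseline).
#' @param sessions_per_block Recording sessions per block.
#' @param seed Integer seed; the simulation is reproducible given
#'   (profiles, seed).
#' @param flock_id Flock label stored in the output.
#' @param calls_per_session Optional override of every profile's call rate.
#' @return An object of class `flock_calls`: a list with `calls` (tibble of
#'   individual, age_class, flock, block, session, call id, duration,
#'   amplitude, harmonics and a `contour` list-column of realized anchor
#'   frequencies) and `truth` (tibble of individual x block with
#'   `contour_dist`, the mean root-mean-square distance between the bird's
#'   current prototype contours and those of its flockmates).
#' @export
simulate_flock_calls <- function(profiles, blocks = 5L, sessions_per_block = 4L,
                                 seed = 1L, flock_id = "f1",
                                 calls_per_session = NULL) {
  stopifnot(blocks >= 2, length(profiles) >= 2,
            all(vapply(profiles, inherits, logical(1), "individual_profile")))
  with_seed(seed, {
    n_birds <- length(profiles)
    n_anchors <- 5L
    state <- purrr::map(profiles, ~ anchors_matrix(.x$repertoire, n_anchors))
    durations <- purrr::map(profiles, ~ vapply(.x$repertoire,
                                               function(p) p$duration,
                                               numeric(1)))
    # flock-mean baseline contour: the common convergence target
    target <- Reduce(`+`, purrr::map(state, colMeans)) / n_birds
    active <- purrr::map(profiles, ~ seq_along(.x$repertoire))
    calls <- vector("list", blocks * n_birds)
    truth <- vector("list", blocks)
    for (b in seq_len(blocks)) {
      if (b >= 2) {
        state <- purrr::map2(state, profiles, function(a, pr) {
          a <- a + pr$convergence_rate * (matrix(target, nrow(a), n_anchors,
                                                 byrow = TRUE) - a)
          if (pr$drift_rate > 0)
            a <- a + matrix(rnorm(length(a), 0, pr$drift_rate), nrow(a))
          pmin(pmax(a, 700), 7800)
        })
        if (b == 2)
          active <- purrr::map2(active, profiles, function(idx, pr) {
            keep <- max(1L, ceiling(length(idx) * (1 - pr$prune_fraction)))
            idx[seq_len(keep)]
          })
      }
      mean_contours <- purrr::map2(state, active, ~ colMeans(.x[.y, , drop = FALSE]))
      truth[[b]] <- tibble(
        individual = vapply(profiles, `[[`, character(1), "individual_id"),
        block = b,
        contour_dist = vapply(seq_len(n_birds), function(i) {
          mean(vapply(setdiff(seq_len(n_birds), i), function(m)
            sqrt(mean((mean_contours[[i]] - mean_contours[[m]])^2)),
            numeric(1)))
        }, numeric(1))
      )
      for (i in seq_len(n_birds)) {
        pr <- profiles[[i]]
        rate <- calls_per_session %||% pr$call_rate
        per_session <- rpois(sessions_per_block, rate)
        n_calls <- sum(per_session)
        if (n_calls == 0) next
        proto <- active[[i]][sample.int(length(active[[i]]), n_calls,
                                        replace = TRUE)]
        contours <- purrr::map(proto, function(j)
          pmin(7800, pmax(700, state[[i]][j, ] +
                            rnorm(n_anchors, 0, pr$call_jitter_hz))))
        dur <- pmin(0.4, pmax(0.05,
          durations[[i]][proto] * exp(rnorm(n_calls, 0, pr$duration_jitter))))
        calls[[(b - 1) * n_birds + i]] <- tibble(
          individual = pr$individual_id, age_class = pr$age_class,
          flock = flock_id, block = b,
          session = rep(seq_len(sessions_per_block), per_session),
          prototype = proto, duration = dur, contour = contours,
          amplitude = runif(n_calls, 0.6, 0.95),
          harmonics = pr$repertoire[[1]]$harmonics
        )
      }
    }
    calls <- dplyr::bind_rows(calls)
    calls$call_id <- seq_len(nrow(calls))
    structure(list(calls = calls, truth = dplyr::bind_rows(truth),
                   profiles = profiles, flock_id = flock_id, seed = seed),
              class = "flock_calls")
  })
}

#' Render waveforms for simulated calls
#'
#' Adds a `waveform` list-column to a simulated call table by synthesizing
#' each realized contour with [synthesize_call()] semantics (harmonic stack
#' under the call's contour, additive noise).
#'
#' @param calls The `calls` tibble of a [simulate_flock_calls()] result.
#' @param sample_rate Sampling rate, Hz.
#' @param noise_level Additive white-noise sd.
#' @param seed Integer seed for the noise.
#' @return The input tibble with a `waveform` list-column.
#' @export
synthesize_call_table <- function(calls, sample_rate = 19000,
                                  noise_level = 0.005, seed = 1L) {
  with_seed(seed, {
    calls$waveform <- purrr::pmap(
      list(calls$contour, calls$duration, calls$amplitude, calls$harmonics),
      function(contour, duration, amplitude, harmonics) {
        p <- call_prototype(pmin(contour, floor(sample_rate / 2 / harmonics) - 1),
                            duration, amplitude, harmonics)
        synthesize_call(p, sample_rate, noise_level = noise_level)
      })
    calls
  })
}

#' Render simulated sessions as WAV files with ground-truth selection tables
#'
#' Assembles each bird x block x session into one mono WAV: a short lead-in,
#' then the session's calls separated by exponentially distributed silent
#' gaps. Ground-truth call positions are written as Raven-style selection
#' tables that tile the rendered sample positions exactly.
#'
#' @param fc A [simulate_flock_calls()] result.
#' @param dir Output directory (created if needed).
#' @param sample_rate Output sampling rate, Hz.
#' @param noise_level Background white-noise sd added to the whole session.
#' @param gap_mean Mean silent gap between calls, s.
#' @param seed Integer seed.
#' @return Manifest tibble: individual, block, session, `wav` and
#'   `selections` paths, `n_calls`.
#' @export
render_sessions <- function(fc, dir, sample_rate = 44100, noise_level = 0.003,
                            gap_mean = 0.35, seed = 1L) {
  stopifnot(inherits(fc, "flock_calls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, {
    groups <- dplyr::group_split(dplyr::group_by(fc$calls, .data$individual,
                                                 .data$block, .data$session))
    manifest <- purrr::map(groups, function(g) {
      waves <- purrr::pmap(
        list(g$contour, g$duration, g$amplitude, g$harmonics),
        function(contour, duration, amplitude, harmonics) {
          p <- call_prototype(pmin(contour, floor(sample_rate / 2 / harmonics) - 1),
                              duration, amplitude, harmonics)
          synthesize_call(p, sample_rate)
        })
      gaps <- round((0.25 + rexp(length(waves), 1 / gap_mean)) * sample_rate)
      starts <- cumsum(gaps) + c(0, cumsum(lengths(waves)))[seq_along(waves)]
      total <- starts[length(starts)] + length(waves[[length(waves)]]) +
        round(0.25 * sample_rate)
      session_wave <- rnorm(total, 0, noise_level)
      for (i in seq_along(waves)) {
        idx <- starts[i] + seq_along(waves[[i]])
        session_wave[idx] <- session_wave[idx] + waves[[i]]
      }
      stem <- sprintf("%s_block%d_session%d", g$individual[1], g$block[1],
                      g$session[1])
      wav_path <- file.path(dir, paste0(stem, ".wav"))
      sel_path <- file.path(dir, paste0(stem, "_selections.txt"))
      write_wav(session_wave, sample_rate, wav_path)
      sel <- tibble(
        start = starts / sample_rate,
        end = (starts + lengths(waves)) / sample_rate,
        low_freq = vapply(g$contour, min, numeric(1)),
        high_freq = vapply(g$contour, max, numeric(1)),
        label = "signal",
        individual = g$individual, flock = g$flock,
        age_class = g$age_class, block = g$block, session = g$session,
        call_id = g$call_id
      )
      write_selection_table(sel, sel_path)
      tibble(individual = g$individual[1], flock = g$flock[1],
             age_class = g$age_class[1], block = g$block[1],
             session = g$session[1], wav = wav_path, selections = sel_path,
             n_calls = nrow(g))
    })
    dplyr::bind_rows(manifest)
  })
}

#' Simulate dyadic social interactions for one flock
#'
#' Draws per-dyad, per-session affiliative and agonistic interaction counts
#' from a negative-binomial distribution (matching the overdispersed count
#' models fitted downstream) and expands them into an event log with random
#' actor/receiver orientation.
#'
#' @param birds Character vector of bird ids (>= 2, typically 4).
#' @param rates List with elements `affiliative` and `agonistic`: expected
#'   counts per dyad per session, each a scalar or one value per dyad
#'   (dyads in `combn(birds, 2)` order).
#' @param sessions Number of observation sessions.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param seed Integer seed.
#' @param flock_id Flock label stored in the output.
#' @return Event-log tibble: flock, session, actor, receiver,
#'   type (`affiliative` / `agonistic`).
#' @export
simulate_interactions <- function(birds, rates, sessions = 8L, dispersion = 2,
                                  seed = 1L, flock_id = "f1") {
  stopifnot(length(birds) >= 2, sessions >= 1,
            all(unlist(rates) >= 0))
  dyads <- utils::combn(birds, 2)
  n_dyads <- ncol(dyads)
  expand_rate <- function(r) {
    if (length(r) == 1) rep(r, n_dyads)
    else { stopifnot(length(r) == n_dyads); r }
  }
  with_seed(seed, {
    out <- purrr::map(c("affiliative", "agonistic"), function(type) {
      mu <- expand_rate(rates[[type]])
      grid <- tidyr::expand_grid(dyad = seq_len(n_dyads),
                                 session = seq_len(sessions))
      counts <- rnbinom(nrow(grid), mu = mu[grid$dyad], size = dispersion)
      keep <- counts > 0
      if (!any(keep)) return(NULL)
      rows <- grid[rep(which(keep), counts[keep]), ]
      flip <- runif(nrow(rows)) < 0.5
      tibble(flock = flock_id, session = rows$session,
             actor = ifelse(flip, dyads[1, rows$dyad], dyads[2, rows$dyad]),
             receiver = ifelse(flip, dyads[2, rows$dyad], dyads[1, rows$dyad]),
             type = type)
    })
    events <- dplyr::bind_rows(out)
    if (nrow(events) > 0)
      events <- dplyr::arrange(events, .data$session, .data$type)
    events
  })
}

#' Simulate proximity snapshots for one flock
#'
#' Emulates the snapshot protocol: at each snapshot every dyad's
#' inter-individual distance is recorded, unless either bird is out of the
#' measurable plane (absent), in which case the distance is missing. A dyad
#' is in close proximity (<= 10 cm) with probability `affinity`.
#'
#' @param birds Character vector of bird ids.
#' @param affinity Probability of close proximity per dyad per snapshot;
#'   scalar or one value per dyad (`combn` order).
#' @param snapshots Number of snapshots (the study design yields 88 per
#'   flock: 11 per session x 8 sessions).
#' @param absence_prob Per-bird, per-snapshot probability of being
#'   unmeasurable.
#' @param seed Integer seed.
#' @param flock_id Flock label.
#' @return Tibble: flock, snapshot, bird_a, bird_b, distance_cm (NA when
#'   missing).
#' @export
simulate_proximity <- function(birds, affinity, snapshots = 88L,
                               absence_prob = 0.15, seed = 1L,
                               flock_id = "f1") {
  stopifnot(all(affinity >= 0 & affinity <= 1),
            absence_prob >= 0, absence_prob <= 1)
  dyads <- utils::combn(birds, 2)
  n_dyads <- ncol(dyads)
  aff <- if (length(affinity) == 1) rep(affinity, n_dyads) else affinity
  stopifnot(length(aff) == n_dyads)
  with_seed(seed, {
    absent <- matrix(runif(snapshots * length(birds)) < absence_prob,
                     snapshots, length(birds), dimnames = list(NULL, birds))
    grid <- tidyr::expand_grid(snapshot = seq_len(snapshots),
                               dyad = seq_len(n_dyads))
    close <- runif(nrow(grid)) < aff[grid$dyad]
    dist <- ifelse(close, runif(nrow(grid), 1, 10), runif(nrow(grid), 10.5, 60))
    a <- dyads[1, grid$dyad]; b <- dyads[2, grid$dyad]
    miss <- absent[cbind(grid$snapshot, match(a, birds))] |
      absent[cbind(grid$snapshot, match(b, birds))]
    tibble(flock = flock_id, snapshot = grid$snapshot, bird_a = a, bird_b = b,
           distance_cm = ifelse(miss, NA_real_, dist))
  })
}

#' Simulate a full flock experiment
#'
#' Generates the complete synthetic analogue of the study design: same-age
#' flocks of four previously unfamiliar birds, contact-call recordings over
#' five blocks (block 1 pre-flock baseline), interaction event logs and
#' proximity snapshots, with age presets governing call acoustics, repertoire
#' dynamics and interaction rates.
#'
#' @param n_flocks_per_age Replicate flocks per age class (study design: 6).
#' @param blocks Recording blocks (study design: 5).
#' @param sessions_per_block Audio sessions per block (study design: 4).
#' @param video_sessions Interaction observation sessions (study design: 8).
#' @param snapshots Proximity snapshots per flock (study design: 88).
#' @param calls_per_session Optional override of preset call rates (use a
#'   small value for quick simulations).
#' @param proximity_affinity Named list with `young` and `old` close-proximity
#'   probabilities.
#' @param seed Master integer seed.
#' @return Object of class `flock_experiment`: `flocks` (tibble flock x
#'   age_class), `calls` (combined call tibble), `truth` (contour-distance
#'   tibble), `events`, `snapshots`, `profiles`.
#' @export
simulate_experiment <- function(n_flocks_per_age = 6L, blocks = 5L,
                                sessions_per_block = 4L, video_sessions = 8L,
                                snapshots = 88L, calls_per_session = NULL,
                                proximity_affinity = list(young = 0.35,
                                                          old = 0.30),
                                seed = 1L) {
  flocks <- tidyr::expand_grid(age_class = c("young", "old"),
                               rep = seq_len(n_flocks_per_age))
  flocks$flock <- sprintf("%s%d", ifelse(flocks$age_class == "young", "Y", "O"),
                          flocks$rep)
  pieces <- purrr::map(seq_len(nrow(flocks)), function(i) {
    age <- flocks$age_class[i]; fid <- flocks$flock[i]
    preset <- age_preset(age)
    profs <- with_seed(stage_seed(seed, paste0("profiles_", fid)),
                       flock_profiles(fid, age, preset))
    fc <- simulate_flock_calls(profs, blocks = blocks,
                               sessions_per_block = sessions_per_block,
                               seed = stage_seed(seed, paste0("calls_", fid)),
                               flock_id = fid,
                               calls_per_session = calls_per_session)
    birds <- vapply(profs, `[[`, character(1), "individual_id")
    events <- simulate_interactions(
      birds,
      rates = list(affiliative = preset$affiliative_rate / 6,
                   agonistic = preset$agonistic_rate / 6),
      sessions = video_sessions, dispersion = preset$interaction_dispersion,
      seed = stage_seed(seed, paste0("events_", fid)), flock_id = fid)
    snaps <- simulate_proximity(
      birds, affinity = proximity_affinity[[age]], snapshots = snapshots,
      seed = stage_seed(seed, paste0("prox_", fid)), flock_id = fid)
    list(fc = fc, events = events, snapshots = snaps, birds = birds)
  })
  flocks$birds <- purrr::map(pieces, "birds")
  structure(
    list(flocks = flocks[c("flock", "age_class", "birds")],
         calls = dplyr::bind_rows(purrr::map(pieces, ~ .x$fc$calls)),
         truth = dplyr::bind_rows(purrr::map(pieces, function(p) {
           dplyr::mutate(p$fc$truth, flock = p$fc$flock_id)
         })),
         events = dplyr::bind_rows(purrr::map(pieces, "events")),
         snapshots = dplyr::bind_rows(purrr::map(pieces, "snapshots")),
         profiles = purrr::map(pieces, ~ .x$fc$profiles),
         seed = seed),
    class = "flock_experiment"
  )
}

#' Summarize interaction totals by age class
#'
#' Recomputes the standard cohort summary of social activity: total
#' affiliative and agonistic interaction counts per age class, their
#' percentage shares, and per-flock means with standard errors.
#'
#' @param events Event-log tibble (flock, type at minimum).
#' @param flock_ages Tibble mapping `flock` to `age_class` (flocks with no
#'   events still enter the per-flock means as zeros).
#' @return Tibble with one row per age class: totals, percentage shares,
#'   per-flock means and standard errors, and the overall total.
#' @export
summarize_interactions <- function(events, flock_ages) {
  stopifnot(all(c("flock", "type") %in% names(events)),
            all(c("flock", "age_class") %in% names(flock_ages)))
  if (!all(events$type %in% c("affiliative", "agonistic")))
    stop("unknown interaction type(s): ",
         paste(setdiff(unique(events$type), c("affiliative", "agonistic")),
               collapse = ", "))
  per_flock <- tidyr::expand_grid(flock = flock_ages$flock,
                                  type = c("affiliative", "agonistic")) %>%
    dplyr::left_join(dplyr::count(events, .data$flock, .data$type),
                     by = c("flock", "type")) %>%
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) %>%
    dplyr::left_join(flock_ages[c("flock", "age_class")], by = "flock")
  se <- function(x) sd(x) / sqrt(length(x))
  per_flock %>%
    dplyr::group_by(.data$age_class, .data$type) %>%
    dplyr::summarise(total = sum(.data$n), per_flock_mean = mean(.data$n),
                     per_flock_se = se(.data$n), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "type",
                       values_from = c("total", "per_flock_mean",
                                       "per_flock_se")) %>%
    dplyr::mutate(
      grand_total = .data$total_affiliative + .data$total_agonistic,
      affiliative_pct = 100 * .data$total_affiliative / .data$grand_total,
      agonistic_pct = 100 * .data$total_agonistic / .data$grand_total
    )
}
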