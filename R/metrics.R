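#' Build all per-individual and pooled-flockmate acoustic spaces
#'
#' From a jointly embedded call table, estimates one [kde_space()] per
#' (individual, block) and, for each individual and block, one pooled space
#' from the concatenated calls of its flockmates in the same block — all on
#' one shared [space_grid()]. Subsets with fewer than `min_calls` calls are
#' skipped and listed in `skipped`.
#'
#' @param emb Embedded call table (see [embed_features()]) with
#'   `individual`, `flock`, `block`, `dim1`, `dim2` columns.
#' @param hdr_level HDR probability mass.
#' @param grid_resolution Cells per grid axis.
#' @param min_calls Minimum calls per subset.
#' @return Object of class `acoustic_spaces`: `grid`, `individual` (nested
#'   list `[[individual]][[block]]`), `pooled` (same shape; flockmates'
#'   calls), `index` (tibble of individual, flock, age_class, block, n,
#'   area), `skipped`.
#' @export
build_acoustic_spaces <- function(emb, hdr_level = 0.95,
                                  grid_resolution = 200L, min_calls = 5L) {
  need <- c("individual", "flock", "block", "dim1", "dim2")
  stopifnot(all(need %in% names(emb)))
  grid <- space_grid(emb, resolution = grid_resolution)
  index <- dplyr::distinct(emb, .data$individual, .data$flock,
                           age_class = if ("age_class" %in% names(emb))
                             .data$age_class else NA_character_)
  blocks <- sort(unique(emb$block))
  spaces <- list(); pooled <- list(); skipped <- list(); rows <- list()
  for (i in seq_len(nrow(index))) {
    ind <- index$individual[i]; fl <- index$flock[i]
    spaces[[ind]] <- list(); pooled[[ind]] <- list()
    for (b in blocks) {
      own <- emb[emb$individual == ind & emb$block == b, ]
      mates <- emb[emb$flock == fl & emb$individual != ind &
                     emb$block == b, ]
      if (nrow(own) >= min_calls) {
        spaces[[ind]][[as.character(b)]] <-
          kde_space(own, grid = grid, hdr_level = hdr_level,
                    key = c(ind, b))
        rows[[length(rows) + 1L]] <- tibble(
          individual = ind, flock = fl, age_class = index$age_class[i],
          block = b, n = nrow(own),
          area = spaces[[ind]][[as.character(b)]]$area)
      } else {
        skipped[[length(skipped) + 1L]] <-
          tibble(individual = ind, block = b, n = nrow(own),
                 subset = "individual")
      }
      if (nrow(mates) >= min_calls) {
        pooled[[ind]][[as.character(b)]] <-
          kde_space(mates, grid = grid, hdr_level = hdr_level,
                    key = c(paste0("flockmates_of_", ind), b))
      } else {
        skipped[[length(skipped) + 1L]] <-
          tibble(individual = ind, block = b, n = nrow(mates),
                 subset = "pooled_flockmates")
      }
    }
  }
  structure(list(grid = grid, individual = spaces, pooled = pooled,
                 index = dplyr::bind_rows(rows),
                 skipped = dplyr::bind_rows(skipped),
                 hdr_level = hdr_level),
            class = "acoustic_spaces")
}

#' Count calls per individual and block (vocal output)
#'
#' @param calls Call or selection table with `individual` and `block`
#'   columns.
#' @param index Optional tibble of the full individual x block universe
#'   (individuals with no calls in a block then appear with count 0);
#'   defaults to the cross product of observed individuals and blocks.
#' @return Tibble: individual, block, `vocal_output`.
#' @export
vocal_output <- function(calls, index = NULL) {
  if (is.null(index)) {
    index <- tidyr::expand_grid(
      individual = unique(calls$individual),
      block = if (nrow(calls) > 0) sort(unique(calls$block)) else integer(0))
  }
  index %>%
    dplyr::left_join(dplyr::count(calls, .data$individual, .data$block,
                                  name = "vocal_output"),
                     by = c("individual", "block")) %>%
    dplyr::mutate(vocal_output = dplyr::coalesce(.data$vocal_output, 0L))
}

block1_space <- function(spaces, ind) {
  s <- spaces$individual[[ind]][["1"]]
  if (is.null(s))
    stop("no block-1 (baseline) space for individual ", ind)
  s
}

empty_metric <- function(name) {
  out <- tibble(individual = character(0), block = numeric(0))
  out[[name]] <- numeric(0)
  out
}

has_baseline <- function(spaces, inds, require_baseline) {
  if (require_baseline) return(inds)
  inds[vapply(inds, function(i) !is.null(spaces$individual[[i]][["1"]]),
              logical(1))]
}

#' Change in vocal diversity relative to baseline
#'
#' For each individual, the HDR area of each post-flock block minus the
#' area of its block-1 (pre-flock baseline) space. Positive values mean a
#' more diverse repertoire than at baseline.
#'
#' @param spaces An [build_acoustic_spaces()] object.
#' @param require_baseline If `TRUE` (default), an individual without a
#'   block-1 space is an error; if `FALSE` such individuals are skipped
#'   (used by [vocal_metrics()], which reports them as missing).
#' @return Tibble: individual, block (>= 2), `diversity_change`
#'   (embedding-units^2).
#' @export
diversity_change <- function(spaces, require_baseline = TRUE) {
  stopifnot(inherits(spaces, "acoustic_spaces"))
  inds <- has_baseline(spaces, names(spaces$individual), require_baseline)
  purrr::map_dfr(inds, function(ind) {
    base <- block1_space(spaces, ind)
    blocks <- setdiff(names(spaces$individual[[ind]]), "1")
    purrr::map_dfr(blocks, function(b) tibble(
      individual = ind, block = as.numeric(b),
      diversity_change = spaces$individual[[ind]][[b]]$area - base$area))
  }) %>% (function(out) if (nrow(out) == 0)
    empty_metric("diversity_change") else out)
}

#' Vocal plasticity: similarity to the starting self
#'
#' The pairwise mean overlap between an individual's space in each
#' post-flock block and its block-1 baseline space. Values are similarities:
#' lower overlap with the starting self indicates greater plasticity.
#'
#' @param spaces An [build_acoustic_spaces()] object.
#' @inheritParams diversity_change
#' @return Tibble: individual, block (>= 2), `plasticity` in \[0, 1\].
#' @export
plasticity <- function(spaces, require_baseline = TRUE) {
  stopifnot(inherits(spaces, "acoustic_spaces"))
  inds <- has_baseline(spaces, names(spaces$individual), require_baseline)
  purrr::map_dfr(inds, function(ind) {
    base <- block1_space(spaces, ind)
    blocks <- setdiff(names(spaces$individual[[ind]]), "1")
    purrr::map_dfr(blocks, function(b) tibble(
      individual = ind, block = as.numeric(b),
      plasticity = mean_overlap(spaces$individual[[ind]][[b]],
                                base)$mean_overlap))
  }) %>% (function(out) if (nrow(out) == 0) empty_metric("plasticity") else out)
}

#' Vocal convergence: similarity to flockmates
#'
#' The pairwise mean overlap between an individual's space and the combined
#' (pooled) space of its three flockmates in the same block. Block 1
#' precedes flock formation, so its value (computed when available) is
#' flagged `pre_exposure`.
#'
#' @param spaces An [build_acoustic_spaces()] object.
#' @return Tibble: individual, block, `convergence` in \[0, 1\],
#'   `pre_exposure`.
#' @export
convergence <- function(spaces) {
  stopifnot(inherits(spaces, "acoustic_spaces"))
  purrr::map_dfr(names(spaces$individual), function(ind) {
    blocks <- intersect(names(spaces$individual[[ind]]),
                        names(spaces$pooled[[ind]]))
    purrr::map_dfr(blocks, function(b) tibble(
      individual = ind, block = as.numeric(b),
      convergence = mean_overlap(spaces$individual[[ind]][[b]],
                                 spaces$pooled[[ind]][[b]])$mean_overlap,
      pre_exposure = as.numeric(b) == 1))
  }) %>% (function(out) if (nrow(out) == 0)
    dplyr::mutate(empty_metric("convergence"), pre_exposure = logical(0))
    else out)
}

#' Assemble the per-individual, per-block vocal metrics table
#'
#' Runs [vocal_output()], [diversity_change()], [plasticity()] and
#' [convergence()] and joins them into one tidy table, the input to the
#' vocal model battery.
#'
#' @param emb Embedded call table (joint embedding of all calls).
#' @param hdr_level,grid_resolution,min_calls Passed to
#'   [build_acoustic_spaces()].
#' @param spaces Optionally, a prebuilt [build_acoustic_spaces()] object.
#' @return Tibble: individual, flock, age_class, block, `vocal_output`,
#'   `area`, `diversity_change`, `plasticity`, `convergence` (the overlap
#'   measures are `NA` at block 1).
#' @export
vocal_metrics <- function(emb, hdr_level = 0.95, grid_resolution = 200L,
                          min_calls = 5L, spaces = NULL) {
  spaces <- spaces %||% build_acoustic_spaces(emb, hdr_level = hdr_level,
                                              grid_resolution = grid_resolution,
                                              min_calls = min_calls)
  out <- vocal_output(emb) %>%
    dplyr::left_join(dplyr::distinct(emb, .data$individual, .data$flock,
                                     .data$age_class),
                     by = "individual") %>%
    dplyr::left_join(spaces$index[c("individual", "block", "area")],
                     by = c("individual", "block")) %>%
    dplyr::left_join(diversity_change(spaces, require_baseline = FALSE),
                     by = c("individual", "block")) %>%
    dplyr::left_join(plasticity(spaces, require_baseline = FALSE),
                     by = c("individual", "block")) %>%
    dplyr::left_join(
      dplyr::select(convergence(spaces), -"pre_exposure"),
      by = c("individual", "block"))
  dplyr::relocate(out, "individual", "flock", "age_class", "block")
}
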