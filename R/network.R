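new_social_network <- function(adjacency, flock, dimension, birds) {
  stopifnot(isSymmetric(unname(adjacency)), all(diag(adjacency) == 0),
            all(adjacency >= 0))
  structure(list(adjacency = adjacency, flock = flock,
                 dimension = dimension, birds = birds),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network %s/%s: density %.3f>\n", x$flock, x$dimension,
              network_density(x)))
  print(round(x$adjacency, 3))
  invisible(x)
}

#' Build a proximity network from snapshot distances
#'
#' Edge weights are the proportion of valid (non-missing) snapshots in which
#' a dyad was in close proximity — at or under `threshold_cm` apart
#' (the threshold is inclusive; 10 cm is one budgerigar body length).
#' Snapshots where either bird was unmeasurable do not enter the
#' denominator; a dyad with no valid snapshots gets weight 0 with a warning.
#'
#' @param snapshots Tibble with `bird_a`, `bird_b`, `distance_cm` (NA =
#'   missing) and optionally `flock`.
#' @param birds Roster of bird ids; defaults to those present. Snapshot rows
#'   naming unknown birds are an error.
#' @param threshold_cm Close-proximity threshold, cm (inclusive).
#' @param flock Flock label; defaults to the one in the data.
#' @return A `social_network` (symmetric weighted adjacency, weights in
#'   \[0, 1\]).
#' @export
proximity_edges <- function(snapshots, birds = NULL, threshold_cm = 10,
                            flock = NULL) {
  seen <- union(snapshots$bird_a, snapshots$bird_b)
  birds <- birds %||% sort(seen)
  unknown <- setdiff(seen, birds)
  if (length(unknown) > 0)
    stop("unknown bird id(s) in snapshots: ", paste(unknown, collapse = ", "))
  adj <- matrix(0, length(birds), length(birds),
                dimnames = list(birds, birds))
  dyads <- utils::combn(birds, 2)
  for (k in seq_len(ncol(dyads))) {
    a <- dyads[1, k]; b <- dyads[2, k]
    d <- snapshots$distance_cm[(snapshots$bird_a == a & snapshots$bird_b == b) |
                                 (snapshots$bird_a == b & snapshots$bird_b == a)]
    valid <- d[!is.na(d)]
    if (length(valid) == 0) {
      warning("dyad ", a, "-", b, " has no valid snapshots; weight set to 0")
      w <- 0
    } else w <- sum(valid <= threshold_cm) / length(valid)
    adj[a, b] <- w; adj[b, a] <- w
  }
  new_social_network(adj, flock %||% snapshots$flock[1] %||% "flock",
                     "proximity", birds)
}

#' Build an affiliation or agonism network from an event log
#'
#' Counts interactions per dyad, collapsing actor/receiver direction.
#' Optionally restricts to the first (blocks 1-2) or second (blocks 3-4)
#' half of the observation period, with video sessions mapped to blocks in
#' consecutive pairs.
#'
#' @param events Event log with `actor`, `receiver`, `type` and optionally
#'   `session`, `flock`.
#' @param dimension `"affiliation"` or `"agonism"`.
#' @param birds Roster of bird ids; defaults to those present in the events.
#' @param period `"all"`, `"first_half"` or `"second_half"`.
#' @param sessions_per_block Video sessions per recording block (study
#'   design: 2).
#' @param flock Flock label.
#' @return A `social_network` with integer count weights.
#' @export
interaction_edges <- function(events, dimension = c("affiliation", "agonism"),
                              birds = NULL,
                              period = c("all", "first_half", "second_half"),
                              sessions_per_block = 2L, flock = NULL) {
  dimension <- match.arg(dimension)
  period <- match.arg(period)
  bad <- setdiff(unique(events$type), c("affiliative", "agonistic"))
  if (length(bad) > 0)
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "))
  if (any(events$actor == events$receiver))
    stop("self-interactions (actor == receiver) are not allowed")
  birds <- birds %||% sort(union(events$actor, events$receiver))
  unknown <- setdiff(union(events$actor, events$receiver), birds)
  if (length(unknown) > 0)
    stop("unknown bird id(s) in events: ", paste(unknown, collapse = ", "))
  type_wanted <- c(affiliation = "affiliative", agonism = "agonistic")[dimension]
  ev <- events[events$type == type_wanted, , drop = FALSE]
  if (period != "all") {
    stopifnot("session" %in% names(ev))
    block <- ceiling(ev$session / sessions_per_block)
    ev <- ev[if (period == "first_half") block <= 2 else block >= 3, ,
             drop = FALSE]
  }
  adj <- matrix(0, length(birds), length(birds),
                dimnames = list(birds, birds))
  if (nrow(ev) > 0) {
    tab <- table(factor(pmin(ev$actor, ev$receiver), levels = birds),
                 factor(pmax(ev$actor, ev$receiver), levels = birds))
    adj <- unclass(tab) + t(unclass(tab))
    dimnames(adj) <- list(birds, birds)
  }
  new_social_network(adj, flock %||% events$flock[1] %||% "flock",
                     dimension, birds)
}

#' Network density
#'
#' The number of dyads with a nonzero edge divided by the number of possible
#' dyads (6 in a 4-bird flock). A group-level measure of connectedness.
#'
#' @param net A `social_network`.
#' @return A proportion in \[0, 1\].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "social_network"))
  w <- net$adjacency[upper.tri(net$adjacency)]
  sum(w > 0) / length(w)
}

#' Node strength (weighted degree)
#'
#' The sum of edge weights incident to each bird: an individual-level
#' measure of gregariousness.
#'
#' @param net A `social_network`.
#' @return Named numeric vector, one value per bird.
#' @export
node_strength <- function(net) {
  stopifnot(inherits(net, "social_network"))
  rowSums(net$adjacency)
}

#' Compute network metrics for a whole experiment
#'
#' Builds the three networks (proximity, affiliation, agonism) for every
#' flock and returns tidy density and strength tables ready for the social
#' model battery.
#'
#' @param events Combined event log (column `flock` required).
#' @param snapshots Combined proximity snapshots (column `flock` required).
#' @param flocks Tibble with `flock`, `age_class` and a `birds` list-column
#'   (as produced by [simulate_experiment()]).
#' @param period Passed to [interaction_edges()].
#' @return List of tibbles: `density` (flock, age_class, dimension,
#'   n_edges, n_possible, density) and `strength` (flock, age_class,
#'   dimension, individual, strength), plus `networks` (named list of
#'   `social_network` objects).
#' @export
network_metrics <- function(events, snapshots, flocks, period = "all") {
  nets <- list()
  rows_d <- list(); rows_s <- list()
  for (i in seq_len(nrow(flocks))) {
    fid <- flocks$flock[i]; age <- flocks$age_class[i]
    birds <- flocks$birds[[i]]
    ev <- events[events$flock == fid, , drop = FALSE]
    sn <- snapshots[snapshots$flock == fid, , drop = FALSE]
    for (dim in c("proximity", "affiliation", "agonism")) {
      net <- if (dim == "proximity")
        proximity_edges(sn, birds = birds, flock = fid)
      else interaction_edges(ev, dimension = dim, birds = birds,
                             period = period, flock = fid)
      nets[[paste(fid, dim, sep = "_")]] <- net
      w <- net$adjacency[upper.tri(net$adjacency)]
      rows_d[[length(rows_d) + 1L]] <- tibble(
        flock = fid, age_class = age, dimension = dim,
        n_edges = sum(w > 0), n_possible = length(w),
        density = network_density(net))
      rows_s[[length(rows_s) + 1L]] <- tibble(
        flock = fid, age_class = age, dimension = dim,
        individual = birds, strength = unname(node_strength(net)[birds]))
    }
  }
  list(density = dplyr::bind_rows(rows_d),
       strength = dplyr::bind_rows(rows_s), networks = nets)
}
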