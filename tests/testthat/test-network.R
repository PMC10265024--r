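birds4 <- paste0("b", 1:4)

test_that("proximity weights use valid snapshots only, with an inclusive threshold", {
  snaps <- tibble::tibble(
    flock = "f1", snapshot = 1:11, bird_a = "b1", bird_b = "b2",
    distance_cm = c(5, 8, 10.0, 9, 30, 40, 50, 60, 20, 15, NA))
  other <- tidyr::expand_grid(snapshot = 1:11,
                              dyad = c("b1-b3", "b1-b4", "b2-b3", "b2-b4",
                                       "b3-b4"))
  other <- tibble::tibble(flock = "f1", snapshot = other$snapshot,
                          bird_a = sub("-.*", "", other$dyad),
                          bird_b = sub(".*-", "", other$dyad),
                          distance_cm = 30)
  net <- proximity_edges(dplyr::bind_rows(snaps, other), birds = birds4)
  # 4 close of 10 valid (10.0 cm inclusive, NA excluded)
  expect_equal(net$adjacency["b1", "b2"], 0.4)
  expect_equal(net$adjacency["b2", "b1"], 0.4)
  expect_true(all(diag(net$adjacency) == 0))
})

test_that("a dyad with no valid snapshots warns and gets weight zero", {
  grid <- tidyr::expand_grid(snapshot = 1:2,
                             dyad = utils::combn(birds4, 2, paste,
                                                 collapse = "-"))
  snaps <- tibble::tibble(flock = "f1", snapshot = grid$snapshot,
                          bird_a = sub("-.*", "", grid$dyad),
                          bird_b = sub(".*-", "", grid$dyad),
                          distance_cm = ifelse(grid$dyad == "b1-b2", NA, 20))
  expect_warning(net <- proximity_edges(snaps, birds = birds4),
                 "b1-b2 has no valid snapshots")
  expect_equal(net$adjacency["b1", "b2"], 0)
})

test_that("unknown bird ids and interaction types are rejected", {
  snaps <- tibble::tibble(flock = "f1", snapshot = 1, bird_a = "intruder",
                          bird_b = "b1", distance_cm = 5)
  expect_error(proximity_edges(snaps, birds = birds4), "intruder")
  ev <- tibble::tibble(flock = "f1", session = 1, actor = "b1",
                       receiver = "b2", type = "grooming")
  expect_error(interaction_edges(ev, "affiliation"), "grooming")
  self_ev <- tibble::tibble(flock = "f1", session = 1, actor = "b1",
                            receiver = "b1", type = "affiliative")
  expect_error(interaction_edges(self_ev, "affiliation"), "actor == receiver")
})

test_that("interaction edges collapse direction and honour the period split", {
  ev <- tibble::tibble(
    flock = "f1",
    session = c(1, 1, 2, 7, 8),
    actor = c("b1", "b2", "b1", "b3", "b4"),
    receiver = c("b2", "b1", "b2", "b4", "b3"),
    type = c("affiliative", "affiliative", "affiliative", "affiliative",
             "agonistic"))
  net <- interaction_edges(ev, "affiliation", birds = birds4)
  expect_equal(net$adjacency["b1", "b2"], 3)
  expect_equal(net$adjacency["b3", "b4"], 1)
  first <- interaction_edges(ev, "affiliation", birds = birds4,
                             period = "first_half")
  expect_equal(first$adjacency["b3", "b4"], 0)
  second <- interaction_edges(ev, "affiliation", birds = birds4,
                              period = "second_half")
  expect_equal(second$adjacency["b1", "b2"], 0)
  expect_equal(second$adjacency["b3", "b4"], 1)
  ago <- interaction_edges(ev, "agonism", birds = birds4)
  expect_equal(sum(ago$adjacency), 2)  # one event counted on both triangles
  empty <- interaction_edges(ev[0, ], "affiliation", birds = birds4)
  expect_true(all(empty$adjacency == 0))
  expect_equal(network_density(empty), 0)
})

test_that("density and strength match brute-force enumeration on random matrices", {
  with_seed(31, {
    for (i in 1:100) {
      m <- matrix(0, 4, 4, dimnames = list(birds4, birds4))
      w <- rbinom(6, 1, 0.6) * round(runif(6, 0.5, 9))
      m[upper.tri(m)] <- w
      m <- m + t(m)
      net <- vocalflock:::new_social_network(m, "f", "affiliation", birds4)
      # brute force over all 6 dyads
      dens_bf <- 0; strength_bf <- setNames(numeric(4), birds4)
      for (a in 1:3) for (b in (a + 1):4) {
        if (m[a, b] > 0) dens_bf <- dens_bf + 1
        strength_bf[a] <- strength_bf[a] + m[a, b]
        strength_bf[b] <- strength_bf[b] + m[a, b]
      }
      expect_identical(network_density(net), dens_bf / 6)
      expect_identical(node_strength(net), strength_bf)
      # handshake identity
      expect_equal(sum(node_strength(net)), 2 * sum(m[upper.tri(m)]))
    }
  })
})

test_that("density and strength agree with igraph on a weighted graph", {
  skip_if_not_installed("igraph")
  m <- matrix(c(0, 2, 0, 1,
                2, 0, 3, 0,
                0, 3, 0, 0,
                1, 0, 0, 0), 4, dimnames = list(birds4, birds4))
  net <- vocalflock:::new_social_network(m, "f", "affiliation", birds4)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(network_density(net), igraph::edge_density(g))
  expect_equal(unname(node_strength(net)), unname(igraph::strength(g)))
})

test_that("network metrics tables cover every flock and dimension", {
  ex <- simulate_experiment(n_flocks_per_age = 2, blocks = 2,
                            sessions_per_block = 1, calls_per_session = 1,
                            snapshots = 22, seed = 5)
  nm <- network_metrics(ex$events, ex$snapshots, ex$flocks)
  expect_equal(nrow(nm$density), 4 * 3)
  expect_equal(nrow(nm$strength), 4 * 3 * 4)
  expect_true(all(nm$density$density >= 0 & nm$density$density <= 1))
  prox <- nm$strength$strength[nm$strength$dimension == "proximity"]
  expect_true(all(prox >= 0 & prox <= 3))  # at most 3 dyads of proportion 1
})
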