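# Build a one-flock embedded call table from per-(bird, block) 2-D samplers.
flock_emb <- function(spec, n = 40, seed = 1) {
  with_seed(seed, purrr::imap_dfr(spec, function(blocks, ind) {
    purrr::imap_dfr(blocks, function(sampler, b) {
      coords_as_emb(sampler(n), ind, as.numeric(b))
    })
  }))
}
gauss <- function(cx, cy, sd = 1) function(n)
  cbind(rnorm(n, cx, sd), rnorm(n, cy, sd))

test_that("vocal output counts calls and zero-fills the full index", {
  calls <- tibble::tibble(individual = c("a", "a", "a", "b"),
                          block = c(2, 2, 2, 1))
  out <- vocal_output(calls)
  expect_equal(out$vocal_output[out$individual == "a" & out$block == 2], 3)
  expect_equal(out$vocal_output[out$individual == "b" & out$block == 2], 0)
  idx <- tidyr::expand_grid(individual = c("a", "b"), block = 1:3)
  empty <- vocal_output(calls[0, ], index = idx)
  expect_equal(nrow(empty), 6)
  expect_true(all(empty$vocal_output == 0))
})

test_that("diversity change tracks repertoire spread against baseline", {
  base_pts <- with_seed(2, rbind(cbind(rnorm(20), rnorm(20)),
                                 cbind(rnorm(20, 8), rnorm(20, 8))))
  emb <- dplyr::bind_rows(
    coords_as_emb(base_pts, "a", 1),
    coords_as_emb(base_pts, "a", 2),                      # identical
    coords_as_emb(base_pts * 1.6, "a", 3),                # widened
    coords_as_emb(base_pts[1:20, ], "a", 4))              # pruned cluster
  spaces <- build_acoustic_spaces(emb, grid_resolution = 150)
  dc <- diversity_change(spaces)
  expect_equal(dc$diversity_change[dc$block == 2], 0, tolerance = 1e-9)
  expect_gt(dc$diversity_change[dc$block == 3], 0)
  expect_lt(dc$diversity_change[dc$block == 4], 0)
})

test_that("a missing baseline block is an error naming the individual", {
  emb <- coords_as_emb(with_seed(3, cbind(rnorm(30), rnorm(30))), "nobase", 2)
  spaces <- suppressWarnings(build_acoustic_spaces(emb, grid_resolution = 100))
  expect_error(diversity_change(spaces), "nobase")
})

test_that("plasticity is the similarity to the starting self", {
  spec <- list(
    stable = list(`1` = gauss(0, 0), `2` = gauss(0, 0), `3` = gauss(0, 0)),
    mover = list(`1` = gauss(0, 0), `2` = gauss(6, 0), `3` = gauss(12, 0)))
  emb <- flock_emb(spec, n = 60, seed = 4)
  spaces <- suppressWarnings(build_acoustic_spaces(emb, grid_resolution = 150))
  pl <- plasticity(spaces)
  stable <- pl$plasticity[pl$individual == "stable"]
  mover <- pl$plasticity[pl$individual == "mover"]
  expect_true(all(stable > 0.7))   # same distribution: high self-similarity
  expect_true(all(mover < min(stable)))
  expect_lt(mover[2], 0.01)        # far from baseline by block 3
})

test_that("convergence contrasts shared and disjoint repertoires and ignores labels", {
  shared_flock <- list(
    b1 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)),
    b2 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)),
    b3 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)),
    b4 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)))
  disjoint_flock <- list(
    loner = list(`1` = gauss(40, 40), `2` = gauss(40, 40)),
    c2 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)),
    c3 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)),
    c4 = list(`1` = gauss(0, 0), `2` = gauss(0, 0)))
  emb <- dplyr::bind_rows(
    flock_emb(shared_flock, n = 50, seed = 5),
    dplyr::mutate(flock_emb(disjoint_flock, n = 50, seed = 6), flock = "f2"))
  spaces <- build_acoustic_spaces(emb, grid_resolution = 200)
  cv <- convergence(spaces)
  shared <- cv$convergence[cv$individual == "b1"]
  expect_true(all(shared > 0.6))
  # disjoint starting repertoire: near-zero overlap with flockmates, flat
  expect_true(all(cv$convergence[cv$individual == "loner"] < 0.01))
  expect_true(all(cv$pre_exposure == (cv$block == 1)))
  # relabeling flockmates does not change the focal bird's convergence
  emb_relab <- emb
  emb_relab$individual <- c(b2 = "b3", b3 = "b2", b1 = "b1", b4 = "b4",
                            loner = "loner", c2 = "c2", c3 = "c3",
                            c4 = "c4")[emb$individual]
  cv2 <- convergence(build_acoustic_spaces(emb_relab, grid_resolution = 200))
  expect_equal(cv2$convergence[cv2$individual == "b1"], shared,
               tolerance = 1e-12)
})

test_that("the assembled metrics table has the right shape and NA pattern", {
  spec <- list(
    b1 = list(`1` = gauss(0, 0), `2` = gauss(1, 0)),
    b2 = list(`1` = gauss(0, 1), `2` = gauss(0, 0)),
    b3 = list(`1` = gauss(1, 1), `2` = gauss(0, 1)),
    b4 = list(`1` = gauss(0, 0), `2` = gauss(1, 1)))
  emb <- flock_emb(spec, n = 30, seed = 6)
  vm <- vocal_metrics(emb, grid_resolution = 120)
  expect_equal(nrow(vm), 8)
  expect_true(all(is.na(vm$diversity_change[vm$block == 1])))
  expect_true(all(!is.na(vm$diversity_change[vm$block == 2])))
  expect_true(all(vm$plasticity[vm$block == 2] >= 0 &
                    vm$plasticity[vm$block == 2] <= 1))
  expect_true(all(vm$convergence[vm$block == 2] >= 0 &
                    vm$convergence[vm$block == 2] <= 1))
  expect_true(all(vm$vocal_output == 30))
})
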