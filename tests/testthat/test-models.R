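fit_col <- function(d, response, ...) {
  d[[response]] <- d$y
  fit_vocal_model(d, response, ...)
}

test_that("the gaussian mixed model recovers a planted age effect with t statistics", {
  with_seed(41, {
    est <- vapply(1:30, function(i) {
      d <- sim_metrics(beta_age = 0.5, family = "gaussian")
      td <- tidy(fit_col(d, "diversity_change", include_interaction = FALSE))
      td$estimate[td$term == "age_classyoung"]
    }, numeric(1))
  })
  expect_equal(mean(est), 0.5, tolerance = 0.1)
  d <- with_seed(42, sim_metrics(beta_age = 0.5))
  td <- tidy(fit_col(d, "diversity_change", include_interaction = FALSE))
  expect_true(all(td$statistic_type == "t"))
})

test_that("the negative-binomial model recovers a planted log-scale age ratio", {
  with_seed(43, {
    est <- vapply(1:25, function(i) {
      d <- sim_metrics(beta_age = 0.3, family = "nb", intercept = 3,
                       sd_ind = 0.15, sd_flock = 0.1)
      td <- tidy(fit_col(d, "vocal_output", include_interaction = FALSE))
      td$estimate[td$term == "age_classyoung"]
    }, numeric(1))
  })
  expect_equal(mean(est), 0.3, tolerance = 0.075)
  d <- with_seed(44, sim_metrics(beta_age = 0.3, family = "nb", intercept = 3))
  td <- tidy(fit_col(d, "vocal_output", include_interaction = FALSE))
  expect_true(all(td$statistic_type == "z"))
})

test_that("the beta model recovers a planted logit-scale age effect", {
  with_seed(45, {
    est <- vapply(1:25, function(i) {
      d <- sim_metrics(beta_age = 0.5, family = "beta", sd_ind = 0.15,
                       sd_flock = 0.1)
      td <- tidy(fit_col(d, "plasticity", include_interaction = FALSE))
      td$estimate[td$term == "age_classyoung"]
    }, numeric(1))
  })
  expect_equal(mean(est), 0.5, tolerance = 0.1)
})

test_that("boundary proportions are squeezed into the open interval", {
  y <- c(0, 0.5, 1)
  sq <- squeeze_proportions(y)
  expect_true(all(sq > 0 & sq < 1))
  expect_equal(squeeze_proportions(c(0.2, 0.8)), c(0.2, 0.8))
  d <- with_seed(46, sim_metrics(family = "beta"))
  d$y[1] <- 1  # an exact-1 overlap must not break the beta fit
  fit <- fit_col(d, "convergence", include_interaction = FALSE)
  expect_true(fit$converged)
})

test_that("the interaction-dropping rule keeps real interactions and drops null ones", {
  strong <- with_seed(47, sim_metrics(beta_inter = 1, family = "gaussian"))
  full <- fit_col(strong, "diversity_change")
  kept <- drop_interaction_if_ns(full)
  expect_false(kept$dropped_interaction)
  expect_true(any(grepl(":", tidy(kept)$term)))
  with_seed(48, {
    dropped <- vapply(1:20, function(i) {
      d <- sim_metrics(beta_inter = 0, beta_age = 0.3)
      drop_interaction_if_ns(fit_col(d, "diversity_change"))$dropped_interaction
    }, logical(1))
  })
  expect_gte(mean(dropped), 0.9)
  # alpha = 1 always drops
  d <- with_seed(49, sim_metrics(beta_inter = 1))
  always <- drop_interaction_if_ns(fit_col(d, "diversity_change"), alpha = 1)
  expect_true(always$dropped_interaction)
  expect_false(any(grepl(":", tidy(always)$term)))
})

test_that("the binomial density model detects strong but incomplete separation", {
  dens <- tibble::tibble(
    flock = paste0("f", 1:12),
    age_class = rep(c("young", "old"), each = 6),
    dimension = "affiliation",
    n_edges = c(6, 5, 6, 6, 5, 6, 3, 4, 3, 2, 4, 3),
    n_possible = 6)
  fit <- fit_network_model(dens, "density", "affiliation")
  td <- tidy(fit)
  young <- td[td$term == "age_classyoung", ]
  expect_gt(young$estimate, 0)
  expect_lt(young$p.value, 0.05)
  expect_equal(young$statistic_type, "z")
})

test_that("complete separation in the density model is flagged, not reported", {
  dens <- tibble::tibble(flock = paste0("f", 1:12),
                         age_class = rep(c("young", "old"), each = 6),
                         dimension = "affiliation",
                         n_edges = 6, n_possible = 6)
  fit <- fit_network_model(dens, "density", "affiliation")
  expect_false(fit$converged)
  expect_match(fit$note, "degenerate|separation")
})

test_that("strength models fit their family per dimension", {
  with_seed(50, {
    strength <- tidyr::expand_grid(flock = paste0("f", 1:12), bird = 1:4)
    strength$age_class <- rep(c("young", "old"), each = 24)
    strength$individual <- paste0(strength$flock, "_b", strength$bird)
    young <- strength$age_class == "young"
    aff <- dplyr::mutate(strength, dimension = "affiliation",
                         strength = rnbinom(48, mu = ifelse(young, 20, 8),
                                            size = 5))
    prox <- dplyr::mutate(strength, dimension = "proximity",
                          strength = rgamma(48, shape = 6,
                                            rate = ifelse(young, 4, 6)))
  })
  f_aff <- fit_network_model(aff, "strength", "affiliation")
  td <- tidy(f_aff)
  expect_gt(td$estimate[td$term == "age_classyoung"], 0)
  expect_equal(unique(td$statistic_type), "z")
  # the inverse link can step through invalid mu during optimization
  f_prox <- suppressWarnings(fit_network_model(prox, "strength", "proximity"))
  expect_true(f_prox$converged)
  expect_equal(f_prox$family$link, "inverse")
  gl <- glance(f_prox)
  expect_equal(gl$nobs, 48)
})
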