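#' Family mapping for the model battery
#'
#' Each response has a fixed error family and link: vocal output (counts)
#' uses negative binomial with a log link; vocal diversity change (a real
#' area difference) is gaussian; vocal plasticity and convergence (overlap
#' proportions) use a beta distribution with a logit link; network density
#' (edges out of 6 possible dyads) is binomial with a logit link;
#' affiliative/agonistic strength (summed counts) is negative binomial and
#' proximity strength (a continuous right-skewed proportion sum) is Gamma
#' with an inverse link.
#'
#' @param response One of `vocal_output`, `diversity_change`, `plasticity`,
#'   `convergence`, `density`, `strength_affiliation`, `strength_agonism`,
#'   `strength_proximity`.
#' @return List with `family` (name) and `link`.
#' @export
model_family <- function(response) {
  map <- list(
    vocal_output = list(family = "negative_binomial", link = "log"),
    diversity_change = list(family = "gaussian", link = "identity"),
    plasticity = list(family = "beta", link = "logit"),
    convergence = list(family = "beta", link = "logit"),
    density = list(family = "binomial", link = "logit"),
    strength_affiliation = list(family = "negative_binomial", link = "log"),
    strength_agonism = list(family = "negative_binomial", link = "log"),
    strength_proximity = list(family = "gamma", link = "inverse"))
  if (!response %in% names(map)) stop("unknown response: ", response)
  map[[response]]
}

#' Squeeze proportions off the boundary for beta models
#'
#' The beta distribution has open support (0, 1); observed overlaps can hit
#' the boundary. When any value does, the whole vector is compressed by the
#' standard transform `(y * (n - 1) + 0.5) / n`.
#'
#' @param y Numeric vector of proportions in \[0, 1\].
#' @return Numeric vector strictly inside (0, 1).
#' @export
squeeze_proportions <- function(y) {
  stopifnot(all(y >= 0 & y <= 1, na.rm = TRUE))
  if (any(y <= 0 | y >= 1, na.rm = TRUE)) {
    n <- sum(!is.na(y))
    y <- (y * (n - 1) + 0.5) / n
  }
  y
}

new_model_fit <- function(model, response, family, data, formula,
                          dropped_interaction = FALSE, converged = TRUE,
                          note = NULL) {
  structure(list(model = model, response = response, family = family,
                 data = data, formula = formula,
                 dropped_interaction = dropped_interaction,
                 converged = converged, note = note),
            class = "vlf_fit")
}

fit_engine <- function(formula, data, family_name) {
  mixed <- grepl("\\|", deparse1(formula))
  fit <- try(switch(
    family_name,
    gaussian = if (mixed) lmerTest::lmer(formula, data = data)
               else stats::lm(formula, data = data),
    negative_binomial = glmmTMB::glmmTMB(formula, data = data,
                                         family = glmmTMB::nbinom2()),
    beta = glmmTMB::glmmTMB(formula, data = data,
                            family = glmmTMB::beta_family()),
    gamma = glmmTMB::glmmTMB(formula, data = data,
                             family = stats::Gamma(link = "inverse")),
    binomial = glm(formula, data = data, family = binomial()),
    stop("unknown family: ", family_name)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(model = NULL, converged = FALSE,
                note = attr(fit, "condition")$message))
  conv <- TRUE; note <- NULL
  if (inherits(fit, "glmmTMB")) {
    conv <- isTRUE(fit$fit$convergence == 0) && !fit$sdr$pdHess %in% FALSE
    if (!conv) note <- "glmmTMB did not converge cleanly"
  } else if (inherits(fit, "glm")) {
    if (!fit$converged) { conv <- FALSE; note <- "glm did not converge" }
    mu <- stats::fitted(fit)
    if (all(mu > 1 - 1e-8) || all(mu < 1e-8)) {
      conv <- FALSE
      note <- "degenerate fit: fitted probabilities at the boundary (complete separation)"
    }
  }
  list(model = fit, converged = conv, note = note)
}

#' Fit one vocal-response mixed model
#'
#' Fits the model for one vocal response with adult age, recording block
#' (continuous) and optionally their interaction as fixed effects, and
#' random intercepts for individual identity and flock. The family follows
#' [model_family()]; beta responses are squeezed off the boundary first.
#' Non-convergence is reported in the returned object, not thrown.
#'
#' @param metrics A [vocal_metrics()] table (overlap responses use blocks
#'   >= 2; rows with missing response are dropped).
#' @param response `"vocal_output"`, `"diversity_change"`, `"plasticity"`
#'   or `"convergence"`.
#' @param include_interaction Include the age x block interaction.
#' @return A `vlf_fit` object; see [tidy.vlf_fit()].
#' @export
fit_vocal_model <- function(metrics, response,
                            include_interaction = TRUE) {
  fam <- model_family(response)
  d <- metrics[!is.na(metrics[[response]]), , drop = FALSE]
  d$age_class <- factor(d$age_class, levels = c("old", "young"))
  d$block_c <- as.numeric(d$block)
  d$.y <- d[[response]]
  if (fam$family == "beta") d$.y <- squeeze_proportions(d$.y)
  fixed <- if (include_interaction) ".y ~ age_class * block_c"
           else ".y ~ age_class + block_c"
  f <- as.formula(paste(fixed, "+ (1 | individual) + (1 | flock)"))
  eng <- fit_engine(f, d, fam$family)
  new_model_fit(eng$model, response, fam, d, f,
                dropped_interaction = !include_interaction,
                converged = eng$converged, note = eng$note)
}

#' Drop a nonsignificant age x block interaction
#'
#' If the interaction term's p-value in the full fit is at or above `alpha`
#' the model is refitted without it and the reduced fit returned (flagged
#' `dropped_interaction`); otherwise the full fit is returned unchanged.
#'
#' @param fit A full-model `vlf_fit` containing the interaction.
#' @param alpha Significance threshold.
#' @return A `vlf_fit`.
#' @export
drop_interaction_if_ns <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "vlf_fit"))
  td <- tidy(fit)
  inter <- td[grepl(":", td$term), , drop = FALSE]
  if (nrow(inter) == 0) return(fit)
  # significance means p < alpha; at alpha >= 1 nothing is significant
  if (alpha < 1 && all(inter$p.value < alpha, na.rm = TRUE)) return(fit)
  refit <- if (fit$response %in% c("vocal_output", "diversity_change",
                                   "plasticity", "convergence"))
    fit_vocal_model(fit$data, fit$response, include_interaction = FALSE)
  else stop("interaction dropping applies to the vocal models")
  refit$dropped_interaction <- TRUE
  refit
}

#' Fit one social-network model
#'
#' Density (edges out of the 6 possible dyads per flock) is a binomial GLM
#' on age class. Strength is modelled per bird with age class fixed and
#' flock as a random intercept: negative binomial for the count-based
#' affiliation/agonism dimensions, Gamma (inverse link) for the continuous
#' right-skewed proximity dimension (zero strengths are nudged to half the
#' smallest positive value, as the Gamma support is positive).
#'
#' @param data The `density` or `strength` tibble from [network_metrics()].
#' @param response `"density"` or `"strength"`.
#' @param dimension `"proximity"`, `"affiliation"` or `"agonism"`.
#' @return A `vlf_fit`.
#' @export
fit_network_model <- function(data, response = c("density", "strength"),
                              dimension = c("proximity", "affiliation",
                                            "agonism")) {
  response <- match.arg(response)
  dimension <- match.arg(dimension)
  d <- data[data$dimension == dimension, , drop = FALSE]
  d$age_class <- factor(d$age_class, levels = c("old", "young"))
  if (response == "density") {
    fam <- model_family("density")
    f <- cbind(n_edges, n_possible - n_edges) ~ age_class
    eng <- fit_engine(f, d, "binomial")
    return(new_model_fit(eng$model, paste0("density_", dimension), fam, d, f,
                         converged = eng$converged, note = eng$note))
  }
  key <- paste0("strength_", dimension)
  fam <- model_family(key)
  d$.y <- d$strength
  if (fam$family == "negative_binomial") d$.y <- round(d$.y)
  if (fam$family == "gamma" && any(d$.y <= 0)) {
    pos <- d$.y[d$.y > 0]
    d$.y[d$.y <= 0] <- if (length(pos) > 0) min(pos) / 2 else 1e-3
  }
  f <- .y ~ age_class + (1 | flock)
  eng <- fit_engine(f, d, fam$family)
  new_model_fit(eng$model, key, fam, d, f,
                converged = eng$converged, note = eng$note)
}

#' Fit the full model battery
#'
#' Fits all four vocal models (with the interaction-dropping rule) and the
#' six social-network models, returning a tidy coefficient table in the
#' conventional layout (response, fixed effect, estimate, s.e., critical
#' value, p-value).
#'
#' @param metrics A [vocal_metrics()] table, or NULL to skip vocal models.
#' @param networks A [network_metrics()] list, or NULL to skip.
#' @param alpha Threshold for the interaction-dropping rule.
#' @return List with `fits` (named `vlf_fit` list) and `table` (combined
#'   [tidy.vlf_fit()] rows for the fixed effects).
#' @export
fit_model_battery <- function(metrics = NULL, networks = NULL, alpha = 0.05) {
  fits <- list()
  if (!is.null(metrics)) {
    for (resp in c("vocal_output", "diversity_change", "plasticity",
                   "convergence")) {
      full <- fit_vocal_model(metrics, resp)
      fits[[resp]] <- if (full$converged) drop_interaction_if_ns(full, alpha)
                      else full
    }
  }
  if (!is.null(networks)) {
    for (dim in c("proximity", "affiliation", "agonism")) {
      fits[[paste0("density_", dim)]] <-
        fit_network_model(networks$density, "density", dim)
      fits[[paste0("strength_", dim)]] <-
        fit_network_model(networks$strength, "strength", dim)
    }
  }
  table <- purrr::map_dfr(fits, function(f) {
    td <- try(tidy(f), silent = TRUE)
    if (inherits(td, "try-error")) tibble() else td
  })
  list(fits = fits, table = table)
}
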