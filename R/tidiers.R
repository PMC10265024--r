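#' Tidy the fixed effects of a fitted model
#'
#' One row per fixed effect with the estimate, standard error, critical
#' value and p-value, in the conventional reporting layout. Gaussian models
#' report t statistics (Satterthwaite df for mixed fits); all other families
#' report Wald z statistics.
#'
#' @param x A `vlf_fit`.
#' @param ... Unused.
#' @return Tibble: response, term, estimate, std.error, statistic,
#'   statistic_type, p.value.
#' @exportS3Method generics::tidy
tidy.vlf_fit <- function(x, ...) {
  if (is.null(x$model))
    return(tibble(response = x$response, term = NA_character_,
                  estimate = NA_real_, std.error = NA_real_,
                  statistic = NA_real_, statistic_type = NA_character_,
                  df = NA_real_, p.value = NA_real_))
  m <- x$model
  df <- NA_real_
  if (inherits(m, "glmmTMB")) {
    co <- summary(m)$coefficients$cond
    type <- "z"
  } else if (inherits(m, "lmerModLmerTest")) {
    full <- summary(m)$coefficients
    df <- full[, "df"]
    co <- full[, c("Estimate", "Std. Error", "t value", "Pr(>|t|)"),
               drop = FALSE]
    type <- "t"
  } else {
    co <- summary(m)$coefficients
    type <- if (inherits(m, "glm") &&
                stats::family(m)$family %in% c("binomial", "poisson"))
      "z" else "t"
    if (type == "t") df <- stats::df.residual(m)
  }
  tibble(response = x$response, term = rownames(co),
         estimate = co[, 1], std.error = co[, 2], statistic = co[, 3],
         statistic_type = type, df = df, p.value = co[, 4])
}

#' One-row model summary
#'
#' @param x A `vlf_fit`.
#' @param ... Unused.
#' @return Tibble: response, family, link, nobs, converged,
#'   dropped_interaction, random-effect variances (as a packed list column
#'   when present) and any convergence note.
#' @exportS3Method generics::glance
glance.vlf_fit <- function(x, ...) {
  re_var <- NULL
  if (!is.null(x$model)) {
    vc <- try(switch(class(x$model)[1],
                     glmmTMB = glmmTMB::VarCorr(x$model)$cond,
                     lmerModLmerTest = lme4::VarCorr(x$model),
                     NULL), silent = TRUE)
    if (!inherits(vc, "try-error") && !is.null(vc))
      re_var <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  }
  tibble(response = x$response, family = x$family$family,
         link = x$family$link,
         nobs = nrow(x$data), converged = x$converged,
         dropped_interaction = x$dropped_interaction,
         random_effects = list(re_var), note = x$note %||% NA_character_)
}

#' @export
print.vlf_fit <- function(x, ...) {
  cat(sprintf("<model fit: %s, %s(%s)%s%s>\n", x$response, x$family$family,
              x$family$link,
              if (x$dropped_interaction) ", interaction dropped" else "",
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.null(x$model)) print(tidy(x), n = Inf)
  invisible(x)
}
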