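#' Compare nested learning models by change in deviance and AIC
#'
#' The study's model-selection device: removal of a term from the model
#' changes the deviance by an amount that, under the null of no effect,
#' follows a chi-square distribution with degrees of freedom equal to
#' the number of parameters removed. `compare_nested()` takes two fitted
#' [fit_learning_model()] objects (the reduced model nested in the full
#' one); `chisq_lrt()` performs the same arithmetic directly on a
#' deviance change and its degrees of freedom, e.g. to work from
#' reported statistics.
#'
#' @param full,null `learning_fit` objects, `null` nested in `full`.
#' @param tolerance slack allowed on the nesting inequality
#'   `deviance(null) >= deviance(full)` (optimizer noise).
#' @return list with `delta_deviance`, `delta_df`, `p_value`,
#'   `delta_aic` (`= delta_deviance - 2 * delta_df`, the AIC drop of the
#'   full model), `aic_full`, `aic_null`, `deviance_full`,
#'   `deviance_null`; class `nested_comparison`.
#' @examples
#' chisq_lrt(13.142, 1)   # strongly significant learning effect
#' chisq_lrt(0.0137, 1)   # p = 0.9067: no effect
#' @export
compare_nested <- function(full, null, tolerance = 1e-3) {
  stopifnot(inherits(full, "learning_fit"), inherits(null, "learning_fit"))
  delta_df <- full$n_params - null$n_params
  if (delta_df < 1L)
    stop("models are not nested: full must have more parameters")
  if (null$deviance < full$deviance - tolerance)
    stop("negative deviance change beyond tolerance: ",
         "models are not nested or a fit did not converge")
  delta_dev <- max(null$deviance - full$deviance, 0)
  out <- chisq_lrt(delta_dev, delta_df)
  out$aic_full <- full$aic; out$aic_null <- null$aic
  out$deviance_full <- full$deviance; out$deviance_null <- null$deviance
  out
}

#' @rdname compare_nested
#' @param delta_deviance observed change in deviance (>= 0).
#' @param delta_df degrees of freedom removed (>= 1).
#' @export
chisq_lrt <- function(delta_deviance, delta_df = 1L) {
  stopifnot(delta_deviance >= 0, delta_df >= 1)
  structure(list(delta_deviance = delta_deviance,
                 delta_df = as.integer(delta_df),
                 p_value = pchisq(delta_deviance, delta_df,
                                  lower.tail = FALSE),
                 delta_aic = delta_deviance - 2 * delta_df),
            class = "nested_comparison")
}

#' @export
print.nested_comparison <- function(x, ...) {
  cat(sprintf(
    "Nested model comparison: delta deviance = %.4g, df = %d, p = %.4g\n",
    x$delta_deviance, x$delta_df, x$p_value))
  cat(sprintf("  AIC change (null - full) = %.4g\n", x$delta_aic))
  if (!is.null(x$aic_full))
    cat(sprintf("  AIC %.2f (null) vs %.2f (full)\n",
                x$aic_null, x$aic_full))
  invisible(x)
}

#' Test for a learning (experience) effect
#'
#' Fits the experience model and its null (intercept plus the same
#' random effects) and compares them: the study's primary test of
#' whether foraging experience increased the proportion of correct
#' choices.
#'
#' @param table a choice table.
#' @param random random-effects structure for both fits (see
#'   [fit_learning_model()]).
#' @param ... passed to [fit_learning_model()].
#' @return A `nested_comparison` with the two fits attached as
#'   attributes `full` and `null`.
#' @export
experience_test <- function(table, random = "intercept_slope", ...) {
  full <- fit_learning_model(table, "experience", random = random, ...)
  null <- fit_learning_model(table, "null", random = random, ...)
  out <- compare_nested(full, null)
  attr(out, "full") <- full; attr(out, "null") <- null
  out
}

#' Test the intensity-contrast-by-experience interaction
#'
#' For intensity-contrast sessions: does the type of (task-irrelevant)
#' intensity contrast alter the learning rate? Compares the model with a
#' condition-by-experience interaction against the main-effects model;
#' a non-significant result indicates the bees learned the polarization
#' pattern while ignoring the intensity overlay.
#'
#' @param table a choice table with a `condition` column of >= 2 levels.
#' @param random random-effects structure for both fits.
#' @param ... passed to [fit_learning_model()].
#' @return A `nested_comparison` with fits attached as attributes.
#' @export
interaction_test <- function(table, random = "intercept_slope", ...) {
  if (!"condition" %in% names(table) ||
      length(unique(stats::na.omit(table$condition))) < 2L)
    stop("interaction test needs >= 2 condition levels")
  full <- fit_learning_model(table, "experience_x_condition",
                             random = random, ...)
  null <- fit_learning_model(table, "experience_condition",
                             random = random, ...)
  out <- compare_nested(full, null)
  attr(out, "full") <- full; attr(out, "null") <- null
  out
}

#' Assemble a learning-analysis report
#'
#' Runs [experience_test()] on a choice table and returns the flat list
#' of headline numbers (ready for JSON serialization).
#'
#' @param table a choice table.
#' @param ... passed to [experience_test()].
#' @return list with `treatment`, `deviance_null`, `deviance_full`,
#'   `delta_deviance`, `df`, `p`, `aic_null`, `aic_full`.
#' @export
learning_report <- function(table, ...) {
  cmp <- experience_test(table, ...)
  list(treatment = attr(table, "treatment") %||% "unknown",
       deviance_null = cmp$deviance_null,
       deviance_full = cmp$deviance_full,
       delta_deviance = cmp$delta_deviance, df = cmp$delta_df,
       p = cmp$p_value, aic_null = cmp$aic_null, aic_full = cmp$aic_full)
}
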