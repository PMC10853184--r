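#' Fit a linear age model for a morphological variable
#'
#' Ordinary least squares of `variable` on age within one diagnostic group
#' (healthy controls by default, so that disease effects do not define the
#' normal aging trajectory). The model is recentred at `reference_age` —
#' by default the mean age of the *full* table, so that age-corrected values
#' stay on the natural scale of the cohort.
#'
#' @param data data.frame containing `age`, `diagnosis` and the variable.
#' @param variable name of the column to model (e.g. `"K"` or
#'   `"log10_thickness"`).
#' @param fit_group diagnosis subset used for the fit; default `"CTL"`.
#' @param reference_age recentring age in years; default `mean(data$age)`
#'   over all rows.
#' @return object of class `"age_model"`: `variable`, `slope` (units/year),
#'   `intercept`, `reference_age`, `fit_group`, `n`, and the underlying `lm`.
#' @export
fit_age_model <- function(data, variable, fit_group = "CTL",
                          reference_age = NULL) {
  stopifnot(variable %in% names(data), "age" %in% names(data))
  reference_age <- reference_age %||% mean(data$age)
  sub <- if (is.null(fit_group)) data else data[data$diagnosis %in% fit_group, , drop = FALSE]
  sub <- sub[is.finite(sub[[variable]]) & is.finite(sub$age), , drop = FALSE]
  if (nrow(sub) < 3L) {
    stop_foldlaw("fit_age_model needs at least 3 observations in group ",
                 paste(fit_group, collapse = "/"), ", got ", nrow(sub),
                 class = "foldlaw_insufficient_data_error")
  }
  fit <- stats::lm(stats::reformulate("age", response = variable), data = sub)
  structure(list(
    variable = variable,
    slope = unname(stats::coef(fit)["age"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    reference_age = reference_age,
    fit_group = fit_group,
    n = nrow(sub),
    lm = fit
  ), class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("Age model for %s (fit on %s, n = %d):\n", x$variable,
              paste(x$fit_group, collapse = "/"), x$n))
  cat(sprintf("  slope = %.6g per year; prediction at reference age %.1f y = %.6g\n",
              x$slope, x$reference_age, predict(x, x$reference_age)))
  invisible(x)
}

#' @export
predict.age_model <- function(object, age, ...) {
  object$intercept + object$slope * age
}

#' @export
coef.age_model <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Remove the linear age effect from a morphological variable
#'
#' Subtracts the fitted age trend, recentred at the model's reference age:
#' `corrected = observed - slope * (age - reference_age)`. Group means at
#' the reference age are preserved, and the corrected variable is
#' (approximately) decorrelated from age within the fit group. The corrected
#' values are appended as `<variable>_agecorr`.
#'
#' @param data data.frame with `age` and the model's variable.
#' @param model an [fit_age_model()] result.
#' @return `data` with a `<variable>_agecorr` column appended.
#' @export
remove_age_effect <- function(data, model) {
  stopifnot(inherits(model, "age_model"), model$variable %in% names(data))
  corrected <- data[[model$variable]] - model$slope * (data$age - model$reference_age)
  data[[paste0(model$variable, "_agecorr")]] <- corrected
  data
}

#' Pearson correlation of a variable with age
#'
#' Pearson's r between `variable` and age with `df = n - 2`, a two-tailed p
#' value, and Cohen's d effect size via [r_to_cohens_d()].
#'
#' @param data data.frame with `age` and the variable.
#' @param variable column name.
#' @return list with `r`, `df`, `p`, `d`, `n`.
#' @export
age_correlation <- function(data, variable) {
  keep <- is.finite(data[[variable]]) & is.finite(data$age)
  v <- data[[variable]][keep]
  a <- data$age[keep]
  if (length(v) < 3L) {
    stop_foldlaw("age_correlation needs at least 3 paired values",
                 class = "foldlaw_insufficient_data_error")
  }
  if (stats::sd(v) == 0 || stats::sd(a) == 0) {
    stop_foldlaw("constant variable: correlation undefined",
                 class = "foldlaw_degenerate_error")
  }
  ct <- stats::cor.test(v, a, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, df = unname(ct$parameter), p = ct$p.value,
       d = r_to_cohens_d(r), n = length(v))
}
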