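#' Fit the universal cortical folding scaling law
#'
#' Fits the log form of the scaling law
#' \deqn{T^{1/2} A_T = k \, A_E^{\alpha}}
#' by ordinary least squares of the response
#' `y = log10(A_T) + 1/2 * log10(T)` on `x = log10(A_E)`. The slope estimate
#' is the self-similarity exponent `alpha` (theoretical value 1.25) and the
#' intercept estimates `log10(k)` at the fit level. The fitted slope is
#' tested against the theoretical value with a two-tailed Student's t-test
#' on `n - 2` degrees of freedom (see [test_slope_vs_theory()]).
#'
#' Each row of `data` is one observation; in the intended use both
#' hemispheres of every subject enter as separate rows.
#'
#' @param data morphometry data.frame with positive `total_area_mm2`,
#'   `exposed_area_mm2`, `avg_thickness_mm`; at least 3 rows.
#' @param theory theoretical slope to test against (default 1.25).
#' @return object of class `"scaling_law_fit"` with components `alpha`,
#'   `alpha_se`, `intercept` (log10 k), `intercept_se`, `r_squared`, `n`,
#'   `df`, `t_vs_theory`, `p_two_tailed`, `theory`, and the underlying `lm`
#'   fit.
#' @examples
#' spec <- cohort_spec(seed = 7)
#' cohort <- generate_cohort(spec)
#' hemi <- cohort$morphometry[cohort$morphometry$roi == "hemisphere", ]
#' fit <- fit_scaling_law(hemi)
#' summary(fit)
#' @export
fit_scaling_law <- function(data, theory = 1.25) {
  data <- validate_morphometry(data)
  if (nrow(data) < 3L) {
    stop_foldlaw("fit_scaling_law needs at least 3 observations, got ", nrow(data),
                 class = "foldlaw_insufficient_data_error")
  }
  x <- log10(data$exposed_area_mm2)
  y <- log10(data$total_area_mm2) + 0.5 * log10(data$avg_thickness_mm)
  if (stats::var(x) == 0) {
    stop_foldlaw("zero variance in log10(exposed area): degenerate design",
                 class = "foldlaw_degenerate_error")
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  # summary.lm warns on exactly law-consistent data; the zero-residual
  # case is legitimate here
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  alpha <- unname(stats::coef(fit)[2L])
  alpha_se <- sm$coefficients[2L, 2L]
  out <- structure(list(
    alpha = alpha,
    alpha_se = alpha_se,
    intercept = unname(stats::coef(fit)[1L]),
    intercept_se = sm$coefficients[1L, 2L],
    r_squared = sm$r.squared,
    n = nrow(data),
    df = fit$df.residual,
    theory = theory,
    lm = fit
  ), class = "scaling_law_fit")
  tt <- test_slope_vs_theory(out, theory = theory)
  out$t_vs_theory <- tt$t
  out$p_two_tailed <- tt$p
  out
}

#' Test a fitted scaling-law slope against a theoretical value
#'
#' Two-tailed Student's t-test of the fitted exponent against the
#' theoretical self-similarity value:
#' `t = (alpha - theory) / alpha_se`, with `df = n - 2`.
#'
#' @param fit a `"scaling_law_fit"`, or a list with `alpha`, `alpha_se`, `df`.
#' @param theory theoretical slope; default 1.25.
#' @return list with components `t`, `p`, `df`.
#' @export
test_slope_vs_theory <- function(fit, theory = 1.25) {
  if (!is.numeric(fit$alpha_se) || fit$alpha_se <= 0) {
    stop_foldlaw("alpha_se must be positive", class = "foldlaw_degenerate_error")
  }
  t <- (fit$alpha - theory) / fit$alpha_se
  list(t = t, p = 2 * stats::pt(-abs(t), df = fit$df), df = fit$df)
}

#' @export
print.scaling_law_fit <- function(x, digits = 4, ...) {
  cat("Universal cortical folding law fit:",
      "log10(T^1/2 * A_T) ~ log10(A_E)\n")
  cat(sprintf("  alpha      = %.*f (SE %.*f), theoretical %.2f\n",
              digits, x$alpha, digits, x$alpha_se, x$theory))
  cat(sprintf("  log10(k)   = %.*f (SE %.*f)\n",
              digits, x$intercept, digits, x$intercept_se))
  cat(sprintf("  R^2 = %.*f on n = %d observations (df = %d)\n",
              digits, x$r_squared, x$n, x$df))
  cat(sprintf("  t vs %.2f = %.*f, two-tailed p = %.3g\n",
              x$theory, digits, x$t_vs_theory, x$p_two_tailed))
  invisible(x)
}

#' @export
summary.scaling_law_fit <- function(object, ...) {
  ci <- stats::confint(object$lm)["x", ]
  structure(list(fit = object, alpha_ci = unname(ci)), class = "summary.scaling_law_fit")
}

#' @export
print.summary.scaling_law_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  95%% CI for alpha: [%.4f, %.4f]\n", x$alpha_ci[1], x$alpha_ci[2]))
  invisible(x)
}

#' @export
coef.scaling_law_fit <- function(object, ...) {
  c(log10_k = object$intercept, alpha = object$alpha)
}

#' @export
confint.scaling_law_fit <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$lm, level = level)
  rownames(ci) <- c("log10_k", "alpha")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict total area from the fitted scaling law
#'
#' For new observations with exposed area and thickness, returns the total
#' pial area implied by the fitted law:
#' `A_T = 10^(intercept + alpha * log10(A_E)) / sqrt(T)`.
#'
#' @param object a `"scaling_law_fit"`.
#' @param newdata data.frame with `exposed_area_mm2` and `avg_thickness_mm`.
#' @param ... unused.
#' @return numeric vector of predicted total areas (mm^2).
#' @export
predict.scaling_law_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(stats::fitted(object$lm))
  y <- object$intercept + object$alpha * log10(newdata$exposed_area_mm2)
  10^y / sqrt(newdata$avg_thickness_mm)
}

#' @export
residuals.scaling_law_fit <- function(object, ...) stats::residuals(object$lm)

#' Plot a scaling-law fit
#'
#' Scatter of `log10(T^1/2 A_T)` against `log10(A_E)` with the fitted line
#' and, for reference, a line of theoretical slope through the data centroid.
#'
#' @param x a `"scaling_law_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.scaling_law_fit <- function(x, ...) {
  m <- x$lm$model
  graphics::plot(m$x, m$y,
                 xlab = expression(log[10] ~ A[E]),
                 ylab = expression(log[10] ~ (T^{1 / 2} ~ A[T])), ...)
  graphics::abline(x$lm, lwd = 2)
  graphics::abline(a = mean(m$y) - x$theory * mean(m$x), b = x$theory,
                   lty = 2, col = "grey40")
  graphics::legend("topleft",
                   legend = c(sprintf("fit (alpha = %.3f)", x$alpha),
                              sprintf("theory (alpha = %.2f)", x$theory)),
                   lty = c(1, 2), lwd = c(2, 1), col = c("black", "grey40"),
                   bty = "n")
  invisible(x)
}
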