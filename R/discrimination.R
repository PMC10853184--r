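#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Tests whether a morphological variable differs across diagnostic groups:
#' one-way ANOVA F-test followed by Tukey multiple comparisons of means
#' (family-wise adjusted p values).
#'
#' @param data data.frame with columns `diagnosis` and `value` (or name the
#'   value column via `value`).
#' @param value name of the value column; default `"value"`.
#' @return object of class `"group_test"`: `f_stat`, `df_between`,
#'   `df_within`, `p`, and `pairwise` (data.frame of pair, difference,
#'   adjusted p).
#' @examples
#' d <- data.frame(diagnosis = rep(c("CTL", "MCI", "AD"), each = 3),
#'                 value = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' group_anova(d)
#' @export
group_anova <- function(data, value = "value") {
  stopifnot("diagnosis" %in% names(data), value %in% names(data))
  keep <- is.finite(data[[value]])
  df <- data.frame(diagnosis = factor(data$diagnosis[keep]),
                   value = data[[value]][keep])
  counts <- table(df$diagnosis)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop_foldlaw("group_anova needs >= 2 groups with >= 2 values each",
                 class = "foldlaw_insufficient_data_error")
  }
  fit <- stats::aov(value ~ diagnosis, data = df)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$diagnosis
  structure(list(
    f_stat = tab[1L, "F value"],
    df_between = tab[1L, "Df"],
    df_within = tab[2L, "Df"],
    p = tab[1L, "Pr(>F)"],
    pairwise = data.frame(pair = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL)
  ), class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g on (%d, %d) df, p = %.3g\n",
              x$f_stat, x$df_between, x$df_within, x$p))
  cat("Tukey HSD pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

# sens/spec at every candidate threshold, positive = disease.
# direction "lower_is_positive": classify positive when score <= threshold.
# Returns a data.frame sorted by threshold.
roc_points <- function(scores, labels, direction, thresholds) {
  pos <- scores[labels]
  neg <- scores[!labels]
  if (direction == "lower_is_positive") {
    sens <- vapply(thresholds, function(t) mean(pos <= t), 0.0)
    spec <- vapply(thresholds, function(t) mean(neg > t), 0.0)
  } else {
    sens <- vapply(thresholds, function(t) mean(pos >= t), 0.0)
    spec <- vapply(thresholds, function(t) mean(neg < t), 0.0)
  }
  data.frame(threshold = thresholds, sensitivity = sens, specificity = spec)
}

#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC curve over every distinct score threshold and
#' computes the AUC as the Mann-Whitney probability that a random diseased
#' score is on the diseased side of a random control score, with ties
#' counted 1/2. `direction = "lower_is_positive"` means lower scores indicate
#' disease (the case for the folding biomarker K and for thickness).
#'
#' @param scores numeric biomarker values.
#' @param labels logical (or 0/1) disease indicator, `TRUE` = disease.
#' @param direction `"lower_is_positive"` or `"higher_is_positive"`.
#' @return object of class `"roc_curve"`: `curve` (threshold, sensitivity,
#'   specificity), `auc`, `direction`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels, direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_foldlaw("empirical_roc requires both classes present",
                 class = "foldlaw_validation_error")
  }
  # Mann-Whitney AUC via midranks: rank-sum of the positive class counts
  # pairs with control > disease (+ half ties) when lower is positive.
  r <- rank(scores)
  p_neg_gt_pos <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  auc <- if (direction == "lower_is_positive") 1 - p_neg_gt_pos else p_neg_gt_pos
  thresholds <- c(-Inf, sort(unique(scores)), Inf)
  structure(list(
    curve = roc_points(scores, labels, direction, thresholds),
    auc = auc, direction = direction, n_pos = n_pos, n_neg = n_neg
  ), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.4f (%d disease vs %d control, %s)\n",
              x$auc, x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

# candidate cut-points: midpoints between adjacent distinct scores, plus
# +-Inf so "classify none"/"classify all" are always available.
cutpoint_candidates <- function(scores) {
  s <- sort(unique(scores))
  mid <- if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2 else numeric(0)
  c(-Inf, mid, Inf)
}

# single best cut-point by max(sens + spec); ties -> max sensitivity,
# then lowest threshold. Deterministic. Cumulative-count implementation:
# O(n log n), exercised against a naive per-threshold search in the tests.
best_cutpoint <- function(scores, labels, direction) {
  o <- order(scores)
  s <- scores[o]; l <- labels[o]
  n_pos <- sum(l); n_neg <- length(l) - n_pos
  is_last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each distinct value
  pos_le <- cumsum(l)[is_last]                 # positives with score <= value
  neg_le <- cumsum(!l)[is_last]
  m <- sum(is_last)
  inner_pos <- if (m > 1L) pos_le[-m] else integer(0)
  inner_neg <- if (m > 1L) neg_le[-m] else integer(0)
  thresholds <- cutpoint_candidates(s)
  if (direction == "lower_is_positive") {
    sens <- c(0, inner_pos, n_pos) / n_pos
    spec <- c(n_neg, n_neg - inner_neg, 0) / n_neg
  } else {
    sens <- c(n_pos, n_pos - inner_pos, 0) / n_pos
    spec <- c(0, inner_neg, n_neg) / n_neg
  }
  j <- sens + spec
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1L) best <- best[which.min(thresholds[best])]
  data.frame(threshold = thresholds[best], sensitivity = sens[best],
             specificity = spec[best])
}

#' Optimal cut-point by maximum sensitivity + specificity
#'
#' Finds the threshold maximising sensitivity + specificity (equivalently
#' the Youden J statistic) over candidate cut-points placed midway between
#' adjacent distinct scores (plus the two degenerate extremes). Ties are
#' broken deterministically: highest sensitivity first (a screening
#' biomarker favours sensitivity), then the lowest threshold. Cut-point
#' sampling variability is estimated by a class-stratified bootstrap
#' (percentile 95% interval, 1000 resamples by default).
#'
#' @inheritParams empirical_roc
#' @param bootstrap_n number of bootstrap resamples (default 1000; 0 skips
#'   the interval).
#' @param seed integer seed for the bootstrap; required when
#'   `bootstrap_n > 0` so reports are reproducible.
#' @param variable,contrast optional labels carried into the report.
#' @return object of class `"cutpoint_report"`: `cutpoint`, `auc`,
#'   `accuracy`, `sensitivity`, `specificity`, `bootstrap_n`, `cutpoint_ci`,
#'   `seed`, counts, and labels.
#' @examples
#' scores <- c(-0.50, -0.51, -0.52, -0.55, -0.56)
#' disease <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
#' optimal_cutpoint(scores, disease, bootstrap_n = 0)
#' @export
optimal_cutpoint <- function(scores, labels,
                             direction = c("lower_is_positive", "higher_is_positive"),
                             bootstrap_n = 1000, seed = NULL,
                             variable = NA_character_, contrast = NA_character_) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop_foldlaw("optimal_cutpoint requires both classes present",
                 class = "foldlaw_validation_error")
  }
  if (bootstrap_n > 0 && is.null(seed)) {
    stop_foldlaw("seed is required when bootstrap_n > 0",
                 class = "foldlaw_validation_error")
  }
  best <- best_cutpoint(scores, labels, direction)
  auc <- empirical_roc(scores, labels, direction)$auc
  tp <- best$sensitivity * n_pos
  tn <- best$specificity * n_neg
  accuracy <- (tp + tn) / (n_pos + n_neg)

  ci <- c(NA_real_, NA_real_)
  boot_cuts <- numeric(0)
  if (bootstrap_n > 0) {
    pos_scores <- scores[labels]
    neg_scores <- scores[!labels]
    boot_cuts <- with_seed(seed, {
      vapply(seq_len(bootstrap_n), function(i) {
        s <- c(sample(pos_scores, n_pos, replace = TRUE),
               sample(neg_scores, n_neg, replace = TRUE))
        l <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
        best_cutpoint(s, l, direction)$threshold
      }, 0.0)
    })
    finite <- boot_cuts[is.finite(boot_cuts)]
    if (length(finite)) {
      ci <- unname(stats::quantile(finite, c(0.025, 0.975)))
    }
  }
  structure(list(
    variable = variable, contrast = contrast, direction = direction,
    cutpoint = best$threshold,
    auc = auc, accuracy = accuracy,
    sensitivity = best$sensitivity, specificity = best$specificity,
    bootstrap_n = bootstrap_n, cutpoint_ci = ci, seed = seed,
    n_pos = n_pos, n_neg = n_neg
  ), class = "cutpoint_report")
}

#' @export
print.cutpoint_report <- function(x, ...) {
  lab <- if (!is.na(x$variable)) paste0(x$variable, " ") else ""
  ctr <- if (!is.na(x$contrast)) paste0(" [", x$contrast, "]") else ""
  cat(sprintf("Optimal cut-point for %s(max sens + spec)%s:\n", lab, ctr))
  cat(sprintf("  cut-point = %.4g (%s), AUC = %.2f\n", x$cutpoint, x$direction, x$auc))
  cat(sprintf("  accuracy = %.2f, sensitivity = %.2f, specificity = %.2f (%d vs %d)\n",
              x$accuracy, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  if (x$bootstrap_n > 0) {
    cat(sprintf("  bootstrap 95%% CI of cut-point: [%.4g, %.4g] (%d resamples, seed %d)\n",
                x$cutpoint_ci[1], x$cutpoint_ci[2], x$bootstrap_n, x$seed))
  }
  invisible(x)
}

#' @export
as.data.frame.cutpoint_report <- function(x, ...) {
  data.frame(variable = x$variable, contrast = x$contrast,
             cutpoint = x$cutpoint, auc = x$auc, accuracy = x$accuracy,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ci_low = x$cutpoint_ci[1], ci_high = x$cutpoint_ci[2],
             n_pos = x$n_pos, n_neg = x$n_neg,
             bootstrap_n = x$bootstrap_n,
             stringsAsFactors = FALSE)
}

#' Cut-point reports for a set of ROIs and diagnostic contrasts
#'
#' Runs [optimal_cutpoint()] for one variable over each requested ROI and
#' diagnostic contrast (control-like group vs disease-like group; the
#' disease group is the positive class). Mirrors the lobe-by-contrast
#' cut-point table layout. Contrasts with an empty cell are skipped with a
#' warning.
#'
#' @param data data.frame with columns `diagnosis`, `roi` and the variable.
#' @param variable name of the score column (e.g. `"K_agecorr"`).
#' @param rois ROIs to analyse; default all present.
#' @param contrasts list of 2-vectors `c(control_group, disease_group)`;
#'   default `list(c("CTL","AD"), c("CTL","MCI"))`.
#' @param direction passed to [optimal_cutpoint()]; default
#'   `"lower_is_positive"` (lower folding / thinner cortex = disease).
#' @param bootstrap_n,seed passed to [optimal_cutpoint()]; each (roi,
#'   contrast) cell gets a sub-seed derived from `seed`.
#' @return data.frame with one row per (roi, contrast) in the cut-point
#'   table layout.
#' @export
contrast_table <- function(data, variable, rois = NULL,
                           contrasts = list(c("CTL", "AD"), c("CTL", "MCI")),
                           direction = "lower_is_positive",
                           bootstrap_n = 1000, seed = NULL) {
  stopifnot(variable %in% names(data))
  rois <- rois %||% intersect(ROI_LEVELS, unique(data$roi))
  rows <- list()
  stage <- 0L
  for (roi in rois) {
    for (ct in contrasts) {
      stage <- stage + 1L
      sub <- data[data$roi == roi & data$diagnosis %in% ct, , drop = FALSE]
      n_dis <- sum(sub$diagnosis == ct[2L])
      n_ctl <- sum(sub$diagnosis == ct[1L])
      if (n_dis == 0L || n_ctl == 0L) {
        warning(sprintf("contrast_table: empty cell for %s %s-%s; skipped",
                        roi, ct[1L], ct[2L]))
        next
      }
      rep <- optimal_cutpoint(sub[[variable]], sub$diagnosis == ct[2L],
                              direction = direction, bootstrap_n = bootstrap_n,
                              seed = derive_seed(seed, stage),
                              variable = variable,
                              contrast = paste(ct, collapse = "-"))
      row <- as.data.frame(rep)
      row <- cbind(data.frame(roi = roi, stringsAsFactors = FALSE), row)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
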