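#' Convert a Pearson correlation to Cohen's d
#'
#' Effect size of a correlation on the standardised mean-difference scale:
#' \deqn{d = \frac{2r}{\sqrt{1 - r^2}}}
#' This conversion reproduces every printed (r, d) pair in the study's
#' association tables (e.g. r = -0.32 -> d = -0.68; r = 0.41 -> d = 0.90).
#' The inverse is `r = d / sqrt(d^2 + 4)` ([cohens_d_to_r()]).
#'
#' @param r Pearson correlation, `|r| < 1`.
#' @return Cohen's d (same sign as `r`).
#' @export
r_to_cohens_d <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop_foldlaw("r must satisfy |r| < 1", class = "foldlaw_domain_error")
  }
  2 * r / sqrt(1 - r^2)
}

#' @rdname r_to_cohens_d
#' @param d Cohen's d.
#' @export
cohens_d_to_r <- function(d) {
  if (any(!is.finite(d))) {
    stop_foldlaw("d must be finite", class = "foldlaw_domain_error")
  }
  d / sqrt(d^2 + 4)
}

#' Correlate a clinical measure with a morphological variable
#'
#' Pairwise-complete Pearson correlation with two-tailed p value, Cohen's d
#' via [r_to_cohens_d()], and Bonferroni adjustment within a declared family
#' of comparisons (`p_adj = min(1, p_raw * family_size)`).
#'
#' @param clinical numeric vector (behavioral or CSF measure).
#' @param morph numeric vector (e.g. K), same length.
#' @param family_size number of comparisons in the Bonferroni family
#'   (default 1 = no correction).
#' @param clinical_measure,morph_variable,roi optional labels for the result.
#' @return object of class `"association_result"` (also a one-row
#'   data.frame): `clinical_measure`, `morph_variable`, `roi`, `r`, `d`,
#'   `p_raw`, `p_adj`, `n`.
#' @export
correlate <- function(clinical, morph, family_size = 1,
                      clinical_measure = NA_character_,
                      morph_variable = NA_character_, roi = NA_character_) {
  stopifnot(length(clinical) == length(morph), family_size >= 1)
  keep <- is.finite(clinical) & is.finite(morph)
  x <- clinical[keep]; y <- morph[keep]
  if (length(x) < 3L) {
    stop_foldlaw("correlate needs at least 3 complete pairs, got ", length(x),
                 class = "foldlaw_insufficient_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_foldlaw("zero variance: correlation undefined",
                 class = "foldlaw_degenerate_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  out <- data.frame(
    clinical_measure = clinical_measure, morph_variable = morph_variable,
    roi = roi, r = r, d = r_to_cohens_d(r), p_raw = ct$p.value,
    p_adj = min(1, ct$p.value * family_size), n = length(x),
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", class(out))
  out
}

#' Association table for clinical measures vs a morphological variable
#'
#' Computes [correlate()] for every requested (clinical measure, ROI) cell
#' against one morphological variable, pooling all diagnostic groups (the
#' morphology-symptom association is studied independently of diagnosis).
#' The Bonferroni family is all cells tested for that morphological
#' variable.
#'
#' @param data joined table (see [join_clinical()]) containing `roi`, the
#'   clinical columns and the morphological variable.
#' @param morph_variable morphological column name (e.g. `"K"`).
#' @param measures character vector of clinical column names.
#' @param rois ROIs to test; default `"hemisphere"`.
#' @return data.frame of association results (one row per measure x ROI),
#'   mirroring the published association-table layout.
#' @export
association_table <- function(data, morph_variable, measures,
                              rois = "hemisphere") {
  stopifnot(morph_variable %in% names(data))
  measures <- intersect(measures, names(data))
  cells <- expand.grid(measure = measures, roi = rois,
                       stringsAsFactors = FALSE)
  family_size <- nrow(cells)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- data[data$roi == cells$roi[i], , drop = FALSE]
    tryCatch(
      correlate(sub[[cells$measure[i]]], sub[[morph_variable]],
                family_size = family_size,
                clinical_measure = cells$measure[i],
                morph_variable = morph_variable, roi = cells$roi[i]),
      foldlaw_error = function(e) NULL
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composite cognitive index from memory and attention scores
#'
#' Global cognition summary: the mean of the z-scores of RAVLT trial A5
#' (last learning trial), RAVLT A7 (delayed recall), and Trail Making Test
#' parts A and B, each standardised against user-supplied normative values
#' by 10-year age band. TMT z-scores are sign-flipped (longer times are
#' worse) so a higher index always means better cognition. Digit Span
#' Backward is deliberately excluded to avoid over-representing executive
#' function.
#'
#' @param data data.frame with `age`, `ravlt_a5`, `ravlt_a7`, `tmt_a`,
#'   `tmt_b`.
#' @param norms normative table with columns `measure` (one of ravlt_a5,
#'   ravlt_a7, tmt_a, tmt_b), `age_low`, `age_high`, `mean`, `sd` (sd > 0).
#'   Bands are matched as `age_low <= age < age_high`. See
#'   [synthetic_norms()] for a synthetic testing default.
#' @return numeric vector of cognitive index values (z-score units); `NA`
#'   where any component score is missing.
#' @export
cognitive_index <- function(data, norms) {
  measures <- c("ravlt_a5", "ravlt_a7", "tmt_a", "tmt_b")
  stopifnot(all(c("age", measures) %in% names(data)),
            all(c("measure", "age_low", "age_high", "mean", "sd") %in% names(norms)))
  if (any(norms$sd <= 0)) {
    stop_foldlaw("normative sd must be > 0", class = "foldlaw_validation_error")
  }
  z_of <- function(measure, value, age) {
    band <- norms[norms$measure == measure &
                    norms$age_low <= age & age < norms$age_high, , drop = FALSE]
    if (nrow(band) == 0L) {
      stop_foldlaw("no norm for measure ", measure, " at age ", age,
                   class = "foldlaw_norms_error")
    }
    (value - band$mean[1L]) / band$sd[1L]
  }
  vapply(seq_len(nrow(data)), function(i) {
    vals <- unlist(data[i, measures])
    if (anyNA(vals)) return(NA_real_)
    z <- vapply(measures, function(m) z_of(m, data[[m]][i], data$age[i]), 0.0)
    z[c("tmt_a", "tmt_b")] <- -z[c("tmt_a", "tmt_b")]
    mean(z)
  }, 0.0)
}

#' Synthetic normative table for the cognitive index
#'
#' A plausibility-shaped stand-in normative table (10-year age bands from 40
#' to 100) for testing and simulation only; real analyses must supply norms
#' appropriate to the population, age and schooling. Values decline (RAVLT)
#' or lengthen (TMT) mildly with age.
#'
#' @return data.frame with columns `measure`, `age_low`, `age_high`, `mean`,
#'   `sd`.
#' @export
synthetic_norms <- function() {
  bands <- data.frame(age_low = seq(40, 90, by = 10))
  bands$age_high <- bands$age_low + 10
  step <- seq_len(nrow(bands)) - 1L
  rbind(
    data.frame(measure = "ravlt_a5", bands, mean = 11 - 0.6 * step, sd = 2.0),
    data.frame(measure = "ravlt_a7", bands, mean = 10 - 0.7 * step, sd = 2.5),
    data.frame(measure = "tmt_a", bands, mean = 35 + 6 * step, sd = 14),
    data.frame(measure = "tmt_b", bands, mean = 80 + 16 * step, sd = 38)
  )
}
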