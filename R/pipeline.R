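#' Configuration for a full analysis run
#'
#' Assembles and checks the options driving [run_full_analysis()]. Exactly
#' one input source is used: a morphometry file path (`morphometry_path`,
#' optionally with `clinical_path`), in-memory data.frames, or a
#' [cohort_spec()] to simulate from.
#'
#' @param morphometry_path,clinical_path input file paths (CSV by default).
#' @param morphometry,clinical in-memory data.frames (alternative to paths).
#' @param simulate a [cohort_spec()] to generate the inputs from.
#' @param output_dir directory for output tables and the run report.
#' @param rois ROIs to analyse in the cut-point stage.
#' @param contrasts list of `c(control_group, disease_group)` pairs.
#' @param variables morphological score columns for discrimination.
#' @param age_correction logical; remove the linear age effect before
#'   discrimination.
#' @param age_fit_group diagnosis group the age model is fitted on.
#' @param clinical_measures clinical columns for the association stage.
#' @param bootstrap_n bootstrap resamples for cut-point intervals.
#' @param seed root integer seed; every stochastic stage derives its own
#'   sub-seed from it. Required whenever any stochastic step is enabled.
#' @param alpha_theory theoretical scaling-law slope to test against.
#' @return object of class `"run_config"`.
#' @export
run_config <- function(morphometry_path = NULL, clinical_path = NULL,
                       morphometry = NULL, clinical = NULL,
                       simulate = NULL,
                       output_dir = NULL,
                       rois = ROI_LEVELS,
                       contrasts = list(c("CTL", "AD"), c("CTL", "MCI")),
                       variables = c("K", "log10_thickness"),
                       age_correction = TRUE,
                       age_fit_group = "CTL",
                       clinical_measures = c("cognitive_index", "ravlt_ratio",
                                             "tmt_b_minus_a", "digit_span_backward",
                                             "csf_abeta40", "csf_abeta42",
                                             "csf_ttau", "csf_lipoxin"),
                       bootstrap_n = 1000,
                       seed = NULL,
                       alpha_theory = 1.25) {
  sources <- c(!is.null(morphometry_path), !is.null(morphometry), !is.null(simulate))
  if (sum(sources) != 1L) {
    stop_foldlaw("provide exactly one of morphometry_path, morphometry, simulate",
                 class = "foldlaw_validation_error")
  }
  stochastic <- bootstrap_n > 0 || !is.null(simulate)
  if (stochastic && is.null(seed)) {
    stop_foldlaw("seed is required when simulation or bootstrap is enabled",
                 class = "foldlaw_validation_error")
  }
  structure(list(
    morphometry_path = morphometry_path, clinical_path = clinical_path,
    morphometry = morphometry, clinical = clinical, simulate = simulate,
    output_dir = output_dir, rois = rois, contrasts = contrasts,
    variables = variables, age_correction = age_correction,
    age_fit_group = age_fit_group, clinical_measures = clinical_measures,
    bootstrap_n = bootstrap_n, seed = seed, alpha_theory = alpha_theory
  ), class = "run_config")
}

write_csv_table <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full cortical-folding analysis
#'
#' Orchestrates the pipeline: load or simulate the morphometry (and
#' clinical) tables; curvature-correct lobar rows; compute folding
#' variables; fit the scaling law on hemisphere rows and test the slope
#' against the theoretical value; quantify and (optionally) remove the age
#' effect; run group ANOVA + Tukey comparisons and optimal cut-point
#' discrimination per ROI and contrast; and correlate morphology with the
#' clinical measures. Outputs are deterministic under a fixed seed.
#'
#' When `output_dir` is set, the stage tables are written as CSV
#' (`folding_variables.csv`, `scaling_fit.json`, `anova.csv`,
#' `cutpoints.csv`, `associations.csv`) plus a machine-readable
#' `run_report.json` recording the package version, configuration hash,
#' seeds and emitted files — enough to re-execute an identical run.
#'
#' @param config a [run_config()].
#' @return object of class `"folding_analysis"`: `folded` (per-observation
#'   table with K, S, I, GI and any age-corrected columns), `scaling_fit`,
#'   `age_models`, `age_correlations`, `anova`, `cutpoints`,
#'   `associations`, `warnings`, `report`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(stage, msg) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, msg))
  }
  capture <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      note(stage, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- input stage -----------------------------------------------------
  ground_truth <- NULL
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate, seed = derive_seed(config$seed, 1L))
    morpho <- cohort$morphometry
    clinical <- cohort$clinical
    ground_truth <- cohort$ground_truth
  } else if (!is.null(config$morphometry_path)) {
    morpho <- read_morphometry(config$morphometry_path)
    clinical <- if (!is.null(config$clinical_path)) read_clinical(config$clinical_path) else NULL
  } else {
    morpho <- validate_morphometry(config$morphometry)
    clinical <- if (!is.null(config$clinical)) validate_clinical(config$clinical) else NULL
  }

  # --- folding stage ---------------------------------------------------
  is_lobe <- morpho$roi != "hemisphere"
  corrected <- morpho
  if (any(is_lobe)) {
    corrected[is_lobe, ] <- capture("curvature", curvature_correct(morpho[is_lobe, , drop = FALSE])[names(morpho)])
  }
  folded <- compute_folding(corrected)

  # --- scaling-law stage (hemisphere rows) -----------------------------
  hemi <- folded[folded$roi == "hemisphere", , drop = FALSE]
  scaling_fit <- fit_scaling_law(hemi, theory = config$alpha_theory)

  # --- age stage -------------------------------------------------------
  age_models <- list()
  age_correlations <- list()
  score_vars <- config$variables
  if (config$age_correction) {
    for (v in config$variables) {
      model <- fit_age_model(hemi, v, fit_group = config$age_fit_group,
                             reference_age = mean(folded$age))
      age_models[[v]] <- model
      folded <- remove_age_effect(folded, model)
      age_correlations[[v]] <- age_correlation(
        folded[folded$roi == "hemisphere" & folded$diagnosis %in% config$age_fit_group, ], v)
    }
    score_vars <- paste0(config$variables, "_agecorr")
  }

  # --- discrimination stage --------------------------------------------
  anova_rows <- list()
  cutpoint_rows <- list()
  stage_seed <- 100L
  for (v in score_vars) {
    for (roi in intersect(config$rois, unique(folded$roi))) {
      sub <- folded[folded$roi == roi, , drop = FALSE]
      counts <- table(sub$diagnosis)
      if (length(counts) >= 2L && all(counts >= 2L)) {
        gt <- group_anova(sub, value = v)
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          variable = v, roi = roi, f_stat = gt$f_stat,
          df_between = gt$df_between, df_within = gt$df_within, p = gt$p,
          stringsAsFactors = FALSE
        )
      } else {
        note("anova", sprintf("%s %s: not enough groups", v, roi))
      }
      stage_seed <- stage_seed + 1L
      ct <- capture("cutpoint",
                    contrast_table(sub, v, rois = roi, contrasts = config$contrasts,
                                   bootstrap_n = config$bootstrap_n,
                                   seed = derive_seed(config$seed, stage_seed)))
      if (nrow(ct)) cutpoint_rows[[length(cutpoint_rows) + 1L]] <- ct
    }
  }
  anova_table <- if (length(anova_rows)) do.call(rbind, anova_rows) else data.frame()
  cutpoints <- if (length(cutpoint_rows)) do.call(rbind, cutpoint_rows) else data.frame()
  rownames(cutpoints) <- NULL

  # --- association stage -----------------------------------------------
  associations <- data.frame()
  if (!is.null(clinical)) {
    joined <- join_clinical(folded, clinical)
    assoc <- lapply(config$variables, function(v) {
      association_table(joined, v, measures = config$clinical_measures,
                        rois = "hemisphere")
    })
    associations <- do.call(rbind, assoc)
    rownames(associations) <- NULL
  }

  # --- report ----------------------------------------------------------
  result <- structure(list(
    folded = folded,
    scaling_fit = scaling_fit,
    age_models = age_models,
    age_correlations = age_correlations,
    anova = anova_table,
    cutpoints = cutpoints,
    associations = associations,
    ground_truth = ground_truth,
    warnings = warnings_log,
    config = config
  ), class = "folding_analysis")
  result$report <- build_run_report(result)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_table(folded, config$output_dir, "folding_variables.csv")
    if (nrow(anova_table)) write_csv_table(anova_table, config$output_dir, "anova.csv")
    if (nrow(cutpoints)) write_csv_table(cutpoints, config$output_dir, "cutpoints.csv")
    if (nrow(associations)) write_csv_table(associations, config$output_dir, "associations.csv")
    jsonlite::write_json(
      list(alpha = scaling_fit$alpha, alpha_se = scaling_fit$alpha_se,
           log10_k = scaling_fit$intercept, r_squared = scaling_fit$r_squared,
           n = scaling_fit$n, t_vs_theory = scaling_fit$t_vs_theory,
           p_two_tailed = scaling_fit$p_two_tailed),
      file.path(config$output_dir, "scaling_fit.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(result$report,
                         file.path(config$output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}

build_run_report <- function(result) {
  config <- result$config
  cfg_serial <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_serial))
  serialisable <- config[!vapply(config, is.function, TRUE)]
  serialisable$output_dir <- NULL  # hash identifies the analysis, not the destination
  serialisable$simulate <- if (!is.null(config$simulate)) unclass(config$simulate) else NULL
  serialisable$morphometry <- if (!is.null(config$morphometry)) "inline-data" else NULL
  serialisable$clinical <- if (!is.null(config$clinical)) "inline-data" else NULL
  jsonlite::write_json(serialisable, cfg_serial, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  list(
    package_version = as.character(utils::packageVersion("foldlaw")),
    config_hash = unname(tools::md5sum(cfg_serial)),
    seed = config$seed,
    alpha = result$scaling_fit$alpha,
    r_squared = result$scaling_fit$r_squared,
    n_observations = nrow(result$folded),
    tables = list(
      anova_rows = nrow(result$anova),
      cutpoint_rows = nrow(result$cutpoints),
      association_rows = nrow(result$associations)
    ),
    warnings = result$warnings
  )
}

#' @export
print.folding_analysis <- function(x, ...) {
  cat("Cortical folding analysis\n")
  cat("-------------------------\n")
  print(x$scaling_fit)
  if (length(x$age_correlations)) {
    for (v in names(x$age_correlations)) {
      ac <- x$age_correlations[[v]]
      cat(sprintf("Age effect on %s (fit group): r = %.3f, df = %d, p = %.3g, d = %.3f\n",
                  v, ac$r, ac$df, ac$p, ac$d))
    }
  }
  if (nrow(x$anova)) {
    cat("Group ANOVA (per variable x ROI):\n")
    print(utils::head(x$anova, 10), row.names = FALSE)
  }
  if (nrow(x$cutpoints)) {
    cat("Optimal cut-points:\n")
    print(utils::head(x$cutpoints[, c("roi", "variable", "contrast", "cutpoint",
                                      "auc", "accuracy", "sensitivity", "specificity")], 10),
          row.names = FALSE)
  }
  if (length(x$warnings)) cat(length(x$warnings), "stage warning(s); see $warnings\n")
  invisible(x)
}
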