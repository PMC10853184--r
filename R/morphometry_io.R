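#' Validate a regional morphometry table
#'
#' Checks the long-format morphometry schema used throughout the package:
#' one row per (subject, hemisphere, ROI) with average cortical thickness
#' (mm), total pial area (mm^2), exposed hull area (mm^2) and the integrated
#' Gaussian curvature of the exposed patch (4*pi for a closed
#' hemisphere-equivalent surface).
#'
#' Invariants enforced: all morphometric fields strictly positive;
#' `total_area_mm2 >= exposed_area_mm2` (a pial surface cannot be smaller
#' than its hull); `(subject_id, hemisphere, roi)` unique; `diagnosis` in
#' CTL/MCI/AD, `sex` in F/M, `hemisphere` in L/R, `roi` in
#' hemisphere/frontal/occipital/parietal/temporal.
#'
#' @param data data.frame with the columns listed in [read_morphometry()].
#' @return `data` invisibly, with enum columns normalised to character.
#' @export
validate_morphometry <- function(data) {
  if (!is.data.frame(data)) {
    stop_foldlaw("morphometry input must be a data.frame", class = "foldlaw_schema_error")
  }
  missing_cols <- setdiff(MORPHO_COLUMNS, names(data))
  if (length(missing_cols)) {
    stop_foldlaw("missing required column(s): ", paste(missing_cols, collapse = ", "),
                 class = "foldlaw_schema_error")
  }
  data$subject_id <- as.character(data$subject_id)
  for (col in c("diagnosis", "sex", "hemisphere", "roi")) data[[col]] <- as.character(data[[col]])

  check_enum <- function(col, levels) {
    bad <- !data[[col]] %in% levels
    if (any(bad)) {
      stop_foldlaw("invalid ", col, " value(s): ",
                   paste(unique(data[[col]][bad]), collapse = ", "),
                   " (allowed: ", paste(levels, collapse = ", "), ")",
                   class = "foldlaw_validation_error")
    }
  }
  check_enum("diagnosis", DIAGNOSIS_LEVELS)
  check_enum("sex", c("F", "M"))
  check_enum("hemisphere", HEMISPHERE_LEVELS)
  check_enum("roi", ROI_LEVELS)

  positive_cols <- c("avg_thickness_mm", "total_area_mm2", "exposed_area_mm2",
                     "integrated_gaussian_curvature")
  for (col in positive_cols) {
    v <- data[[col]]
    bad <- !is.finite(v) | v <= 0
    if (any(bad)) {
      i <- which(bad)[1L]
      stop_foldlaw("non-positive or non-finite ", col, " for subject ",
                   data$subject_id[i], " (", data$hemisphere[i], " ", data$roi[i], ")",
                   class = "foldlaw_validation_error")
    }
  }
  if (any(bad_age <- !is.finite(data$age) | data$age <= 0)) {
    stop_foldlaw("non-positive age for subject ", data$subject_id[which(bad_age)[1L]],
                 class = "foldlaw_validation_error")
  }
  if (any(bad_edu <- !is.finite(data$education) | data$education < 0)) {
    stop_foldlaw("negative education for subject ", data$subject_id[which(bad_edu)[1L]],
                 class = "foldlaw_validation_error")
  }
  bad_area <- data$total_area_mm2 < data$exposed_area_mm2
  if (any(bad_area)) {
    i <- which(bad_area)[1L]
    stop_foldlaw("total_area_mm2 < exposed_area_mm2 for subject ", data$subject_id[i],
                 " (", data$hemisphere[i], " ", data$roi[i], ")",
                 class = "foldlaw_validation_error")
  }
  key <- paste(data$subject_id, data$hemisphere, data$roi, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_foldlaw("duplicate (subject_id, hemisphere, roi): ",
                 gsub("\r", " / ", dup, fixed = TRUE),
                 class = "foldlaw_uniqueness_error")
  }
  invisible(data)
}

#' Read a regional morphometry table
#'
#' Reads the long-format CSV/TSV schema: one row per subject x hemisphere x
#' ROI with columns `subject_id, diagnosis, age, sex, education, hemisphere,
#' roi, avg_thickness_mm, total_area_mm2, exposed_area_mm2,
#' integrated_gaussian_curvature`. Units are fixed at mm and mm^2 (the log
#' terms of the folding variables are scale-dependent); no unit detection is
#' attempted. Every row is validated against the schema invariants; row
#' order is preserved.
#'
#' @param path path to a delimited text file with a header.
#' @param delimiter field delimiter; default `","`, use `"\t"` for TSV.
#' @return data.frame of validated morphometry rows.
#' @seealso [write_morphometry()], [validate_morphometry()]
#' @export
read_morphometry <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    stop_foldlaw("file not found: ", path, class = "foldlaw_io_error")
  }
  # read everything as character first: single-letter enum codes (F, T)
  # must not be coerced to logicals
  data <- utils::read.table(path, header = TRUE, sep = delimiter,
                            stringsAsFactors = FALSE, colClasses = "character",
                            check.names = FALSE)
  numeric_cols <- c("age", "education", "avg_thickness_mm", "total_area_mm2",
                    "exposed_area_mm2", "integrated_gaussian_curvature")
  for (col in intersect(names(data), numeric_cols)) {
    data[[col]] <- as.numeric(data[[col]])
  }
  extra <- setdiff(names(data), MORPHO_COLUMNS)
  for (col in extra) {
    parsed <- suppressWarnings(as.numeric(data[[col]]))
    if (!anyNA(parsed) || any(is.na(parsed) & !nzchar(data[[col]]))) {
      data[[col]] <- parsed
    }
  }
  validate_morphometry(data)
}

#' Write a regional morphometry table
#'
#' Writes the same schema [read_morphometry()] reads, with a deterministic
#' column order and full decimal precision (17 significant digits, so a
#' write/read round trip reproduces every double bit-for-bit).
#'
#' @param records validated morphometry data.frame; must be non-empty.
#' @param path output file path.
#' @param delimiter field delimiter; default `","`.
#' @return `path`, invisibly.
#' @export
write_morphometry <- function(records, path, delimiter = ",") {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_foldlaw("records must be a non-empty data.frame", class = "foldlaw_validation_error")
  }
  records <- validate_morphometry(records)
  extra <- setdiff(names(records), MORPHO_COLUMNS)
  out <- records[, c(MORPHO_COLUMNS, extra), drop = FALSE]
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
    }
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop_foldlaw("cannot write to ", path, ": ", conditionMessage(ok),
                 class = "foldlaw_io_error")
  }
  invisible(path)
}

#' Read a clinical / CSF table
#'
#' Reads per-subject behavioral and cerebrospinal-fluid measures. Empty
#' cells are kept as `NA` (missing, never imputed). When both components are
#' present, derived columns are checked for consistency:
#' `ravlt_ratio = ravlt_a7 / ravlt_a5` and `tmt_b_minus_a = tmt_b - tmt_a`;
#' absent derived columns are filled in from their components.
#'
#' @param path path to a delimited text file with a `subject_id` column.
#' @param delimiter field delimiter; default `","`.
#' @return data.frame of clinical records, one row per subject.
#' @export
read_clinical <- function(path, delimiter = ",") {
  if (!file.exists(path)) {
    stop_foldlaw("file not found: ", path, class = "foldlaw_io_error")
  }
  data <- utils::read.table(path, header = TRUE, sep = delimiter,
                            stringsAsFactors = FALSE, na.strings = c("NA", ""),
                            check.names = FALSE)
  validate_clinical(data)
}

#' @rdname read_clinical
#' @param data clinical data.frame to validate in place of a file.
#' @export
validate_clinical <- function(data) {
  if (!"subject_id" %in% names(data)) {
    stop_foldlaw("clinical table lacks subject_id", class = "foldlaw_schema_error")
  }
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) {
    stop_foldlaw("duplicate subject_id in clinical table: ",
                 data$subject_id[duplicated(data$subject_id)][1L],
                 class = "foldlaw_uniqueness_error")
  }
  has <- function(col) col %in% names(data)
  if (has("ravlt_a5") && has("ravlt_a7")) {
    expect <- ifelse(!is.na(data$ravlt_a5) & data$ravlt_a5 > 0,
                     data$ravlt_a7 / data$ravlt_a5, NA_real_)
    if (!has("ravlt_ratio")) {
      data$ravlt_ratio <- expect
    } else {
      both <- !is.na(data$ravlt_ratio) & !is.na(expect)
      if (any(both) && any(abs(data$ravlt_ratio[both] - expect[both]) > 1e-6)) {
        stop_foldlaw("ravlt_ratio inconsistent with ravlt_a7 / ravlt_a5",
                     class = "foldlaw_validation_error")
      }
    }
  }
  if (has("tmt_a") && has("tmt_b")) {
    expect <- data$tmt_b - data$tmt_a
    if (!has("tmt_b_minus_a")) {
      data$tmt_b_minus_a <- expect
    } else {
      both <- !is.na(data$tmt_b_minus_a) & !is.na(expect)
      if (any(both) && any(abs(data$tmt_b_minus_a[both] - expect[both]) > 1e-6)) {
        stop_foldlaw("tmt_b_minus_a inconsistent with tmt_b - tmt_a",
                     class = "foldlaw_validation_error")
      }
    }
  }
  data
}

#' Left-join clinical records onto morphometry rows
#'
#' Joins by `subject_id`; every morphometry row is kept and clinical fields
#' for unmatched subjects are `NA` (flagged missing, never zero). The
#' clinical table must have unique subject ids.
#'
#' @param morpho validated morphometry data.frame.
#' @param clinical clinical data.frame with one row per subject.
#' @return data.frame: morphometry columns followed by clinical columns.
#' @export
join_clinical <- function(morpho, clinical) {
  morpho <- validate_morphometry(morpho)
  clinical <- validate_clinical(clinical)
  morpho$.row_order <- seq_len(nrow(morpho))
  merged <- merge(morpho, clinical, by = "subject_id", all.x = TRUE,
                  sort = FALSE, suffixes = c("", ".clinical"))
  merged <- merged[order(merged$.row_order), , drop = FALSE]
  merged$.row_order <- NULL
  rownames(merged) <- NULL
  merged
}
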