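#' Compute gyrification variables from regional morphometry
#'
#' Appends the folding variables of the universal cortical folding model to a
#' morphometry table. With `A_T` the total (pial) area in mm^2, `A_E` the
#' exposed hull area in mm^2 and `T` the average cortical thickness in mm,
#' all logarithms base 10:
#'
#' \deqn{K = \log_{10} k = \log_{10} A_T - \frac{5}{4}\log_{10} A_E +
#'   \frac{1}{4}\log_{10} T^2}
#' \deqn{S = \frac{3}{2}\log_{10} A_T - \frac{3}{4}\log_{10} A_E -
#'   \frac{9}{4}\log_{10} T^2}
#' \deqn{I = \log_{10} A_T + \log_{10} A_E + \log_{10} T^2}
#'
#' `K` is the log offset of the scaling law (interpreted as axonal tension
#' and used here as the neurodegeneration biomarker), `S` a shape-complexity
#' axis and `I` an isometric-volume axis. The classical gyrification index
#' `GI = A_T / A_E` and `log10(T)` are appended as well.
#'
#' Note on `S`: the coefficient vector above, as published, is not orthogonal
#' to `K`'s or `I`'s over `(log10 A_T, log10 A_E, log10 T^2)` even though the
#' three axes are described as perpendicular. `s_orthogonal = TRUE` switches
#' to the variant `(3/2, 3/4, -9/4)`, which is orthogonal to both; the
#' default reproduces the published definition.
#'
#' Lobar rows should be passed through [curvature_correct()] first so that
#' partition size effects are removed before `K` is computed.
#'
#' @param data morphometry data.frame (see [read_morphometry()]).
#' @param s_orthogonal logical; use the orthogonalised `S` variant.
#' @return `data` with columns `K`, `k`, `S`, `I`, `gi`, `log10_thickness`
#'   appended.
#' @examples
#' ctl <- data.frame(
#'   subject_id = "ctl-mean", diagnosis = "CTL", age = 66, sex = "F",
#'   education = 15, hemisphere = "L", roi = "hemisphere",
#'   avg_thickness_mm = 2.5, total_area_mm2 = 98000, exposed_area_mm2 = 37000,
#'   integrated_gaussian_curvature = 4 * pi
#' )
#' compute_folding(ctl)[, c("K", "k", "gi")]
#' @export
compute_folding <- function(data, s_orthogonal = FALSE) {
  data <- validate_morphometry(data)
  lat <- log10(data$total_area_mm2)
  lae <- log10(data$exposed_area_mm2)
  lt2 <- log10(data$avg_thickness_mm^2)
  data$K <- lat - 5 / 4 * lae + 1 / 4 * lt2
  data$k <- 10^data$K
  s_coef <- if (s_orthogonal) c(3 / 2, 3 / 4, -9 / 4) else c(3 / 2, -3 / 4, -9 / 4)
  data$S <- s_coef[1] * lat + s_coef[2] * lae + s_coef[3] * lt2
  data$I <- lat + lae + lt2
  data$gi <- data$total_area_mm2 / data$exposed_area_mm2
  data$log10_thickness <- log10(data$avg_thickness_mm)
  data
}

#' Correct lobar areas by integrated Gaussian curvature
#'
#' A lobe is a patch of the cortical surface, so its raw areas carry a
#' partition-size effect: a patch covering a fraction of the closed surface
#' has proportionally less integrated Gaussian curvature than the full
#' hemisphere's 4*pi (Gauss-Bonnet). Multiplying both areas by
#' `4 * pi / integrated_gaussian_curvature` rescales the patch to a
#' hemisphere-equivalent closed surface, making lobar and hemispheric
#' folding variables directly comparable. The same factor is applied to
#' `total_area_mm2` and `exposed_area_mm2`; thickness and the stored
#' curvature are untouched. Apply before [compute_folding()] for lobar rows.
#'
#' @param data morphometry data.frame; lobar rows are corrected, hemisphere
#'   rows are passed through unchanged with a warning.
#' @return `data` with corrected areas and a logical `curvature_corrected`
#'   column.
#' @export
curvature_correct <- function(data) {
  data <- validate_morphometry(data)
  is_hemi <- data$roi == "hemisphere"
  if (any(is_hemi)) {
    warning("curvature_correct: ", sum(is_hemi),
            " hemisphere row(s) left unchanged (correction applies to lobes)")
  }
  factor <- 4 * pi / data$integrated_gaussian_curvature
  factor[is_hemi] <- 1
  data$total_area_mm2 <- data$total_area_mm2 * factor
  data$exposed_area_mm2 <- data$exposed_area_mm2 * factor
  data$curvature_corrected <- !is_hemi
  data
}
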