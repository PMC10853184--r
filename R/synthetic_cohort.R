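#' Specification for a synthetic three-group cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate
#' the elderly clinical cohort the analysis is designed for: 77 healthy
#' controls (age 66 +/- 8.4 y), 31 mild cognitive impairment (72 +/- 4.8 y)
#' and 13 Alzheimer's disease subjects (77 +/- 6.1 y), with group folding
#' parameters K = -0.52 +/- 0.014, -0.53 +/- 0.014 and -0.55 +/- 0.015,
#' thickness 2.5/2.5/2.4 mm, exposed area centred on 37000 mm^2, a linear
#' K-age slope of -5e-4 per year, and behavioral / CSF measures drawn as
#' Gaussians correlated with each subject's K deviation.
#'
#' The simulated primitive is K, not total area: per hemisphere the total
#' pial area is solved from the scaling law
#' `log10(A_T) = K + alpha * log10(A_E) - 1/2 * log10(T)`, so the law holds
#' by construction (exactly, when `alpha = 1.25`). Each subject's two
#' hemispheres share a latent K; `hemisphere_noise_prop` is the fraction of
#' the K variance assigned to independent hemisphere noise (default 0.5).
#' Lobar rows are patches with area share `lobes$share`, integrated Gaussian
#' curvature `share * 4 * pi`, and lobe-specific K offsets, constructed so
#' that [curvature_correct()] + [compute_folding()] recover the intended
#' lobar K.
#'
#' @param n named vector of subjects per group, `c(CTL = , MCI = , AD = )`.
#' @param seed default seed stored in the spec (can be overridden in
#'   [generate_cohort()]).
#' @param alpha scaling-law exponent used to solve for total area.
#' @param k_age_slope K units per year of age (negative: folding declines).
#' @param hemisphere_noise_prop fraction of K variance that is
#'   hemisphere-specific, in [0, 1).
#' @param include_lobes generate the four lobar ROIs as well as hemispheres.
#' @param ad_mixture logical; if `TRUE`, half the AD subjects get an extra
#'   downward K offset (`ad_mixture_offset`), emulating a bimodal
#'   severely-affected subgroup. Default off.
#' @param ad_mixture_offset extra K offset for the affected AD subcomponent.
#' @return object of class `"cohort_spec"`; a list whose fields (`groups`,
#'   `shared`, `lobes`, `clinical`, ...) may be edited before generation.
#' @export
cohort_spec <- function(n = c(CTL = 77, MCI = 31, AD = 13),
                        seed = NULL,
                        alpha = 1.25,
                        k_age_slope = -5e-4,
                        hemisphere_noise_prop = 0.5,
                        include_lobes = TRUE,
                        ad_mixture = FALSE,
                        ad_mixture_offset = -0.02) {
  n <- n[DIAGNOSIS_LEVELS[DIAGNOSIS_LEVELS %in% names(n)]]
  groups <- data.frame(
    diagnosis = c("CTL", "MCI", "AD"),
    n = c(77, 31, 13),
    age_mean = c(66, 72, 77), age_sd = c(8.4, 4.8, 6.1),
    k_mean = c(-0.52, -0.53, -0.55), k_sd = c(0.014, 0.014, 0.015),
    thickness_mean = c(2.5, 2.5, 2.4), thickness_sd = c(0.099, 0.088, 0.079),
    education_mean = c(15, 13, 13), education_sd = c(2.2, 2.4, 3.0),
    female_frac = c(0.69, 0.61, 0.62),
    csf_n = c(29, 13, 6),
    stringsAsFactors = FALSE
  )
  groups <- groups[groups$diagnosis %in% names(n), , drop = FALSE]
  groups$n <- as.integer(n[groups$diagnosis])
  groups$csf_n <- pmin(groups$csf_n, groups$n)

  clinical <- list(
    cognitive_index = list(mean = c(0.21, -1.5, -3.4), sd = c(0.64, 1.3, 1.5),
                           rho = 0.41, min = -Inf, csf = FALSE),
    ravlt_ratio = list(mean = c(0.82, 0.53, 0.24), sd = c(0.18, 0.31, 0.31),
                       rho = 0.36, min = 0.01, csf = FALSE),
    tmt_b_minus_a = list(mean = c(59, 130, 230), sd = c(48, 110, 130),
                         rho = -0.30, min = 5, csf = FALSE),
    digit_span_backward = list(mean = c(5.8, 4.6, 3.8), sd = c(1.7, 1.6, 1.4),
                               rho = 0.25, min = 0, csf = FALSE),
    csf_lipoxin = list(mean = c(130, 120, 79), sd = c(62, 51, 74),
                       rho = 0.11, min = 1, csf = TRUE),
    csf_abeta40 = list(mean = c(4200, 5000, 5700), sd = c(1900, 2600, 1700),
                       rho = -0.073, min = 100, csf = TRUE),
    csf_abeta42 = list(mean = c(530, 450, 280), sd = c(240, 320, 60),
                       rho = 0.26, min = 50, csf = TRUE),
    csf_ttau = list(mean = c(350, 470, 630), sd = c(190, 200, 280),
                    rho = -0.26, min = 20, csf = TRUE)
  )
  keep <- match(groups$diagnosis, c("CTL", "MCI", "AD"))
  clinical <- lapply(clinical, function(m) {
    m$mean <- m$mean[keep]; m$sd <- m$sd[keep]; m
  })

  structure(list(
    groups = groups,
    shared = list(
      alpha = alpha,
      k_age_slope = k_age_slope,
      log10_exposed_mean = log10(37000),
      log10_exposed_sd = 0.028,
      hemisphere_noise_prop = hemisphere_noise_prop,
      reference_age = sum(groups$n * groups$age_mean) / sum(groups$n),
      age_range = c(45, 95),
      min_thickness = 1.2
    ),
    lobes = list(
      share = c(frontal = 0.35, occipital = 0.15, parietal = 0.25, temporal = 0.25),
      k_offset = c(frontal = 0.06, occipital = 0.18, parietal = 0.19, temporal = 0.19),
      k_extra_sd_mult = 1.0,
      thickness_jitter_sd = 0.05
    ),
    clinical = clinical,
    aux = list(
      ravlt_a5 = list(mean = c(10, 8, 7)[keep], sd = c(2, 2, 2)[keep], min = 1),
      tmt_a = list(mean = c(50, 70, 90)[keep], sd = c(15, 25, 30)[keep], min = 10)
    ),
    include_lobes = include_lobes,
    ad_mixture = ad_mixture,
    ad_mixture_offset = ad_mixture_offset,
    seed = seed
  ), class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop_foldlaw("spec must be a cohort_spec", class = "foldlaw_validation_error")
  }
  g <- spec$groups
  if (nrow(g) < 1L || any(g$n < 1L)) {
    stop_foldlaw("each requested group needs n >= 1", class = "foldlaw_validation_error")
  }
  sds <- c(g$age_sd, g$k_sd, g$thickness_sd, g$education_sd,
           spec$shared$log10_exposed_sd)
  if (any(sds < 0)) {
    stop_foldlaw("all standard deviations must be >= 0", class = "foldlaw_validation_error")
  }
  p <- spec$shared$hemisphere_noise_prop
  if (p < 0 || p >= 1) {
    stop_foldlaw("hemisphere_noise_prop must be in [0, 1)", class = "foldlaw_validation_error")
  }
  rhos <- vapply(spec$clinical, function(m) m$rho, 0.0)
  if (any(abs(rhos) >= 1)) {
    stop_foldlaw("clinical correlations must satisfy |rho| < 1",
                 class = "foldlaw_validation_error")
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification:\n")
  print(x$groups[, c("diagnosis", "n", "age_mean", "age_sd", "k_mean", "k_sd")],
        row.names = FALSE)
  cat(sprintf("  alpha = %.3f, K age slope = %.2g / yr, reference age = %.1f y\n",
              x$shared$alpha, x$shared$k_age_slope, x$shared$reference_age))
  cat(sprintf("  lobes: %s\n", if (x$include_lobes) "yes" else "no"))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a full morphometry table (one row per subject x hemisphere x ROI)
#' and a per-subject clinical table from a [cohort_spec()], together with a
#' ground-truth record of the generating parameters for parameter-recovery
#' tests. Fully reproducible: the same spec and seed give byte-identical
#' tables.
#'
#' Generation, per subject: age is drawn from the group's Gaussian; a latent
#' subject K is `group mean + slope * (age - reference age) + subject
#' noise`; each hemisphere adds independent hemisphere noise; exposed area
#' (log10-Gaussian) and thickness are drawn; total area is solved from the
#' scaling law so the law holds by construction. Clinical measures are
#' Gaussians correlated (at the spec's `rho`) with the subject's
#' age-detrended K deviation; CSF measures are restricted to the first
#' `csf_n` subjects per group, the rest `NA`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`. Required.
#' @return list with class `"synthetic_cohort"`: `morphometry` (validated
#'   morphometry data.frame), `clinical` (one row per subject), and
#'   `ground_truth` (see [ground_truth_report()]).
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  if (is.null(seed)) {
    stop_foldlaw("a seed is required (set it in cohort_spec() or pass seed=)",
                 class = "foldlaw_validation_error")
  }
  with_seed(seed, generate_cohort_impl(spec, seed))
}

generate_cohort_impl <- function(spec, seed) {
  sh <- spec$shared
  morpho_rows <- list()
  clin_rows <- list()

  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    n <- g$n
    id <- sprintf("%s-%03d", tolower(g$diagnosis), seq_len(n))
    age <- pmin(pmax(stats::rnorm(n, g$age_mean, g$age_sd), sh$age_range[1]),
                sh$age_range[2])
    sex <- ifelse(stats::runif(n) < g$female_frac, "F", "M")
    education <- pmax(stats::rnorm(n, g$education_mean, g$education_sd), 8)

    s_subj <- g$k_sd * sqrt(1 - sh$hemisphere_noise_prop)
    s_hemi <- g$k_sd * sqrt(sh$hemisphere_noise_prop)
    k_noise <- stats::rnorm(n, 0, s_subj)
    k_trend <- g$k_mean + sh$k_age_slope * (age - sh$reference_age)
    k_subj <- k_trend + k_noise
    if (isTRUE(spec$ad_mixture) && g$diagnosis == "AD") {
      affected <- stats::runif(n) < 0.5
      k_subj[affected] <- k_subj[affected] + spec$ad_mixture_offset
    }
    z_k <- if (s_subj > 0) k_noise / s_subj else rep(0, n)

    for (hemi in HEMISPHERE_LEVELS) {
      k_hem <- k_subj + stats::rnorm(n, 0, s_hemi)
      lae <- stats::rnorm(n, sh$log10_exposed_mean, sh$log10_exposed_sd)
      thick <- pmax(stats::rnorm(n, g$thickness_mean, g$thickness_sd),
                    sh$min_thickness)
      lat <- k_hem + sh$alpha * lae - 0.5 * log10(thick)
      morpho_rows[[length(morpho_rows) + 1L]] <- data.frame(
        subject_id = id, diagnosis = g$diagnosis, age = age, sex = sex,
        education = education, hemisphere = hemi, roi = "hemisphere",
        avg_thickness_mm = thick, total_area_mm2 = 10^lat,
        exposed_area_mm2 = 10^lae,
        integrated_gaussian_curvature = 4 * pi,
        stringsAsFactors = FALSE
      )
      if (isTRUE(spec$include_lobes)) {
        for (lobe in names(spec$lobes$share)) {
          share <- spec$lobes$share[[lobe]]
          k_lobe <- k_hem + spec$lobes$k_offset[[lobe]] +
            stats::rnorm(n, 0, spec$lobes$k_extra_sd_mult * g$k_sd)
          lae_corr <- stats::rnorm(n, sh$log10_exposed_mean, sh$log10_exposed_sd)
          t_lobe <- pmax(thick + stats::rnorm(n, 0, spec$lobes$thickness_jitter_sd),
                         sh$min_thickness)
          lat_corr <- k_lobe + sh$alpha * lae_corr - 0.5 * log10(t_lobe)
          morpho_rows[[length(morpho_rows) + 1L]] <- data.frame(
            subject_id = id, diagnosis = g$diagnosis, age = age, sex = sex,
            education = education, hemisphere = hemi, roi = lobe,
            avg_thickness_mm = t_lobe,
            total_area_mm2 = share * 10^lat_corr,
            exposed_area_mm2 = share * 10^lae_corr,
            integrated_gaussian_curvature = share * 4 * pi,
            stringsAsFactors = FALSE
          )
        }
      }
    }

    clin <- data.frame(subject_id = id, stringsAsFactors = FALSE)
    for (m in names(spec$clinical)) {
      par <- spec$clinical[[m]]
      eps <- stats::rnorm(n)
      val <- par$mean[gi] + par$sd[gi] * (par$rho * z_k + sqrt(1 - par$rho^2) * eps)
      val <- pmax(val, par$min)
      if (par$csf) val[seq_len(n) > g$csf_n] <- NA_real_
      clin[[m]] <- val
    }
    a5 <- pmax(stats::rnorm(n, spec$aux$ravlt_a5$mean[gi], spec$aux$ravlt_a5$sd[gi]),
               spec$aux$ravlt_a5$min)
    tmt_a <- pmax(stats::rnorm(n, spec$aux$tmt_a$mean[gi], spec$aux$tmt_a$sd[gi]),
                  spec$aux$tmt_a$min)
    clin$ravlt_a5 <- a5
    clin$ravlt_a7 <- clin$ravlt_ratio * a5
    clin$tmt_a <- tmt_a
    clin$tmt_b <- tmt_a + clin$tmt_b_minus_a
    clin_rows[[length(clin_rows) + 1L]] <- clin
  }

  morphometry <- do.call(rbind, morpho_rows)
  # canonical row order: group block, then subject, hemisphere, ROI
  ord <- order(match(morphometry$diagnosis, spec$groups$diagnosis),
               morphometry$subject_id, morphometry$hemisphere,
               match(morphometry$roi, ROI_LEVELS))
  morphometry <- morphometry[ord, , drop = FALSE]
  rownames(morphometry) <- NULL
  clinical <- do.call(rbind, clin_rows)
  rownames(clinical) <- NULL

  structure(list(
    morphometry = validate_morphometry(morphometry),
    clinical = clinical,
    ground_truth = ground_truth_report(spec, seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d morphometry rows (%d subjects), seed %s\n",
              nrow(x$morphometry), nrow(x$clinical),
              format(x$ground_truth$seed)))
  print(table(diagnosis = x$morphometry$diagnosis, roi = x$morphometry$roi))
  invisible(x)
}

#' Ground-truth parameter record for a synthetic cohort
#'
#' Emits the exact generating parameters of [generate_cohort()] — one key
#' per stochastic element — so that pipeline estimates can be checked
#' against the values that generated the data.
#'
#' @param spec a [cohort_spec()].
#' @param seed the seed the cohort was (or will be) generated with.
#' @return named list: `alpha`, `k_age_slope`, `reference_age`, per-group
#'   parameter vectors, exposed-area log-normal parameters, hemisphere
#'   noise split, lobe geometry/offsets, clinical means/SDs/correlations,
#'   auxiliary score parameters, mixture settings and `seed`.
#' @export
ground_truth_report <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  g <- spec$groups
  list(
    alpha = spec$shared$alpha,
    k_age_slope = spec$shared$k_age_slope,
    reference_age = spec$shared$reference_age,
    group_n = stats::setNames(g$n, g$diagnosis),
    group_age_mean = stats::setNames(g$age_mean, g$diagnosis),
    group_age_sd = stats::setNames(g$age_sd, g$diagnosis),
    group_k_mean = stats::setNames(g$k_mean, g$diagnosis),
    group_k_sd = stats::setNames(g$k_sd, g$diagnosis),
    group_thickness_mean = stats::setNames(g$thickness_mean, g$diagnosis),
    group_thickness_sd = stats::setNames(g$thickness_sd, g$diagnosis),
    group_education_mean = stats::setNames(g$education_mean, g$diagnosis),
    group_education_sd = stats::setNames(g$education_sd, g$diagnosis),
    group_female_frac = stats::setNames(g$female_frac, g$diagnosis),
    group_csf_n = stats::setNames(g$csf_n, g$diagnosis),
    log10_exposed_mean = spec$shared$log10_exposed_mean,
    log10_exposed_sd = spec$shared$log10_exposed_sd,
    hemisphere_noise_prop = spec$shared$hemisphere_noise_prop,
    age_range = spec$shared$age_range,
    min_thickness = spec$shared$min_thickness,
    lobe_share = spec$lobes$share,
    lobe_k_offset = spec$lobes$k_offset,
    lobe_k_extra_sd_mult = spec$lobes$k_extra_sd_mult,
    lobe_thickness_jitter_sd = spec$lobes$thickness_jitter_sd,
    clinical_mean = lapply(spec$clinical, function(m) stats::setNames(m$mean, g$diagnosis)),
    clinical_sd = lapply(spec$clinical, function(m) stats::setNames(m$sd, g$diagnosis)),
    clinical_rho = vapply(spec$clinical, function(m) m$rho, 0.0),
    aux_ravlt_a5 = spec$aux$ravlt_a5,
    aux_tmt_a = spec$aux$tmt_a,
    ad_mixture = spec$ad_mixture,
    ad_mixture_offset = spec$ad_mixture_offset,
    include_lobes = spec$include_lobes,
    seed = seed
  )
}
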