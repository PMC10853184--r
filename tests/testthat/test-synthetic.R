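test_that("generation is byte-deterministic under a fixed seed", {
  spec <- cohort_spec(n = c(CTL = 15, MCI = 6, AD = 4), seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$morphometry, b$morphometry)
  expect_identical(a$clinical, b$clinical)
  c <- generate_cohort(spec, seed = 10)
  expect_false(identical(a$morphometry, c$morphometry))
})

test_that("zero K-noise and zero slope make K the group mean exactly", {
  spec <- cohort_spec(n = c(CTL = 8, AD = 4), seed = 2, k_age_slope = 0)
  spec$groups$k_sd <- 0
  cohort <- generate_cohort(spec)
  folded <- compute_folding(correct_lobes(cohort$morphometry))
  means <- cohort$ground_truth$group_k_mean
  offsets <- c(hemisphere = 0, cohort$ground_truth$lobe_k_offset)
  expected <- means[folded$diagnosis] + offsets[folded$roi]
  expect_equal(folded$K, unname(expected), tolerance = 1e-9)
})

test_that("generated morphometry satisfies the scaling law by construction", {
  cohort <- generate_cohort(cohort_spec(n = c(CTL = 20, MCI = 8, AD = 5), seed = 13))
  hemi <- cohort$morphometry[cohort$morphometry$roi == "hemisphere", ]
  folded <- compute_folding(hemi)
  # law residual: log10(T^1/2 A_T) - (K + alpha log10 A_E) = 0 identically
  resid <- log10(folded$total_area_mm2) + 0.5 * log10(folded$avg_thickness_mm) -
    (folded$K + cohort$ground_truth$alpha * log10(folded$exposed_area_mm2))
  expect_lt(max(abs(resid)), 1e-9)

  # noiseless 1000-observation cohort recovers alpha to 1e-6
  big <- cohort_spec(n = c(CTL = 500), seed = 3, k_age_slope = 0)
  big$groups$k_sd <- 0
  noiseless <- generate_cohort(big)
  fit <- fit_scaling_law(noiseless$morphometry[noiseless$morphometry$roi == "hemisphere", ])
  expect_equal(fit$alpha, 1.25, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
})

test_that("group K means are calibrated to the cohort summary", {
  # across seeds the CTL hemisphere K mean stays within +-0.005 of -0.52
  nrep <- 60
  means <- vapply(seq_len(nrep), function(i) {
    cohort <- generate_cohort(cohort_spec(seed = 4000 + i))
    m <- cohort$morphometry
    mean(compute_folding(m[m$roi == "hemisphere" & m$diagnosis == "CTL", ])$K)
  }, 0.0)
  expect_lt(abs(mean(means) - (-0.52)), 0.005)
  # each individual cohort stays within a band generous to the per-seed
  # sampling SD (~0.0015) of the 77-subject group mean
  expect_true(all(abs(means - (-0.52)) < 0.01))
})

test_that("invalid specs are rejected", {
  bad <- cohort_spec(seed = 1)
  bad$groups$k_sd[1] <- -0.1
  expect_error(generate_cohort(bad), class = "foldlaw_validation_error")

  bad2 <- cohort_spec(seed = 1)
  bad2$clinical$cognitive_index$rho <- 1.2
  expect_error(generate_cohort(bad2), class = "foldlaw_validation_error")

  bad3 <- cohort_spec(seed = 1, hemisphere_noise_prop = 1)
  expect_error(generate_cohort(bad3), class = "foldlaw_validation_error")

  expect_error(generate_cohort(cohort_spec()), "seed",
               class = "foldlaw_validation_error")
})

test_that("ground truth records every generating parameter", {
  spec <- cohort_spec(seed = 5, k_age_slope = -5e-4)
  gt <- ground_truth_report(spec)
  expect_equal(gt$alpha, 1.25)
  expect_equal(gt$k_age_slope, -5e-4)
  expect_equal(unname(gt$group_n), c(77, 31, 13))

  # a non-default value is recorded verbatim
  spec2 <- cohort_spec(seed = 5, alpha = 1.18, k_age_slope = -0.0005)
  expect_equal(ground_truth_report(spec2)$alpha, 1.18)

  # schema coverage: every stochastic element of the generator has a key
  needed <- c(
    "group_age_mean", "group_age_sd",            # age draw
    "group_k_mean", "group_k_sd",                # K draws (subject + hemisphere)
    "hemisphere_noise_prop",                     # K variance split
    "k_age_slope", "reference_age",              # K age trend
    "group_thickness_mean", "group_thickness_sd",# thickness draw
    "log10_exposed_mean", "log10_exposed_sd",    # exposed-area draw
    "group_female_frac",                         # sex draw
    "group_education_mean", "group_education_sd",# education draw
    "lobe_share", "lobe_k_offset",               # lobe construction
    "lobe_k_extra_sd_mult", "lobe_thickness_jitter_sd",
    "clinical_mean", "clinical_sd", "clinical_rho", # clinical draws
    "group_csf_n",                               # CSF missingness
    "aux_ravlt_a5", "aux_tmt_a",                 # raw-score decomposition
    "ad_mixture", "ad_mixture_offset",           # AD mixture switch
    "seed"
  )
  expect_true(all(needed %in% names(gt)))
})

test_that("clinical measures carry the planted correlation with K", {
  # within controls, corr(measure, age-detrended subject K) should match
  # rho attenuated by the hemisphere-noise share of the subject-mean K:
  # att = s_subj / sqrt(s_subj^2 + s_hem^2 / 2)
  spec <- cohort_spec(n = c(CTL = 2000), seed = 27)
  cohort <- generate_cohort(spec)
  m <- compute_folding(cohort$morphometry[cohort$morphometry$roi == "hemisphere", ])
  k_subj <- tapply(m$K, m$subject_id, mean)
  detrended <- k_subj - spec$shared$k_age_slope *
    (tapply(m$age, m$subject_id, mean) - spec$shared$reference_age)
  idx <- match(names(detrended), cohort$clinical$subject_id)
  p <- spec$shared$hemisphere_noise_prop
  att <- sqrt(1 - p) / sqrt((1 - p) + p / 2)
  for (meas in c("cognitive_index", "tmt_b_minus_a")) {
    rho <- spec$clinical[[meas]]$rho
    r_hat <- cor(detrended, cohort$clinical[[meas]][idx])
    se <- (1 - (rho * att)^2) / sqrt(length(detrended) - 3)
    expect_lt(abs(r_hat - rho * att), 3 * se)
  }
})

test_that("the AD mixture produces a wider, bimodal-leaning AD group", {
  base <- generate_cohort(cohort_spec(n = c(AD = 600), seed = 8))
  mixed <- generate_cohort(cohort_spec(n = c(AD = 600), seed = 8,
                                       ad_mixture = TRUE,
                                       ad_mixture_offset = -0.05))
  k_base <- compute_folding(base$morphometry[base$morphometry$roi == "hemisphere", ])$K
  k_mix <- compute_folding(mixed$morphometry[mixed$morphometry$roi == "hemisphere", ])$K
  expect_gt(sd(k_mix), sd(k_base))
  expect_lt(mean(k_mix), mean(k_base))
})
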