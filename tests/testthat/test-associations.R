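test_that("r to Cohen's d conversion reproduces the reference pairs", {
  pairs <- rbind(
    c(-0.32, -0.68), c(-0.79, -2.58), c(0.41, 0.90), c(0.36, 0.77),
    c(-0.26, -0.54), c(-0.30, -0.63)
  )
  for (i in seq_len(nrow(pairs))) {
    expect_equal(round(r_to_cohens_d(pairs[i, 1]), 2), pairs[i, 2])
  }
  expect_equal(r_to_cohens_d(0), 0)
  expect_error(r_to_cohens_d(1), class = "foldlaw_domain_error")
  expect_error(r_to_cohens_d(-1.2), class = "foldlaw_domain_error")
})

test_that("r to d is odd, strictly increasing, and invertible", {
  r <- seq(-0.95, 0.95, by = 0.05)
  d <- r_to_cohens_d(r)
  expect_equal(r_to_cohens_d(-r), -d)
  expect_true(all(diff(d) > 0))
  expect_equal(cohens_d_to_r(d), r, tolerance = 1e-12)
})

test_that("published association-table (r, d) pairs are internally consistent", {
  # all 14 rows of the K column of the association table, as a regression
  # fixture: every printed d matches 2r/sqrt(1-r^2) within the table's
  # rounding (+-0.01)
  k_column <- rbind(
    c(0.41, 0.90),    # cognitive index, hemisphere
    c(0.36, 0.77),    # RAVLT A7/A5, hemisphere
    c(0.31, 0.65),    # RAVLT A7/A5, temporal
    c(-0.30, -0.63),  # TMT B-A, hemisphere
    c(-0.21, -0.43),  # TMT B-A, frontal
    c(0.25, 0.52),    # digit span backward, hemisphere
    c(0.21, 0.43),    # digit span backward, frontal
    c(-0.073, -0.15), # CSF abeta 1-40
    c(0.26, 0.54),    # CSF abeta 1-42
    c(-0.26, -0.54),  # CSF t-tau
    c(0.18, 0.37),    # abeta 42/40 ratio
    c(-0.32, -0.68),  # t-tau / abeta42
    c(-0.28, -0.58),  # t-tau / (abeta42/abeta40)
    c(0.11, 0.22)     # CSF lipoxin
  )
  expect_true(all(abs(r_to_cohens_d(k_column[, 1]) - k_column[, 2]) <= 0.01))
})

test_that("correlate computes pairwise-complete r with Bonferroni capping", {
  withr::with_seed(17, {
    x <- rnorm(60)
    y <- 0.5 * x + rnorm(60, 0, 0.8)
  })
  res <- correlate(x, y, family_size = 4)
  expect_equal(res$r, cor(x, y))
  expect_equal(res$d, r_to_cohens_d(res$r))
  expect_equal(res$p_adj, min(1, res$p_raw * 4))
  expect_equal(res$n, 60)

  # missing values drop pairwise
  x[1:10] <- NA
  res2 <- correlate(x, y, family_size = 1)
  expect_equal(res2$n, 50)
  expect_equal(res2$p_adj, res2$p_raw)

  # cap at 1
  noise <- correlate(rnorm(30), rnorm(30), family_size = 500)
  expect_equal(noise$p_adj, 1)

  expect_error(correlate(1:2, 2:3), class = "foldlaw_insufficient_data_error")
  expect_error(correlate(rep(1, 5), rnorm(5)), class = "foldlaw_degenerate_error")
})

test_that("association_table pools diagnoses and sizes the family correctly", {
  cohort <- generate_cohort(cohort_spec(n = c(CTL = 30, MCI = 12, AD = 8), seed = 20))
  folded <- compute_folding(cohort$morphometry[cohort$morphometry$roi == "hemisphere", ])
  joined <- join_clinical(folded, cohort$clinical)
  tab <- association_table(joined, "K",
                           measures = c("cognitive_index", "ravlt_ratio",
                                        "csf_ttau"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$p_adj, pmin(1, tab$p_raw * 3))
  expect_true(all(tab$morph_variable == "K"))
  # the cohort generator plants a positive K / cognition correlation
  expect_gt(tab$r[tab$clinical_measure == "cognitive_index"], 0)
})

test_that("cognitive index averages the four z-scores with TMT sign flipped", {
  norms <- data.frame(
    measure = c("ravlt_a5", "ravlt_a7", "tmt_a", "tmt_b"),
    age_low = 60, age_high = 70,
    mean = c(10, 9, 40, 90), sd = c(2, 2.5, 14, 38)
  )
  at_norm <- data.frame(age = 65, ravlt_a5 = 10, ravlt_a7 = 9,
                        tmt_a = 40, tmt_b = 90)
  expect_equal(cognitive_index(at_norm, norms), 0)

  # memory one SD up, trails one SD faster -> index exactly 1
  better <- data.frame(age = 65, ravlt_a5 = 12, ravlt_a7 = 11.5,
                       tmt_a = 26, tmt_b = 52)
  expect_equal(cognitive_index(better, norms), 1)

  # missing component score propagates NA
  holes <- data.frame(age = 65, ravlt_a5 = 10, ravlt_a7 = NA,
                      tmt_a = 40, tmt_b = 90)
  expect_true(is.na(cognitive_index(holes, norms)))

  # missing age band is an error naming the measure
  out_of_band <- data.frame(age = 95, ravlt_a5 = 10, ravlt_a7 = 9,
                            tmt_a = 40, tmt_b = 90)
  expect_error(cognitive_index(out_of_band, norms), "ravlt_a5",
               class = "foldlaw_norms_error")

  bad_norms <- norms; bad_norms$sd[1] <- 0
  expect_error(cognitive_index(at_norm, bad_norms),
               class = "foldlaw_validation_error")
})

test_that("the synthetic norms cover the simulated age range", {
  norms <- synthetic_norms()
  cohort <- generate_cohort(cohort_spec(n = c(CTL = 20, AD = 8), seed = 33))
  idx <- cognitive_index(cohort$clinical[,
    c("ravlt_a5", "ravlt_a7", "tmt_a", "tmt_b")] |>
      cbind(age = cohort$morphometry$age[match(cohort$clinical$subject_id,
                                               cohort$morphometry$subject_id)]),
    norms)
  expect_length(idx, 28)
  expect_true(all(is.finite(idx)))
})
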