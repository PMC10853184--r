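# Independent oracles and fixture builders used across the suite.

# Build valid morphometry rows from vectors (defaults: one CTL hemisphere).
make_morpho <- function(thickness, total, exposed,
                        subject_id = sprintf("s%03d", seq_along(thickness)),
                        diagnosis = "CTL", age = 66, sex = "F", education = 15,
                        hemisphere = "L", roi = "hemisphere",
                        curvature = 4 * pi) {
  data.frame(
    subject_id = subject_id, diagnosis = diagnosis, age = age, sex = sex,
    education = education, hemisphere = hemisphere, roi = roi,
    avg_thickness_mm = thickness, total_area_mm2 = total,
    exposed_area_mm2 = exposed, integrated_gaussian_curvature = curvature,
    stringsAsFactors = FALSE
  )
}

# Brute-force AUC: count concordant pairs, ties half credit.
# Positive class is "disease"; lower_is_positive means a diseased score
# below a control score is concordant.
auc_pair_counting <- function(scores, labels, direction = "lower_is_positive") {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p == q) 0.5 else if (direction == "lower_is_positive") {
      as.numeric(p < q)
    } else {
      as.numeric(p > q)
    }
  }
  total / (length(pos) * length(neg))
}

# Naive exhaustive cut-point search: evaluate sensitivity/specificity at
# every candidate threshold directly, apply the documented tie-breaks.
cutpoint_exhaustive <- function(scores, labels, direction = "lower_is_positive") {
  labels <- as.logical(labels)
  s <- sort(unique(scores))
  mids <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  cand <- c(-Inf, mids, Inf)
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- spec <- numeric(length(cand))
  for (i in seq_along(cand)) {
    if (direction == "lower_is_positive") {
      sens[i] <- mean(pos <= cand[i]); spec[i] <- mean(neg > cand[i])
    } else {
      sens[i] <- mean(pos >= cand[i]); spec[i] <- mean(neg < cand[i])
    }
  }
  j <- sens + spec
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[sens[best] == max(sens[best])]
  if (length(best) > 1) best <- best[which.min(cand[best])]
  list(cutpoint = cand[best], sensitivity = sens[best], specificity = spec[best])
}

# Curvature-correct the lobar rows of a mixed table, leaving hemispheres.
correct_lobes <- function(m) {
  is_lobe <- m$roi != "hemisphere"
  if (any(is_lobe)) {
    m[is_lobe, ] <- curvature_correct(m[is_lobe, , drop = FALSE])[names(m)]
  }
  m
}

# Direct evaluation of the folding variables from the printed coefficient
# vectors, independent of compute_folding's implementation.
folding_direct <- function(thickness, total, exposed) {
  lat <- log10(total); lae <- log10(exposed); lt2 <- log10(thickness^2)
  list(K = lat - 1.25 * lae + 0.25 * lt2,
       S = 1.5 * lat - 0.75 * lae - 2.25 * lt2,
       I = lat + lae + lt2)
}
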