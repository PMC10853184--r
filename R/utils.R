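# internal helpers shared across modules

DIAGNOSIS_LEVELS <- c("CTL", "MCI", "AD")
HEMISPHERE_LEVELS <- c("L", "R")
ROI_LEVELS <- c("hemisphere", "frontal", "occipital", "parietal", "temporal")
LOBE_LEVELS <- setdiff(ROI_LEVELS, "hemisphere")

MORPHO_COLUMNS <- c(
  "subject_id", "diagnosis", "age", "sex", "education", "hemisphere", "roi",
  "avg_thickness_mm", "total_area_mm2", "exposed_area_mm2",
  "integrated_gaussian_curvature"
)

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stage seed from a root seed; keeps results within 32-bit range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(stage)
}

stop_foldlaw <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "foldlaw_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
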