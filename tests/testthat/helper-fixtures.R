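# shared in-code fixtures

toy_table <- function(n_samples = 4, n_features = 3, space = "immune",
                      unit = "absolute", seed = 1) {
  set.seed(seed)
  m <- matrix(abs(rnorm(n_samples * n_features, 10, 3)), n_samples, n_features)
  rownames(m) <- paste0("s", seq_len(n_samples), ":V1")
  colnames(m) <- paste0("f", seq_len(n_features))
  featureTable(m, space, unit)
}

# minimal three-visit metadata for n subjects (one arm)
toy_metadata <- function(n = 10, seed = 1) {
  set.seed(seed)
  md <- expand.grid(visit = c("V1", "V2", "V3"),
                    subject_id = sprintf("P%02d", seq_len(n)),
                    stringsAsFactors = FALSE)[, 2:1]
  md$sample_id <- paste(md$subject_id, md$visit, sep = ":")
  md$arm <- "fasting+DASH"
  md$age <- rep(round(rnorm(n, 60, 8)), each = 3)
  md$sex <- rep(sample(c("F", "M"), n, TRUE), each = 3)
  md$bmi <- rep(round(rnorm(n, 33, 4), 1), each = 3)
  md
}

# cohort defaults scaled for fast unit tests
small_design <- function(...) {
  cohortDesign(n_subjects_per_arm = 8, n_taxa = 30, n_modules = 10,
               n_immune = 15, n_clinical = 5, med_confounded_features = 4,
               sequencing_depth_mean = 5000, ...)
}
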