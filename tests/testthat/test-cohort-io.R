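test_that("rarefaction conserves depth and never exceeds originals", {
  set.seed(3)
  m <- matrix(rpois(8 * 20, 30), 8, 20,
              dimnames = list(paste0("s", 1:8, ":V1"), paste0("t", 1:20)))
  tab <- featureTable(m, "taxa16S", "counts")
  r <- rarefyTable(tab, depth = 200, seed = 9)
  expect_true(all(rowSums(featureValues(r)) == 200))
  expect_true(all(featureValues(r) <= featureValues(tab)))
  # determinism
  r2 <- rarefyTable(tab, depth = 200, seed = 9)
  expect_identical(featureValues(r), featureValues(r2))
  r3 <- rarefyTable(tab, depth = 200, seed = 10)
  expect_false(identical(featureValues(r), featureValues(r3)))
})

test_that("auto depth is floor of 95% of the smallest library", {
  m <- rbind(`a:V1` = c(60L, 40L), `b:V1` = c(150L, 50L))
  colnames(m) <- c("t1", "t2")
  r <- rarefyTable(featureTable(m, "taxa16S", "counts"), depth = "auto", seed = 1)
  expect_true(all(rowSums(featureValues(r)) == 95))   # floor(0.95 * 100)
})

test_that("full-depth rarefaction is the identity and small samples drop", {
  m <- rbind(`a:V1` = c(30L, 70L), `b:V1` = c(10L, 20L))
  colnames(m) <- c("t1", "t2")
  tab <- featureTable(m, "taxa16S", "counts")
  expect_warning(r <- rarefyTable(tab, depth = 100, seed = 1), "b:V1")
  expect_equal(featureValues(r)["a:V1", ], c(t1 = 30, t2 = 70))
  expect_error(rarefyTable(tab, depth = 100, seed = 1, on_small = "error"), "b:V1")
  # one-taxon table: no subsampling choice exists
  m1 <- matrix(80L, 1, 1, dimnames = list("a:V1", "t1"))
  r1 <- rarefyTable(featureTable(m1, "taxa16S", "counts"), depth = 50, seed = 1)
  expect_equal(unname(featureValues(r1)[1, 1]), 50)
})

test_that("rarefaction is unbiased: mean count tracks depth x proportion", {
  counts <- c(t1 = 500L, t2 = 300L, t3 = 200L)
  m <- matrix(counts, 1, 3, dimnames = list("a:V1", names(counts)))
  tab <- featureTable(m, "taxa16S", "counts")
  draws <- vapply(1:1000, function(s)
    featureValues(rarefyTable(tab, depth = 100, seed = s))[1, "t1"], numeric(1))
  expected <- 100 * 0.5
  se <- sqrt(100 * 0.5 * 0.5 * (1000 - 100) / (1000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("binning averages over the full mapping and sums for rollups", {
  m <- matrix(c(2, 4, 10), 1, 3, dimnames = list("s:V1", c("K1", "K2", "K9")))
  tab <- featureTable(m, "functionalModule", "relative")
  got <- binFeatures(tab, c(K1 = "M1", K2 = "M1"), "mean")
  expect_equal(unname(featureValues(got)[1, "M1"]), 3)
  # an absent member contributes zero under mean binning
  got2 <- binFeatures(tab, c(K1 = "M1", K2 = "M1", K_missing = "M1"), "mean")
  expect_equal(unname(featureValues(got2)[1, "M1"]), 2)
  # singleton group is the identity
  got3 <- binFeatures(tab, c(K9 = "solo"), "mean")
  expect_equal(unname(featureValues(got3)[1, "solo"]), 10)
  # genus rollup sums member species
  sp <- matrix(c(5L, 7L), 1, 2, dimnames = list("s:V1", c("spA", "spB")))
  rolled <- binFeatures(featureTable(sp, "taxa16S", "counts"),
                        c(spA = "genusX", spB = "genusX"), "taxonomic-rollup")
  expect_equal(unname(featureValues(rolled)[1, "genusX"]), 12)
  # empty group excluded with warning
  expect_warning(binFeatures(tab, c(K1 = "M1", K_gone = "M2"), "mean"), "M2")
})

test_that("medication normalization follows the baseline-reference rules", {
  led <- data.frame(subject_id = rep("P1", 6),
                    drug_class = rep(c("diuretics", "beta-blockers"), each = 3),
                    drug = rep(c("hct", "met"), each = 3),
                    visit = rep(c("V1", "V2", "V3"), 2),
                    dose = c(5, 5, 5, 5, 5, 0))
  norm <- normalizeMedication(led, visits = c("V1", "V2", "V3"))
  nn <- norm$normalized
  hct <- nn[nn$drug == "hct", ]
  expect_equal(hct$normalized_dose, c(1, 1, 1))   # unchanged regimen = 1
  met <- nn[nn$drug == "met", ]
  expect_equal(met$normalized_dose[met$visit == "V3"], 0)  # discontinued = 0
  # dose doubling
  led2 <- data.frame(subject_id = "P2", drug_class = "RAS agents", drug = "ram",
                     visit = c("V1", "V3"), dose = c(5, 10))
  n2 <- normalizeMedication(led2, visits = c("V1", "V2", "V3"))$normalized
  expect_equal(n2$normalized_dose[n2$visit == "V3"], 2)
  expect_equal(n2$normalized_dose[n2$visit == "V2"], 0)    # absent record = 0
  # drug initiated mid-study: reference is lowest nonzero dose
  led3 <- data.frame(subject_id = "P3", drug_class = "other antihypertensives",
                     drug = "x", visit = c("V2", "V3"), dose = c(10, 20))
  n3 <- normalizeMedication(led3, visits = c("V1", "V2", "V3"))$normalized
  expect_equal(n3$normalized_dose, c(0, 1, 2))
  # all-zero trajectory dropped with warning
  led4 <- data.frame(subject_id = "P4", drug_class = "diuretics", drug = "z",
                     visit = "V1", dose = 0)
  expect_warning(n4 <- normalizeMedication(led4, visits = c("V1", "V2", "V3")), "P4")
  expect_equal(nrow(n4$normalized), 0)
})

test_that("normalization is idempotent on already-normalized 0/1 doses", {
  led <- data.frame(subject_id = "P1", drug_class = "diuretics", drug = "d",
                    visit = c("V1", "V2", "V3"), dose = c(1, 1, 0))
  n1 <- normalizeMedication(led, visits = c("V1", "V2", "V3"))
  led_renorm <- data.frame(subject_id = "P1", drug_class = "diuretics", drug = "d",
                           visit = n1$normalized$visit, dose = n1$normalized$normalized_dose)
  n2 <- normalizeMedication(led_renorm, visits = c("V1", "V2", "V3"))
  expect_equal(n2$normalized$normalized_dose, n1$normalized$normalized_dose)
})

test_that("medication change classes follow the agent-sum sign", {
  led <- data.frame(subject_id = rep(c("A", "A", "B", "C", "C"), each = 2),
                    drug_class = "diuretics",
                    drug = c("d1", "d1", "d2", "d2", "d3", "d3", "d4", "d4", "d5", "d5"),
                    visit = rep(c("V1", "V3"), 5),
                    dose = c(10, 5, 8, 4,   # A: both halved -> reduced
                             5, 5,          # B: unchanged
                             10, 0, 5, 10)) # C: one stopped, one doubled -> unchanged
  norm <- normalizeMedication(led, visits = c("V1", "V2", "V3"))
  cls <- medicationChangeClass(norm, "V1", "V3")
  expect_equal(unname(cls["A"]), "reduced")
  expect_equal(unname(cls["B"]), "unchanged")
  expect_equal(unname(cls["C"]), "unchanged")
})

test_that("HOMA follows insulin x glucose / 22.5", {
  expect_equal(computeHoma(22.5, 1), 1)
  expect_equal(computeHoma(10, 5), 50 / 22.5)
  expect_equal(computeHoma(0, 5), 0)
  expect_error(computeHoma(-1, 5), "non-negative")
})

test_that("cohort export/import round-trips and handles degenerate sizes", {
  co <- simulateCohort(small_design(seed = 4))
  dir <- withr::local_tempdir()
  exportCohort(co, dir)
  back <- importCohortTables(dir)
  expect_equal(featureValues(back$taxa), featureValues(cohortTable(co, "taxa")) * 1.0)
  expect_equal(back$metadata$sample_id, cohortMetadata(co)$sample_id)
  expect_equal(nrow(back$medication), nrow(cohortMedication(co)))
  # 0-subject cohort: headers only, no crash
  co0 <- simulateCohort(cohortDesign(n_subjects_per_arm = 0, n_taxa = 3,
                                     n_modules = 2, n_immune = 2, n_clinical = 2,
                                     med_confounded_features = 0, seed = 1))
  dir0 <- withr::local_tempdir()
  exportCohort(co0, dir0)
  expect_equal(nrow(importCohortTables(dir0)$metadata), 0)
  # 35/arm design: 210 metadata rows
  expect_equal(nrow(cohortMetadata(simulateCohort(cohortDesign(
    n_taxa = 5, n_modules = 2, n_immune = 2, med_confounded_features = 0,
    seed = 2)))), 210)
})
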