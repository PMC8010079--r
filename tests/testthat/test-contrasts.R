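# O(n*m) pair-enumeration oracle for Cliff's delta
cliffs_oracle <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

# full-enumeration oracle for the two-sided MWU p-value (tie-free data)
mwu_enum_oracle <- function(x, y) {
  pooled <- c(x, y); n <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  cmb <- utils::combn(length(pooled), n)
  us <- apply(cmb, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# independent literal step-up BH
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    pi <- p[i]
    cand <- vapply(seq_len(m), function(j) {
      pj <- p[ord[j]]
      if (pj >= pi) pj * m / j else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

test_that("Cliff's delta matches hand values and the enumeration oracle", {
  expect_equal(cliffsDelta(c(1, 2, 3), c(4, 5, 6)), -1)
  expect_equal(cliffsDelta(c(2, 5, 9), c(2, 5, 9)), 0)
  expect_equal(cliffsDelta(c(1, 3), c(2, 2)), 0)
  set.seed(21)
  for (i in 1:50) {
    x <- sample(1:8, sample(2:20, 1), replace = TRUE)
    y <- sample(1:8, sample(2:20, 1), replace = TRUE)
    expect_equal(cliffsDelta(x, y), cliffs_oracle(x, y), tolerance = 1e-12)
  }
  expect_error(cliffsDelta(numeric(0), 1), "empty")
})

test_that("Cliff's delta is antisymmetric and monotone-invariant", {
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(12)
    expect_equal(cliffsDelta(x, y), -cliffsDelta(y, x))
    expect_equal(cliffsDelta(exp(x), exp(y)), cliffsDelta(x, y))
    expect_equal(cliffsDelta(rank(c(x, y))[1:15], rank(c(x, y))[16:27]),
                 cliffsDelta(x, y))
  }
})

test_that("MWU p-values are exact for small tie-free samples", {
  r <- mwuTest(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$u_stat, 0)
  expect_equal(mwuTest(c(5, 5, 5), c(5, 5))$p, 1)   # constant pooled data
  set.seed(23)
  for (i in 1:20) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    v <- sample(1:1000, n + m)   # tie-free
    expect_equal(mwuTest(v[1:n], v[-(1:n)])$p,
                 mwu_enum_oracle(v[1:n], v[-(1:n)]), tolerance = 1e-12)
  }
})

test_that("BH q-values match the literal step-up oracle and its identities", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.05, 1)), c(0.1, 1))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bhAdjust(c(0.5, 1.2)), "outside")
  set.seed(24)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- bhAdjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15), all(q <= 1))
  }
})

test_that("nested LRT handles degenerate, perfect and aliased designs", {
  md <- toy_metadata(10, seed = 31)
  const <- rep(4, nrow(md))
  r <- nestedLrt(const, md)
  expect_equal(r$lrt_stat, 0)
  expect_equal(r$p, 1)
  sig <- as.numeric(md$visit == "V2") + rnorm(nrow(md), 0, 1e-4)
  expect_lt(nestedLrt(sig, md)$p, 1e-6)
  # age and sex are constant within subject: aliased by patient dummies,
  # yet the test keeps df = number of visit columns
  expect_equal(r$df, 2)
  expect_equal(r$rank_full - r$rank_null, 2)
})

test_that("nested LRT equals the explicit normal-equations oracle", {
  md <- toy_metadata(10, seed = 32)
  set.seed(32)
  led <- data.frame(subject_id = rep(sprintf("P%02d", 1:5), each = 3),
                    drug_class = "diuretics", drug = "d1",
                    visit = rep(c("V1", "V2", "V3"), 5),
                    dose = rep(c(10, 5, 5), 5))
  norm <- normalizeMedication(led, visits = c("V1", "V2", "V3"))
  for (i in 1:3) {
    y <- rnorm(nrow(md)) + as.numeric(md$visit == "V2") * 0.5
    got <- nestedLrt(y, md, norm)
    # independent oracle: pseudo-inverse normal equations + Gaussian ML loglik
    ds <- refeedomics:::nested_designs(md, norm, FALSE)
    rss <- function(X) {
      b <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
      sum((y - X %*% b)^2)
    }
    stat_oracle <- nrow(md) * log(rss(ds$null) / rss(ds$full))
    expect_equal(got$lrt_stat, stat_oracle, tolerance = 1e-8)
  }
})

test_that("screen gate semantics and BH family bookkeeping", {
  co <- simulateCohort(cohortDesign(
    n_subjects_per_arm = 20, n_taxa = 40, n_modules = 10, n_immune = 10,
    med_confounded_features = 0,
    planted_effects = list(plantedEffect(NA, "taxa", "reversible", 0.9)),
    seed = 33))
  md <- cohortMetadata(co); fa <- md[md$arm == "fasting+DASH", ]
  norm <- normalizeMedication(cohortMedication(co), visits = c("V1", "V2", "V3"))
  res <- runContrastScreen(list(cohortTable(co, "taxa"), cohortTable(co, "immune")),
                           fa, norm)
  # LRT family is one per measurement space
  for (sp in unique(res$space)) {
    sub <- res[res$space == sp & !duplicated(res$feature_id), ]
    expect_equal(sub$q_lrt, unname(bhAdjust(sub$p_lrt)))
  }
  # post-hoc family is the 3 contrasts within each gated feature
  gated <- unique(res$feature_id[!is.na(res$p_mwu)])
  for (f in gated) {
    sub <- res[res$feature_id == f, ]
    expect_equal(nrow(sub), 3)
    expect_equal(sub$q_mwu, unname(bhAdjust(sub$p_mwu)))
  }
  # significant implies both gates
  sig <- res[res$significant & !duplicated(res$feature_id), ]
  expect_true(all(sig$q_lrt < 0.1))
  expect_true(all(vapply(sig$feature_id, function(f)
    any(res$q_mwu[res$feature_id == f] < 0.05, na.rm = TRUE), logical(1))))
  # features failing the LRT gate carry no post-hoc p but keep deltas
  failed <- res[!is.na(res$q_lrt) & res$q_lrt >= 0.1, ]
  expect_true(all(is.na(failed$p_mwu)))
  expect_true(all(is.finite(failed$cliffs_delta)))
  # the planted taxon is recovered
  expect_true(cohortTruth(co)$differential_features$feature_id %in% contrastHits(res))
})

test_that("BMI sensitivity handles empty results and missing BMI", {
  co <- simulateCohort(small_design(seed = 34))
  md <- cohortMetadata(co); fa <- md[md$arm == "fasting+DASH", ]
  norm <- normalizeMedication(cohortMedication(co), visits = c("V1", "V2", "V3"))
  res <- runContrastScreen(cohortTable(co, "immune"), fa, norm)
  out <- bmiSensitivity(res, cohortTable(co, "immune"), fa, norm)
  if (!length(contrastHits(res))) expect_true(is.na(out$retention))
  fa2 <- fa; fa2$bmi <- NULL
  expect_error(bmiSensitivity(res, cohortTable(co, "immune"), fa2, norm), "BMI")
})
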