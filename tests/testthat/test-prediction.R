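test_that("responder stratification follows the two-branch rule", {
  md <- data.frame(subject_id = rep(c("A", "B", "C", "D"), each = 2),
                   visit = rep(c("V1", "V3"), 4),
                   sbp_24h = c(130, 122,   # A: -8, no med change -> responder
                               130, 135,   # B: +5 -> non-responder
                               130, 129,   # C: -1 with med reduction -> responder
                               130, 129))  # D: -1, no med change -> non-responder
  led <- data.frame(subject_id = "C", drug_class = "diuretics", drug = "d",
                    visit = c("V1", "V3"), dose = c(10, 5))
  norm <- normalizeMedication(led, visits = c("V1", "V2", "V3"))
  rl <- stratifyResponders(md, norm)
  got <- setNames(rl$label, rl$subject_id)
  expect_equal(unname(got[c("A", "B", "C", "D")]),
               c("responder", "non-responder", "responder", "non-responder"))
  # missing follow-up excludes the subject
  md2 <- rbind(md, data.frame(subject_id = "E", visit = "V1", sbp_24h = 140))
  expect_false("E" %in% stratifyResponders(md2, norm)$subject_id)
})

test_that("stepwise selection is deterministic, bounded and finds planted signal", {
  expect_length(forwardStepwiseSelect(matrix(rnorm(40), 10), rep(0:1, 5), 0)$indices, 0)
  expect_error(forwardStepwiseSelect(matrix(rnorm(40), 10), rep(0:1, 5), 7), "exceeds")
  set.seed(51)
  y <- rep(0:1, each = 15)
  X <- matrix(rnorm(30 * 100), 30)
  X[, 42] <- y + rnorm(30, 0, 0.1)
  X <- scale(X)
  p <- forwardStepwiseSelect(X, y, 3)
  expect_equal(p$indices[1], 42)
  expect_lt(p$p_values[1], 1e-4)
  p2 <- forwardStepwiseSelect(X, y, 3)
  expect_identical(p$indices, p2$indices)
})

test_that("first stepwise pick equals the brute-force single-feature LRT argmin", {
  set.seed(52)
  y <- sample(rep(0:1, each = 10))
  X <- scale(matrix(rnorm(20 * 30), 20))
  p <- forwardStepwiseSelect(X, y, 1)
  # independent oracle: unregularized single-feature logistic vs empty model
  ll0 <- -20 * log(2)
  stats <- vapply(seq_len(ncol(X)), function(j) {
    f <- suppressWarnings(glm(y ~ X[, j] - 1, family = binomial))
    as.numeric(logLik(f)) - ll0
  }, numeric(1))
  expect_equal(p$indices[1], which.max(stats))
})

test_that("ridge logistic solves the stated objective", {
  # all-zero design: objective minimized at the origin
  f0 <- fitRidgeLogistic(matrix(0, 10, 3), rep(0:1, 5))
  expect_equal(unname(f0$weights), c(0, 0, 0))
  # 1-D solution matches golden-section minimization to 1e-6
  set.seed(53)
  x <- rnorm(25); y <- rbinom(25, 1, plogis(1.5 * x))
  for (C in c(0.3, 1, 3)) {
    obj <- function(w) 0.5 * w^2 + C * sum(log1p(exp(-(2 * y - 1) * (x * w))))
    gold <- optimize(obj, c(-50, 50), tol = 1e-12)$minimum
    w <- unname(fitRidgeLogistic(matrix(x), y, C)$weights)
    expect_lt(abs(w - gold), 1e-6)
  }
  # gradient norm at the solution and shrinkage as C -> 0
  X <- scale(matrix(rnorm(25 * 4), 25))
  norms <- vapply(c(1, 0.1, 0.01, 0.001), function(C) {
    f <- fitRidgeLogistic(X, y, C)
    expect_lte(f$grad_norm, 1e-8)
    sqrt(sum(f$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 0.05)
  expect_error(fitRidgeLogistic(matrix(c(1, NA), 1), 1), "non-finite")
})

test_that("classification metrics reproduce confusion arithmetic", {
  truth <- c(rep(1, 8), rep(0, 10))
  pred <- c(rep(1, 6), rep(0, 2), rep(1, 3), rep(0, 7))
  m <- classificationMetrics(truth, pred)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.70)
  expect_equal(m$accuracy, 13 / 18, tolerance = 1e-4)
  expect_equal(m$f1, 12 / 17, tolerance = 1e-4)
  perfect <- classificationMetrics(c(1, 0, 1), c(1, 0, 1))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity", "f1")]) == 1))
  allpos <- classificationMetrics(rep(c(1, 0), 5), rep(1, 10))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)
  expect_equal(classificationMetrics(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                                     c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0))$f1, 6 / 9)
  expect_error(classificationMetrics(numeric(0), numeric(0)), "empty")
})

test_that("LOSO folds never leak the held-out subject", {
  set.seed(54)
  X <- matrix(rnorm(12 * 20), 12, dimnames = list(paste0("S", 1:12),
                                                  paste0("f", 1:20)))
  y <- rep(0:1, 6)
  seen <- list()
  rep <- losoCvPredict(X, y, k = 2, fold_hook = function(info) {
    seen[[length(seen) + 1]] <<- info
  })
  expect_equal(nrow(rep$folds), 12)   # exactly one fold per subject
  expect_length(seen, 12)
  for (info in seen) {
    expect_false(info$test_index %in% info$train_indices)
    # scaler statistics computed from the training rows only
    expect_equal(info$center, colMeans(X[info$train_indices, ]))
    expect_equal(info$scale, apply(X[info$train_indices, ], 2, sd))
  }
  # metrics recomputable from the fold records
  m <- classificationMetrics(rep$folds$true, rep$folds$predicted)
  expect_equal(rep$metrics$accuracy, m$accuracy)
})

test_that("single-class training folds are skipped with a warning", {
  set.seed(55)
  X <- matrix(rnorm(5 * 4), 5); y <- c(1, 0, 0, 0, 0)
  expect_warning(rep <- losoCvPredict(X, y, k = 1), "single-class")
  expect_equal(nrow(rep$folds), 4)   # the lone positive cannot be held out
})

test_that("transfer prediction is consistent, imputes and validates overlap", {
  set.seed(56)
  y <- rep(0:1, each = 10)
  X <- matrix(rnorm(20 * 30), 20, dimnames = list(NULL, paste0("f", 1:30)))
  X[, 1:3] <- X[, 1:3] + 1.2 * y
  # external set identical to training: predictions equal in-sample predictions
  tr <- transferPredict(X, y, NULL, X, k = 3)
  sc <- refeedomics:::train_scaler(X)
  Xs <- refeedomics:::apply_scaler(X, sc)
  path <- forwardStepwiseSelect(Xs, y, 3)
  model <- fitRidgeLogistic(Xs[, path$indices, drop = FALSE], y, 1)
  insample <- predictRidge(model, Xs[, path$indices, drop = FALSE])$label
  expect_equal(tr$labels, insample)
  # missing selected features impute to the training mean (0 after scaling)
  half <- X[, setdiff(colnames(X), tr$selected[1]), drop = FALSE]
  expect_warning(tr2 <- transferPredict(X, y, NULL, half, k = 3), "imputing")
  expect_length(tr2$labels, 20)
  # feature filter restricts candidates
  tr3 <- transferPredict(X, y, feature_filter = c("f1", "f2", "f3"), X, k = 2)
  expect_true(all(tr3$selected %in% c("f1", "f2", "f3")))
  # disjoint namespaces fail
  ext <- X; colnames(ext) <- paste0("g", 1:30)
  expect_error(transferPredict(X, y, NULL, ext, k = 2), "overlapping")
  # truth reporting
  tr4 <- transferPredict(X, y, NULL, X, k = 3, external_truth = y)
  expect_equal(tr4$n_correct, sum(tr4$labels == y))
})

test_that("responderMatrix extracts baseline features for labeled subjects", {
  co <- simulateCohort(small_design(informative_predictors = 3, seed = 57))
  rm <- responderMatrix(co, "immune", "V1")
  expect_equal(nrow(rm$X), 8)   # fasting arm only
  expect_equal(length(rm$y), 8)
  expect_true(all(rownames(rm$X) %in% cohortMetadata(co)$subject_id))
  expect_setequal(unique(rm$y), c(0, 1))
})
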