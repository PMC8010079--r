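#' Cliff's delta ordinal effect size
#'
#' The signed probability-of-superiority difference
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (n m)`, in [-1, 1]; ties
#' contribute zero. Computed via pooled average ranks (algebraically equal
#' to pair enumeration, including under ties), so it is invariant under any
#' strictly monotone transform of the pooled data.
#'
#' @param x,y non-empty numeric vectors.
#' @return delta in [-1, 1]; positive means x tends to exceed y.
#' @examples
#' cliffsDelta(c(1, 3), c(2, 2))  # 0
#' @export
cliffsDelta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty input to cliffsDelta")
  r <- rank(c(x, y))
  n <- length(x); m <- length(y)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # #(x>y) + 0.5 * #ties
  2 * u / (n * m) - 1
}

#' Mann-Whitney U test
#'
#' Two-sided (by default) rank-sum comparison. The p-value is exact (full
#' enumeration of the U null distribution) when `length(x) + length(y) <= 16`
#' and the pooled data are tie-free; otherwise the normal approximation with
#' tie and continuity correction is used. Constant pooled data give p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative as in [stats::wilcox.test()].
#' @return list with `u_stat` (counting pairs where x exceeds y, ties as
#'   half) and `p`.
#' @export
mwuTest <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty input to mwuTest")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (length(unique(pooled)) == 1L)
    return(list(u_stat = u, p = 1))
  ties <- any(duplicated(pooled))
  exact <- (n + m <= 16) && !ties
  p <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                    exact = exact, correct = TRUE)$p.value)
  list(u_stat = u, p = min(p, 1))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values of the same length; `q >= p` elementwise, capped at 1.
#' @export
bhAdjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values outside [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Configuration of the deconfounded contrast screen
#'
#' @param screen_fdr_threshold BH FDR gate of the likelihood-ratio stage
#'   (default 0.1, within each measurement space).
#' @param posthoc_fdr_threshold BH FDR gate of the Mann-Whitney post-hoc
#'   stage (default 0.05, across the visit-pair contrasts per feature).
#' @param contrasts list of visit pairs to test post hoc.
#' @param include_bmi add BMI to the covariates of both nested models.
#' @param rank_transform rank-transform each feature before the linear
#'   models (default off; the abundance-scale model).
#' @return list of class `ContrastConfig`.
#' @export
contrastConfig <- function(screen_fdr_threshold = 0.1,
                           posthoc_fdr_threshold = 0.05,
                           contrasts = list(c("V1", "V2"), c("V2", "V3"), c("V1", "V3")),
                           include_bmi = FALSE,
                           rank_transform = FALSE) {
  stopifnot(screen_fdr_threshold > 0, screen_fdr_threshold < 1,
            posthoc_fdr_threshold > 0, posthoc_fdr_threshold < 1,
            length(contrasts) >= 1)
  structure(list(screen_fdr_threshold = screen_fdr_threshold,
                 posthoc_fdr_threshold = posthoc_fdr_threshold,
                 contrasts = contrasts, include_bmi = include_bmi,
                 rank_transform = rank_transform),
            class = "ContrastConfig")
}

# normalized dose of each drug as a samples x drugs matrix aligned to metadata
dose_matrix <- function(metadata, norm_medication) {
  if (is.null(norm_medication) || !nrow(norm_medication$normalized))
    return(matrix(0, nrow(metadata), 0, dimnames = list(metadata$sample_id, NULL)))
  nn <- norm_medication$normalized
  drugs <- unique(paste(nn$drug_class, nn$drug, sep = "|"))
  m <- matrix(0, nrow(metadata), length(drugs),
              dimnames = list(metadata$sample_id, drugs))
  sid <- paste(nn$subject_id, nn$visit, sep = ":")
  keep <- sid %in% rownames(m)
  nn <- nn[keep, ]; sid <- sid[keep]
  m[cbind(match(sid, rownames(m)),
          match(paste(nn$drug_class, nn$drug, sep = "|"), drugs))] <- nn$normalized_dose
  m
}

# null and full design matrices of the nested comparison
nested_designs <- function(metadata, norm_medication, include_bmi) {
  pid <- factor(metadata$subject_id)
  x_pid <- stats::model.matrix(~pid)[, -1, drop = FALSE]
  sexnum <- as.numeric(factor(metadata$sex))
  covs <- cbind(`(Intercept)` = 1, age = metadata$age, sex = sexnum, x_pid,
                dose_matrix(metadata, norm_medication))
  if (include_bmi) covs <- cbind(covs, bmi = metadata$bmi)
  visit <- factor(metadata$visit)
  x_visit <- stats::model.matrix(~visit)[, -1, drop = FALSE]
  list(null = covs, full = cbind(covs, x_visit))
}

# Gaussian-ML likelihood-ratio screen of a response matrix, pivoted QR,
# shared design across features (complete columns only)
lrt_matrix <- function(Y, X0, X1) {
  n <- nrow(Y)
  f0 <- stats::lm.fit(X0, Y)
  f1 <- stats::lm.fit(X1, Y)
  rss0 <- colSums(as.matrix(f0$residuals)^2)
  rss1 <- colSums(as.matrix(f1$residuals)^2)
  df <- f1$rank - f0$rank
  eps <- 1e-12 * pmax(colSums(as.matrix(Y)^2), 1)
  stat <- ifelse(rss0 < eps & rss1 < eps, 0, n * log(pmax(rss0, eps) / pmax(rss1, eps)))
  stat <- pmax(stat, 0)
  p <- if (df > 0) pchisq(stat, df, lower.tail = FALSE) else rep(NA_real_, length(stat))
  p[df > 0 & stat == 0] <- 1
  list(stat = stat, p = p, df = df, rank_null = f0$rank, rank_full = f1$rank)
}

#' Nested linear-model likelihood-ratio test for one feature
#'
#' Compares, by a Gaussian maximum-likelihood ratio test, a null linear
#' model of the feature on age, sex, patient identity and the normalized
#' dose of every tracked medication (optionally BMI) against the same model
#' plus visit as a categorical predictor. Because patient dummies make age
#' and sex (and any between-subject covariate) collinear, fitting uses
#' pivoted least squares and aliased columns drop out identically in both
#' models, leaving the test unaffected. Degrees of freedom are the design
#' rank difference.
#'
#' @param feature_values numeric vector aligned to `metadata` rows.
#' @param metadata data.frame with `subject_id`, `visit`, `age`, `sex`,
#'   `sample_id` (and `bmi` if `include_bmi`).
#' @param norm_medication result of [normalizeMedication()], or NULL.
#' @param include_bmi add BMI as a covariate to both models.
#' @return list: `lrt_stat`, `p`, `df`, `rank_null`, `rank_full`.
#' @export
nestedLrt <- function(feature_values, metadata, norm_medication = NULL,
                      include_bmi = FALSE) {
  stopifnot(length(feature_values) == nrow(metadata))
  cc <- !is.na(feature_values)
  ds <- nested_designs(metadata[cc, , drop = FALSE], norm_medication, include_bmi)
  r <- lrt_matrix(matrix(feature_values[cc], ncol = 1), ds$null, ds$full)
  if (r$df == 0)
    warning("full model rank-deficient in the visit columns; test undefined")
  list(lrt_stat = unname(r$stat), p = unname(r$p), df = r$df,
       rank_null = r$rank_null, rank_full = r$rank_full)
}

#' Medication-deconfounded two-step contrast screen
#'
#' Step one tests every feature with the nested likelihood-ratio model of
#' [nestedLrt()] and adjusts p-values by Benjamini-Hochberg within each
#' measurement space; features passing the screen FDR gate proceed to step
#' two: unpaired two-sided Mann-Whitney tests between each configured pair
#' of visits, BH-adjusted across the visit-pair family per feature.
#' A feature is flagged significant when it passes both gates. Cliff's
#' delta is reported for every feature and contrast regardless of
#' significance (positive delta = higher at the later visit).
#'
#' @param tables a [FeatureTable-class] or named list of them.
#' @param metadata per-sample metadata; rows are matched to each table's
#'   sample ids (restrict `metadata` to one arm to screen within that arm).
#' @param norm_medication result of [normalizeMedication()], or NULL for an
#'   unmedicated cohort.
#' @param config a [contrastConfig()].
#' @return data.frame with one row per (feature, contrast): `feature_id`,
#'   `space`, `lrt_stat`, `p_lrt`, `q_lrt`, `contrast`, `cliffs_delta`,
#'   `u_stat`, `p_mwu`, `q_mwu`, `significant` (feature-level flag).
#' @export
runContrastScreen <- function(tables, metadata, norm_medication = NULL,
                              config = contrastConfig()) {
  if (is(tables, "FeatureTable")) tables <- list(tables)
  out <- list()
  for (tab in tables) {
    keep <- metadata$sample_id %in% sampleIds(tab)
    md <- metadata[keep, , drop = FALSE]
    md <- md[match(intersect(sampleIds(tab), md$sample_id), md$sample_id), , drop = FALSE]
    Y <- featureValues(tab)[md$sample_id, , drop = FALSE]
    if (config$rank_transform) Y <- apply(Y, 2L, rank)
    ds <- nested_designs(md, norm_medication, config$include_bmi)
    scr <- lrt_matrix(Y, ds$null, ds$full)
    q_lrt <- bhAdjust(scr$p)
    gate <- !is.na(q_lrt) & q_lrt < config$screen_fdr_threshold

    nf <- ncol(Y)
    rows <- vector("list", nf)
    visit <- md$visit
    for (j in seq_len(nf)) {
      recs <- lapply(config$contrasts, function(ct) {
        xa <- Y[visit == ct[2], j]; xb <- Y[visit == ct[1], j]
        delta <- cliffsDelta(xa, xb)
        if (gate[j]) {
          mt <- mwuTest(xa, xb)
          c(delta = delta, u = mt$u_stat, p = mt$p)
        } else c(delta = delta, u = NA_real_, p = NA_real_)
      })
      recs <- do.call(rbind, recs)
      q_mwu <- if (gate[j]) bhAdjust(recs[, "p"]) else rep(NA_real_, nrow(recs))
      rows[[j]] <- data.frame(
        feature_id = colnames(Y)[j], space = measurementSpace(tab),
        lrt_stat = scr$stat[j], p_lrt = scr$p[j], q_lrt = q_lrt[j],
        contrast = vapply(config$contrasts, paste, "", collapse = "-"),
        cliffs_delta = recs[, "delta"], u_stat = recs[, "u"],
        p_mwu = recs[, "p"], q_mwu = q_mwu,
        significant = gate[j] && any(q_mwu < config$posthoc_fdr_threshold, na.rm = TRUE),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Significant feature ids of a contrast-screen result
#' @param results data.frame from [runContrastScreen()].
#' @return character vector of feature ids flagged significant.
#' @export
contrastHits <- function(results) {
  unique(results$feature_id[results$significant])
}

#' Covariate-free marginal Mann-Whitney screen
#'
#' The naive per-feature visit comparison without any medication adjustment;
#' used to demonstrate what the deconfounded screen protects against.
#'
#' @param table a [FeatureTable-class].
#' @param metadata per-sample metadata (possibly one arm).
#' @param contrast a visit pair, e.g. `c("V1", "V2")`.
#' @return data.frame: feature_id, cliffs_delta, p, q (BH over features).
#' @export
marginalMwu <- function(table, metadata, contrast = c("V1", "V2")) {
  keep <- metadata$sample_id %in% sampleIds(table)
  md <- metadata[keep, , drop = FALSE]
  Y <- featureValues(table)[md$sample_id, , drop = FALSE]
  res <- t(vapply(seq_len(ncol(Y)), function(j) {
    xa <- Y[md$visit == contrast[2], j]; xb <- Y[md$visit == contrast[1], j]
    c(cliffsDelta(xa, xb), mwuTest(xa, xb)$p)
  }, numeric(2)))
  data.frame(feature_id = colnames(Y), cliffs_delta = res[, 1], p = res[, 2],
             q = bhAdjust(res[, 2]), stringsAsFactors = FALSE)
}

#' BMI sensitivity re-test of a contrast screen
#'
#' Re-runs the screen with BMI added as a covariate to both nested models
#' and reports which originally significant features retain significance.
#'
#' @param results data.frame from [runContrastScreen()].
#' @param tables,metadata,norm_medication,config as in [runContrastScreen()].
#' @return list: `retention` (fraction retained, NA when nothing was
#'   significant), `bmi_robust` (named logical over originally significant
#'   features), `results_bmi` (the re-run screen).
#' @export
bmiSensitivity <- function(results, tables, metadata, norm_medication = NULL,
                           config = contrastConfig()) {
  if (!"bmi" %in% names(metadata) || all(is.na(metadata$bmi)))
    stop("BMI missing from metadata")
  config$include_bmi <- TRUE
  res_bmi <- runContrastScreen(tables, metadata, norm_medication, config)
  orig <- contrastHits(results)
  if (!length(orig))
    return(list(retention = NA_real_, bmi_robust = logical(0), results_bmi = res_bmi))
  still <- contrastHits(res_bmi)
  robust <- setNames(orig %in% still, orig)
  list(retention = mean(robust), bmi_robust = robust, results_bmi = res_bmi)
}
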