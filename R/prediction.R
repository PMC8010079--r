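#' Stratify subjects into blood-pressure responders
#'
#' Labels each subject from the change in 24 h ambulatory systolic blood
#' pressure between baseline and follow-up, adjusted for the change in
#' medication load (sum of normalized agent doses). The default rule is a
#' two-branch reconstruction of a decision-tree stratification: a subject
#' responds if SBP dropped by at least `sbp_cut` mmHg without a medication
#' increase, or if medication was reduced while SBP did not rise. All
#' thresholds are configurable.
#'
#' @param metadata per-sample metadata with `subject_id`, `visit`,
#'   `sbp_24h`.
#' @param norm_medication result of [normalizeMedication()], or NULL for an
#'   unmedicated cohort (medication change treated as 0).
#' @param from_visit,to_visit visits defining the response window (default
#'   V1 to V3).
#' @param sbp_cut minimum SBP drop (mmHg) for the blood-pressure branch
#'   (default 2).
#' @return data.frame of class `ResponderLabels`: `subject_id`, `label`
#'   (`"responder"`/`"non-responder"`), `delta_sbp` (mmHg), `delta_med`
#'   (dimensionless agent-sum change). Subjects missing either visit are
#'   excluded.
#' @export
stratifyResponders <- function(metadata, norm_medication = NULL,
                               from_visit = "V1", to_visit = "V3",
                               sbp_cut = 2) {
  md1 <- metadata[metadata$visit == from_visit, c("subject_id", "sbp_24h")]
  md3 <- metadata[metadata$visit == to_visit, c("subject_id", "sbp_24h")]
  m <- merge(md1, md3, by = "subject_id", suffixes = c("_from", "_to"))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  delta_med <- setNames(rep(0, nrow(m)), m$subject_id)
  if (!is.null(norm_medication)) {
    agg <- norm_medication$agent_sum
    get <- function(v) {
      x <- setNames(rep(0, nrow(m)), m$subject_id)
      sel <- agg$visit == v & agg$subject_id %in% m$subject_id
      x[agg$subject_id[sel]] <- agg$agent_sum[sel]
      x
    }
    delta_med <- get(to_visit) - get(from_visit)
  }
  delta_sbp <- m$sbp_24h_to - m$sbp_24h_from
  responder <- (delta_sbp <= -sbp_cut & delta_med <= 0) |
    (delta_med < 0 & delta_sbp <= 0)
  out <- data.frame(subject_id = m$subject_id,
                    label = ifelse(responder, "responder", "non-responder"),
                    delta_sbp = delta_sbp, delta_med = unname(delta_med),
                    stringsAsFactors = FALSE)
  class(out) <- c("ResponderLabels", "data.frame")
  out
}

as_y01 <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    stopifnot(all(y %in% c("responder", "non-responder")))
    as.numeric(y == "responder")
  } else as.numeric(y)
}

#' Forward-stepwise feature selection by likelihood-ratio p-value
#'
#' Greedily grows a no-intercept logistic model: at each step the candidate
#' whose addition gives the smallest 1-df likelihood-ratio p-value (largest
#' likelihood gain) joins the model; ties break by feature order. Fitting
#' uses a micro-ridge (lambda = 1e-6) for numerical stability under
#' separation. Selection runs to `k` features regardless of significance;
#' steps with p >= 0.05 are flagged.
#'
#' @param X numeric matrix (subjects x features), expected z-scored.
#' @param y binary outcome: 0/1 or `"responder"`/`"non-responder"` labels.
#' @param k number of features to select.
#' @return list of class `StepwisePath`: `features` (ids), `indices`,
#'   `p_values` (at the step of selection), `nonsignificant` (logical
#'   flags), `loglik` (model log-likelihood per step, empty model first).
#' @export
forwardStepwiseSelect <- function(X, y, k) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  y01 <- as_y01(y)
  stopifnot(k >= 0, nrow(X) == length(y01))
  if (k > ncol(X)) stop("k exceeds the number of candidate features")
  if (k == 0)
    return(structure(list(features = character(0), indices = integer(0),
                          p_values = numeric(0), nonsignificant = logical(0),
                          loglik = -nrow(X) * log(2)),
                     class = "StepwisePath"))
  fit <- .stepwise_cpp(X, y01, as.integer(k))
  idx <- fit$path + 1L
  ll <- fit$loglik
  pvals <- pchisq(pmax(0, 2 * diff(ll)), df = 1, lower.tail = FALSE)
  structure(list(features = colnames(X)[idx], indices = idx,
                 p_values = pvals, nonsignificant = pvals >= 0.05,
                 loglik = ll),
            class = "StepwisePath")
}

#' Fit a no-intercept ridge-penalized logistic model
#'
#' Minimizes `0.5 ||w||^2 + C * sum_i log(1 + exp(-y~_i x_i.w))` with
#' `y~ in {-1, +1}` and no intercept term, by Newton iteration to gradient
#' norm <= 1e-8. The objective is strictly convex, so the solution is
#' unique.
#'
#' @param X numeric matrix (subjects x features), finite.
#' @param y binary outcome (0/1 or responder labels).
#' @param c_penalty the loss weight C (default 1.0); smaller C shrinks
#'   `w` toward zero.
#' @return list of class `RidgeModel`: `weights` (named), `c_penalty`,
#'   `grad_norm`.
#' @export
fitRidgeLogistic <- function(X, y, c_penalty = 1.0) {
  X <- as.matrix(X)
  y01 <- as_y01(y)
  if (!all(is.finite(X))) stop("non-finite values in X")
  stopifnot(nrow(X) == length(y01), all(y01 %in% c(0, 1)))
  fit <- .ridge_logistic_cpp(X, y01, lambda = 1.0, C = c_penalty,
                             tol = 1e-10, maxit = 500)
  w <- as.numeric(fit$w)
  names(w) <- colnames(X)
  structure(list(weights = w, c_penalty = c_penalty,
                 grad_norm = fit$grad_norm),
            class = "RidgeModel")
}

#' Decision scores and labels of a ridge model
#' @param model a `RidgeModel`.
#' @param X matrix with the model's features as columns (already scaled).
#' @return list: `score` (X w), `label` (1 if score > 0 else 0).
#' @export
predictRidge <- function(model, X) {
  score <- as.numeric(as.matrix(X) %*% model$weights)
  list(score = score, label = as.numeric(score > 0))
}

train_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2L, sc$center, "-"), 2L, sc$scale, "/")
}

#' Confusion-matrix classification metrics
#'
#' @param true_labels,predicted_labels aligned label vectors (0/1 or
#'   responder labels).
#' @param positive_class value counted as positive (default 1, i.e.
#'   responder).
#' @return list: `accuracy`, `sensitivity` TP/(TP+FN), `specificity`
#'   TN/(TN+FP), `f1` 2TP/(2TP+FP+FN), and the counts `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
classificationMetrics <- function(true_labels, predicted_labels,
                                  positive_class = 1) {
  if (!length(true_labels)) stop("empty input")
  stopifnot(length(true_labels) == length(predicted_labels))
  tv <- as_y01(true_labels) == as_y01(positive_class[1])
  pv <- as_y01(predicted_labels) == as_y01(positive_class[1])
  tp <- sum(tv & pv); fp <- sum(!tv & pv)
  tn <- sum(!tv & !pv); fn <- sum(tv & !pv)
  list(accuracy = (tp + tn) / length(tv),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Leave-one-subject-out cross-validated response prediction
#'
#' The leakage-safe evaluation loop: for each fold, the held-out subject is
#' removed, z-scoring statistics (mean, SD) are computed from the training
#' subjects only, forward-stepwise selection of `k` features runs on the
#' training subjects only, a no-intercept ridge-logistic model is fitted on
#' the selected features, and the held-out subject is classified at
#' decision threshold 0. Folds whose training outcomes are single-class are
#' skipped with a warning.
#'
#' @param X numeric matrix, one row per subject (e.g. baseline features or
#'   baseline-to-follow-up deltas).
#' @param y binary outcome per subject.
#' @param k number of stepwise-selected features per fold (default 10).
#' @param c_penalty ridge loss weight C (default 1.0).
#' @param fold_hook optional function called per fold with a list
#'   (`test_index`, `train_indices`, `center`, `scale`, `selected`);
#'   intended for instrumentation.
#' @return list of class `PredictionReport`: `folds` (data.frame with
#'   held-out subject, truth, prediction, decision score, selected path),
#'   `metrics` (see [classificationMetrics()]).
#' @export
losoCvPredict <- function(X, y, k = 10L, c_penalty = 1.0, fold_hook = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  y01 <- as_y01(y)
  n <- nrow(X)
  stopifnot(n == length(y01))
  if (is.null(rownames(X))) rownames(X) <- paste0("subject_", seq_len(n))
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (length(unique(y01[tr])) < 2) {
      warning("fold ", i, ": single-class training outcomes; fold skipped")
      next
    }
    sc <- train_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
    path <- forwardStepwiseSelect(Xtr, y01[tr], k)
    if (!is.null(fold_hook))
      fold_hook(list(test_index = i, train_indices = tr, center = sc$center,
                     scale = sc$scale, selected = path$features))
    model <- fitRidgeLogistic(Xtr[, path$indices, drop = FALSE], y01[tr],
                              c_penalty = c_penalty)
    xte <- apply_scaler(X[i, , drop = FALSE], sc)[, path$indices, drop = FALSE]
    pr <- predictRidge(model, xte)
    recs[[i]] <- data.frame(subject_id = rownames(X)[i], true = y01[i],
                            predicted = pr$label, score = pr$score,
                            selected = paste(path$features, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, recs)
  if (is.null(folds)) stop("no evaluable fold")
  structure(list(folds = folds,
                 metrics = classificationMetrics(folds$true, folds$predicted)),
            class = "PredictionReport")
}

#' Train on one cohort, predict an external cohort
#'
#' Fits a single stepwise-then-ridge model on all training subjects
#' (optionally restricted to a feature filter, e.g. responder-specific
#' taxa) and applies it to an external table sharing the feature namespace.
#' External features missing a selected feature are imputed at the training
#' mean, i.e. contribute 0 after scaling.
#'
#' @param train_X,train_y training subjects (rows) and binary outcomes.
#' @param feature_filter optional character vector restricting candidate
#'   features.
#' @param external_X external subjects x features matrix.
#' @param k number of stepwise-selected features (default 5).
#' @param c_penalty ridge loss weight C (default 1.0).
#' @param external_truth optional binary outcomes of the external subjects.
#' @return list of class `TransferReport`: `labels`, `scores`, `selected`;
#'   plus `metrics` and `n_correct` when `external_truth` is given.
#' @export
transferPredict <- function(train_X, train_y, feature_filter = NULL,
                            external_X, k = 5L, c_penalty = 1.0,
                            external_truth = NULL) {
  train_X <- as.matrix(train_X)
  external_X <- as.matrix(external_X)
  y01 <- as_y01(train_y)
  if (!is.null(feature_filter)) {
    keep <- intersect(colnames(train_X), feature_filter)
    if (!length(keep)) stop("feature filter removes every training feature")
    train_X <- train_X[, keep, drop = FALSE]
  }
  if (!length(intersect(colnames(train_X), colnames(external_X))))
    stop("no overlapping features between training and external tables")
  sc <- train_scaler(train_X)
  Xtr <- apply_scaler(train_X, sc)
  path <- forwardStepwiseSelect(Xtr, y01, min(k, ncol(Xtr)))
  model <- fitRidgeLogistic(Xtr[, path$indices, drop = FALSE], y01,
                            c_penalty = c_penalty)
  sel <- path$features
  missing <- setdiff(sel, colnames(external_X))
  if (length(missing))
    warning("external table lacks ", length(missing),
            " selected feature(s); imputing training mean: ",
            paste(missing, collapse = ", "))
  Xe <- matrix(0, nrow(external_X), length(sel),
               dimnames = list(rownames(external_X), sel))
  have <- intersect(sel, colnames(external_X))
  if (length(have)) {
    scaled <- apply_scaler(external_X[, have, drop = FALSE],
                           list(center = sc$center[have], scale = sc$scale[have]))
    Xe[, have] <- scaled
  }
  pr <- predictRidge(model, Xe)
  out <- list(labels = pr$label, scores = pr$score, selected = sel,
              model = model)
  if (!is.null(external_truth)) {
    out$metrics <- classificationMetrics(external_truth, pr$label)
    out$n_correct <- sum(as_y01(external_truth) == pr$label)
  }
  class(out) <- "TransferReport"
  out
}

#' Subject-level baseline feature matrix of a cohort
#'
#' Convenience accessor for prediction: extracts one row per fasting-arm
#' subject from a cohort table at a given visit, together with the
#' ground-truth responder outcome.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param table which measurement table (default `"immune"`).
#' @param visit which visit to take features from (default baseline V1).
#' @return list: `X` (subjects x features), `y` (0/1 responder truth).
#' @export
responderMatrix <- function(cohort, table = "immune", visit = "V1") {
  md <- cohortMetadata(cohort)
  labels <- cohortTruth(cohort)$responder_labels
  subs <- names(labels)
  rows <- paste(subs, visit, sep = ":")
  tab <- cohortTable(cohort, table)
  X <- featureValues(tab)[rows, , drop = FALSE]
  rownames(X) <- subs
  list(X = X, y = as.numeric(labels == "responder"))
}
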