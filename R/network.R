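#' Pooled Spearman correlation screen between two measurement spaces
#'
#' Correlates every feature of one table with every feature of the other
#' using samples pooled across visits: average-rank Spearman rho with the
#' t-approximation p-value, BH-adjusted across all pairs of the space pair
#' (one family per unordered pair of spaces). Constant features yield no
#' edge (skipped with a note attribute).
#'
#' @param table_a,table_b [FeatureTable-class] objects sharing sample ids.
#' @param q_threshold screen FDR gate recorded in the output (default 0.05;
#'   the value used in the downstream robust-edge rule).
#' @return data.frame of class `EdgeSet`: `feature_a`, `space_a`,
#'   `feature_b`, `space_b`, `rho`, `p`, `q`, `screen_pass`, with columns
#'   `p_posthoc`/`robust` initialized NA (see [posthocEdges()]).
#' @export
spearmanScreen <- function(table_a, table_b, q_threshold = 0.05) {
  ids <- intersect(sampleIds(table_a), sampleIds(table_b))
  if (length(ids) < 4) stop("need at least 4 shared samples")
  A <- featureValues(table_a)[ids, , drop = FALSE]
  B <- featureValues(table_b)[ids, , drop = FALSE]
  const_a <- apply(A, 2L, function(v) length(unique(v)) == 1L)
  const_b <- apply(B, 2L, function(v) length(unique(v)) == 1L)
  skipped <- c(colnames(A)[const_a], colnames(B)[const_b])
  A <- A[, !const_a, drop = FALSE]; B <- B[, !const_b, drop = FALSE]
  ra <- apply(A, 2L, rank); rb <- apply(B, 2L, rank)
  n <- length(ids)
  rho <- cor(ra, rb)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  out <- data.frame(
    feature_a = rep(rownames(rho), ncol(rho)),
    space_a = measurementSpace(table_a),
    feature_b = rep(colnames(rho), each = nrow(rho)),
    space_b = measurementSpace(table_b),
    rho = as.vector(rho), p = as.vector(p), stringsAsFactors = FALSE)
  out$q <- bhAdjust(out$p)
  out$screen_pass <- out$q < q_threshold
  out$p_posthoc <- NA_real_
  out$robust <- NA
  attr(out, "skipped_constant") <- skipped
  attr(out, "n_samples") <- n
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("EdgeSet", "data.frame")
  out
}

#' Same-donor mixed-model post-hoc test for one correlated pair
#'
#' Guards a pooled correlation against pseudo-replication from repeated
#' samples of the same donor. Both rank-transformed variables are modelled
#' in turn as a linear function of the other's ranks with a per-subject
#' random intercept (ML fit), each compared by likelihood ratio against the
#' intercept-plus-random-effect null; the LARGER of the two p-values is
#' returned, so an association must survive in both directions. Fits whose
#' variance estimation fails return p = 1 (conservative).
#'
#' @param x,y numeric vectors over pooled samples.
#' @param subject_ids donor of each sample.
#' @return the post-hoc p-value.
#' @export
sameDonorPosthoc <- function(x, y, subject_ids) {
  stopifnot(length(x) == length(y), length(x) == length(subject_ids))
  cc <- !(is.na(x) | is.na(y))
  x <- x[cc]; y <- y[cc]; subject_ids <- subject_ids[cc]
  if (length(unique(subject_ids)) < 2) stop("need at least 2 subjects")
  rx <- rank(x); ry <- rank(y)
  p1 <- lrt_ranks_lmer(ry, rx, subject_ids)
  p2 <- lrt_ranks_lmer(rx, ry, subject_ids)
  max(p1, p2)
}

lrt_ranks_lmer <- function(resp, pred, subj) {
  # no within-donor variation in the response => no within-donor evidence;
  # the residual variance degenerates and the test is conservatively 1
  within_ss <- sum(tapply(resp, subj, function(v) sum((v - mean(v))^2)))
  total_ss <- sum((resp - mean(resp))^2)
  if (total_ss <= 0 || within_ss / total_ss < 1e-10) return(1)
  df <- data.frame(resp = resp, pred = pred, subj = factor(subj))
  p <- tryCatch({
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(resp ~ pred + (1 | subj), data = df, REML = FALSE)))
    null <- suppressMessages(suppressWarnings(
      lme4::lmer(resp ~ 1 + (1 | subj), data = df, REML = FALSE)))
    stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, error = function(e) 1)
  if (!is.finite(p)) 1 else p
}

#' Apply the same-donor post-hoc to screen-passing edges
#'
#' @param edges an `EdgeSet` from [spearmanScreen()].
#' @param table_a,table_b the tables the edges came from.
#' @param metadata per-sample metadata providing `subject_id` per
#'   `sample_id`.
#' @param posthoc_threshold significance gate for the post-hoc p (default
#'   0.05).
#' @return the `EdgeSet` with `p_posthoc` filled for screen-passing edges
#'   and `robust = screen_pass & p_posthoc < posthoc_threshold`.
#' @export
posthocEdges <- function(edges, table_a, table_b, metadata,
                         posthoc_threshold = 0.05) {
  ids <- intersect(sampleIds(table_a), sampleIds(table_b))
  subj <- metadata$subject_id[match(ids, metadata$sample_id)]
  A <- featureValues(table_a)[ids, , drop = FALSE]
  B <- featureValues(table_b)[ids, , drop = FALSE]
  sel <- which(edges$screen_pass)
  for (i in sel) {
    edges$p_posthoc[i] <- sameDonorPosthoc(A[, edges$feature_a[i]],
                                           B[, edges$feature_b[i]], subj)
  }
  edges$robust <- edges$screen_pass & !is.na(edges$p_posthoc) &
    edges$p_posthoc < posthoc_threshold
  edges
}

robust_pairs <- function(edges, a_col = "feature_a", b_col = "feature_b") {
  e <- edges[which(edges$robust), , drop = FALSE]
  if (!nrow(e)) return(e)
  e
}

#' Assemble phenotype-immune-microbiome triplets
#'
#' Enumerates clinical x immune x microbiome feature combinations and
#' retains a triplet when at least two of its three pairwise edges are
#' robust (screen FDR gate plus same-donor post-hoc) and at least one
#' member feature was independently flagged by the intervention contrast
#' screen.
#'
#' @param edges_clin_imm,edges_clin_mic,edges_imm_mic `EdgeSet`s from
#'   [posthocEdges()] for the three space pairs (orientation: clinical
#'   features as `feature_a` in the first two; immune as `feature_a` in the
#'   third).
#' @param contrast_hits character vector of intervention-affected feature
#'   ids (see [contrastHits()]).
#' @return data.frame: `clinical_feature`, `immune_feature`,
#'   `microbiome_feature`, `edge_ci`, `edge_cm`, `edge_im` (robust flags),
#'   `rho_ci`, `rho_cm`, `rho_im`, `n_significant_edges`,
#'   `intervention_hit` (comma-joined member ids in `contrast_hits`).
#' @export
buildTriplets <- function(edges_clin_imm, edges_clin_mic, edges_imm_mic,
                          contrast_hits) {
  eci <- robust_pairs(edges_clin_imm)
  ecm <- robust_pairs(edges_clin_mic)
  eim <- robust_pairs(edges_imm_mic)
  rho_of <- function(edges, fa, fb) {
    i <- match(paste(fa, fb), paste(edges$feature_a, edges$feature_b))
    edges$rho[i]
  }
  robust_of <- function(edges, fa, fb) {
    i <- match(paste(fa, fb), paste(edges$feature_a, edges$feature_b))
    !is.na(i) & !is.na(edges$robust[i]) & edges$robust[i]
  }
  # candidate triplets: union over pairs of robust edges sharing a member
  cand <- list()
  if (nrow(eci) && nrow(ecm)) {
    j <- merge(eci[c("feature_a", "feature_b")], ecm[c("feature_a", "feature_b")],
               by = "feature_a", suffixes = c("_imm", "_mic"))
    if (nrow(j)) cand[[1]] <- data.frame(clin = j$feature_a, imm = j$feature_b_imm,
                                         mic = j$feature_b_mic)
  }
  if (nrow(eci) && nrow(eim)) {
    j <- merge(eci[c("feature_a", "feature_b")], eim[c("feature_a", "feature_b")],
               by.x = "feature_b", by.y = "feature_a")
    if (nrow(j)) cand[[2]] <- data.frame(clin = j$feature_a, imm = j$feature_b,
                                         mic = j$feature_b.y)
  }
  if (nrow(ecm) && nrow(eim)) {
    j <- merge(ecm[c("feature_a", "feature_b")], eim[c("feature_a", "feature_b")],
               by.x = "feature_b", by.y = "feature_b")
    if (nrow(j)) cand[[3]] <- data.frame(clin = j$feature_a.x, imm = j$feature_a.y,
                                         mic = j$feature_b)
  }
  cand <- do.call(rbind, cand)
  empty <- data.frame(clinical_feature = character(), immune_feature = character(),
                      microbiome_feature = character(), edge_ci = logical(),
                      edge_cm = logical(), edge_im = logical(),
                      rho_ci = numeric(), rho_cm = numeric(), rho_im = numeric(),
                      n_significant_edges = integer(), intervention_hit = character())
  if (is.null(cand) || !nrow(cand)) return(empty)
  cand <- unique(cand)
  out <- data.frame(
    clinical_feature = cand$clin, immune_feature = cand$imm,
    microbiome_feature = cand$mic,
    edge_ci = robust_of(edges_clin_imm, cand$clin, cand$imm),
    edge_cm = robust_of(edges_clin_mic, cand$clin, cand$mic),
    edge_im = robust_of(edges_imm_mic, cand$imm, cand$mic),
    rho_ci = rho_of(edges_clin_imm, cand$clin, cand$imm),
    rho_cm = rho_of(edges_clin_mic, cand$clin, cand$mic),
    rho_im = rho_of(edges_imm_mic, cand$imm, cand$mic),
    stringsAsFactors = FALSE)
  out$n_significant_edges <- out$edge_ci + out$edge_cm + out$edge_im
  hit <- function(r) {
    members <- c(out$clinical_feature[r], out$immune_feature[r], out$microbiome_feature[r])
    paste(members[members %in% contrast_hits], collapse = ",")
  }
  out$intervention_hit <- vapply(seq_len(nrow(out)), hit, "")
  out <- out[out$n_significant_edges >= 2 & nzchar(out$intervention_hit), , drop = FALSE]
  rownames(out) <- NULL
  out
}
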