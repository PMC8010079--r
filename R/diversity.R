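#' Alpha diversity of a count vector
#'
#' Standard within-sample diversity summaries of a taxon count vector:
#' species richness, Shannon entropy (natural log), Pielou evenness
#' (Shannon / log richness), Simpson (1 - sum p^2), inverse Simpson
#' (1 / sum p^2) and the bias-corrected Chao1 estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, which stays defined when no
#' doubletons are observed.
#'
#' @param counts_row non-negative counts with positive sum.
#' @param metric one of `"richness"`, `"shannon"`, `"evenness"`,
#'   `"simpson"`, `"inv_simpson"`, `"chao1"`.
#' @param base logarithm base for Shannon/evenness (default natural log).
#' @return a single numeric value.
#' @examples
#' alphaDiversity(c(5, 5, 5, 5), "shannon")  # log(4)
#' @export
alphaDiversity <- function(counts_row,
                           metric = c("richness", "shannon", "evenness",
                                      "simpson", "inv_simpson", "chao1"),
                           base = exp(1)) {
  metric <- match.arg(metric)
  if (any(counts_row < 0)) stop("negative counts")
  tot <- sum(counts_row)
  if (tot <= 0) stop("all-zero count row: diversity undefined")
  p <- counts_row[counts_row > 0] / tot
  S <- length(p)
  switch(metric,
    richness = S,
    shannon = -sum(p * log(p, base = base)),
    evenness = if (S == 1) NA_real_ else (-sum(p * log(p, base = base))) / log(S, base = base),
    simpson = 1 - sum(p^2),
    inv_simpson = 1 / sum(p^2),
    chao1 = {
      f1 <- sum(counts_row == 1); f2 <- sum(counts_row == 2)
      S + f1 * (f1 - 1) / (2 * (f2 + 1))
    })
}

#' Between-sample distance matrix
#'
#' Bray-Curtis dissimilarity `sum|x-y| / sum(x+y)` for (rarefied) taxon
#' profiles, or Euclidean distance for immune profiles. Bray-Curtis is a
#' semimetric: no triangle inequality is asserted. A pair of all-zero
#' samples has Bray-Curtis distance 0 (with a warning).
#'
#' @param table a [FeatureTable-class] (samples x features).
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @return list of class `DistanceMatrix`: `values` (symmetric matrix,
#'   zero diagonal), `sample_ids`, `metric`.
#' @examples
#' m <- rbind(`a:V1` = c(2, 0), `b:V1` = c(1, 1))
#' colnames(m) <- c("t1", "t2")
#' betaDistance(featureTable(m, "taxa16S", "counts"), "bray-curtis")$values
#' @export
betaDistance <- function(table, metric = c("bray-curtis", "euclidean")) {
  metric <- match.arg(metric)
  m <- featureValues(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (metric == "euclidean") {
    g <- tcrossprod(m)
    sq <- diag(g)
    d2 <- outer(sq, sq, "+") - 2 * g
    d <- sqrt(pmax(d2, 0))
  } else {
    if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
    rs <- rowSums(m)
    warned <- FALSE
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      denom <- rs[i] + rs[j]
      if (denom == 0) {
        if (!warned) { warning("all-zero sample pair: Bray-Curtis set to 0"); warned <- TRUE }
        val <- 0
      } else val <- sum(abs(m[i, ] - m[j, ])) / denom
      d[i, j] <- d[j, i] <- val
    }
  }
  diag(d) <- 0
  structure(list(values = d, sample_ids = rownames(m), metric = metric),
            class = "DistanceMatrix")
}

as_dist_matrix <- function(dist) {
  if (inherits(dist, "DistanceMatrix")) dist$values
  else if (inherits(dist, "dist")) as.matrix(dist)
  else if (is.list(dist) && !is.null(dist$values)) as.matrix(dist$values)
  else as.matrix(dist)
}

#' Principal coordinates analysis
#'
#' Classical metric multidimensional scaling: Gower double-centering of
#' `-D^2 / 2` followed by eigendecomposition. Coordinates are returned for
#' positive-eigenvalue axes only (`eigenvector * sqrt(eigenvalue)`), ordered
#' by descending eigenvalue; negative eigenvalues (possible for semimetric
#' input such as Bray-Curtis) are reported but contribute no axis.
#'
#' @param dist a `DistanceMatrix` (or square symmetric matrix / `dist`).
#' @param k number of axes to return (default all positive ones).
#' @return list of class `OrdinationResult`: `coordinates` (samples x k),
#'   `eigenvalues` (all, descending), `proportion_explained` (of the sum of
#'   positive eigenvalues).
#' @export
runPcoa <- function(dist, k = NULL) {
  d <- as_dist_matrix(dist)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  ev <- e$values
  pos <- which(ev > 1e-8 * max(abs(ev), 1))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  keep <- pos[seq_len(k)]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]), length(keep))
  dimnames(coords) <- list(rownames(d),
                           if (length(keep)) paste0("PCo", seq_along(keep)))
  prop <- if (length(keep)) ev[keep] / sum(ev[ev > 0]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop),
            class = "OrdinationResult")
}

#' Per-subject ordination displacement vectors
#'
#' For paired-visit visualisation: the coordinate difference of each subject
#' between two visits on the first `k` ordination axes (e.g. the fasting
#' delta V2-V1 and refeeding delta V3-V2).
#'
#' @param ord an `OrdinationResult` whose samples are `subject:visit` ids.
#' @param from_visit,to_visit visit labels.
#' @param k number of axes (default 2).
#' @return matrix of per-subject displacement vectors.
#' @export
ordinationDeltas <- function(ord, from_visit, to_visit, k = 2L) {
  co <- ord$coordinates[, seq_len(min(k, ncol(ord$coordinates))), drop = FALSE]
  parts <- do.call(rbind, strsplit(rownames(co), ":", fixed = TRUE))
  subj <- unique(parts[, 1])
  out <- t(vapply(subj, function(s) {
    i1 <- which(parts[, 1] == s & parts[, 2] == from_visit)
    i2 <- which(parts[, 1] == s & parts[, 2] == to_visit)
    if (length(i1) != 1L || length(i2) != 1L) return(rep(NA_real_, ncol(co)))
    co[i2, ] - co[i1, ]
  }, numeric(ncol(co))))
  rownames(out) <- subj
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Donor-stratified PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix,
#' with the permutation null restricted to shuffling group labels within
#' each stratum (donor), the appropriate exchangeability scheme for
#' repeated-measures designs. The pseudo-F statistic partitions the total
#' sum of squared distances into between- and within-group components
#' (`F = (SSB/(a-1)) / (SSW/(N-a))`); the p-value uses the add-one rule
#' `p = (1 + #(F* >= F_obs)) / (1 + n_permutations)`.
#'
#' @param dist a `DistanceMatrix` (or square matrix / `dist`).
#' @param groups factor of group labels (e.g. visit), length n.
#' @param strata factor of stratum labels (e.g. subject), length n.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed; deterministic given the seed.
#' @return list of class `PermanovaResult`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanovaStratified <- function(dist, groups, strata, n_permutations = 999L,
                                seed = 1L) {
  n_permutations <- as.integer(n_permutations)
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  groups <- as.factor(groups); strata <- as.factor(strata)
  stopifnot(length(groups) == n, length(strata) == n)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  d2 <- d^2
  sst <- sum(d2) / (2 * n)
  a <- nlevels(droplevels(groups))

  ssw_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) < 2) next
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  f_of <- function(g) {
    ssw <- ssw_of(g)
    ssb <- sst - ssw
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)

  strata_idx <- split(seq_len(n), strata)
  degenerate <- vapply(strata_idx, function(ix)
    length(unique(groups[ix])) < 2, logical(1))
  if (all(degenerate)) {
    warning("all strata are degenerate (constant group labels): p = 1")
    return(structure(list(pseudo_F = f_obs, p_value = 1,
                          n_permutations = n_permutations, seed = seed),
                     class = "PermanovaResult"))
  }
  count <- with_local_seed(seed, {
    cnt <- 0L
    gp <- groups
    for (b in seq_len(n_permutations)) {
      for (ix in strata_idx) gp[ix] <- groups[ix][sample.int(length(ix))]
      if (f_of(gp) >= f_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "PermanovaResult")
}
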