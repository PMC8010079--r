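#' Read / write a feature table as TSV
#'
#' Feature tables are stored as UTF-8 tab-separated text with a header row of
#' feature ids and the first column holding sample ids. Round-trips are exact
#' at full double precision.
#'
#' @param path file path.
#' @param space,unit tags for the resulting [FeatureTable-class].
#' @return `readFeatureTable` returns a [FeatureTable-class];
#'   `writeFeatureTable` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1:V1", "s2:V1"), c("fA", "fB")))
#' writeFeatureTable(featureTable(m, "immune", "absolute"), tf)
#' readFeatureTable(tf, "immune", "absolute")
#' @export
readFeatureTable <- function(path, space, unit) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  feat <- hdr[-1]
  if (anyDuplicated(feat))
    stop("duplicated feature id(s) in ", path, ": ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = c("character", rep("numeric", length(feat))))
  if (anyDuplicated(df[[1]]))
    stop("duplicated sample id(s) in ", path, ": ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (unit %in% c("counts", "relative") && any(m < 0, na.rm = TRUE)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', feature '%s' in %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]], path))
  }
  featureTable(m, space, unit)
}

#' @rdname readFeatureTable
#' @param table a [FeatureTable-class] to write.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "FeatureTable"))
  sid <- sampleIds(table)
  if (is.null(sid)) sid <- character(0)
  df <- data.frame(sample_id = sid, table@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each library without replacement (multivariate hypergeometric
#' draw) to a common depth, the standard device for removing sequencing-depth
#' bias before diversity and abundance analysis. With `depth = "auto"` the
#' depth is `floor(0.95 * min(library size))`, the convention of rarefaction
#' toolkits that keep 95% of the smallest library.
#'
#' @param table a [FeatureTable-class] with `unit == "counts"`.
#' @param depth integer target depth, or `"auto"`.
#' @param seed integer; the subsampling is deterministic given the seed.
#' @param on_small `"drop"` (default) drops samples whose library is below
#'   `depth` with a warning; `"error"` stops instead.
#' @return A rarefied [FeatureTable-class]; every retained row sums exactly
#'   to `depth`.
#' @examples
#' m <- matrix(rpois(40, 50), 4, 10,
#'             dimnames = list(paste0("s", 1:4, ":V1"), paste0("t", 1:10)))
#' r <- rarefyTable(featureTable(m, "taxa16S", "counts"), depth = 100, seed = 1)
#' rowSums(featureValues(r))
#' @export
rarefyTable <- function(table, depth = "auto", seed = 1L, on_small = c("drop", "error")) {
  stopifnot(is(table, "FeatureTable"), table@unit == "counts")
  on_small <- match.arg(on_small)
  m <- table@values
  libs <- rowSums(m)
  if (identical(depth, "auto")) depth <- floor(0.95 * min(libs))
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  small <- libs < depth
  if (any(small)) {
    if (on_small == "error")
      stop("library below rarefaction depth: ", paste(rownames(m)[small], collapse = ", "))
    warning(sprintf("dropping %d sample(s) with library < %d: %s",
                    sum(small), depth, paste(rownames(m)[small], collapse = ", ")))
    m <- m[!small, , drop = FALSE]
  }
  out <- with_local_seed(seed, {
    t(apply(m, 1L, rarefy_row, depth = depth))
  })
  dimnames(out) <- dimnames(m)
  featureTable(out, table@space, "counts")
}

# sequential multivariate hypergeometric draw: exact sampling w/o replacement
rarefy_row <- function(counts, depth) {
  counts <- as.integer(round(counts))
  total <- sum(counts)
  if (total == depth) return(counts)
  out <- integer(length(counts))
  remaining <- total
  todraw <- depth
  for (j in seq_along(counts)) {
    if (todraw == 0L) break
    cj <- counts[j]
    if (cj == 0L) next
    x <- rhyper(1L, m = cj, n = remaining - cj, k = todraw)
    out[j] <- x
    todraw <- todraw - x
    remaining <- remaining - cj
  }
  out
}

#' Bin features into groups (KO-to-module averaging, taxonomic rollup)
#'
#' Functional profiles are conventionally summarised by averaging gene-family
#' (KO) abundances within each curated module, while taxonomic profiles are
#' rolled up by summation to more rootwards ranks. `method = "mean"` divides
#' by the full group size from the mapping, so members absent from the table
#' contribute zero; `"sum"` (alias `"taxonomic-rollup"`) adds member values.
#'
#' @param table a [FeatureTable-class].
#' @param mapping named character vector: names are member feature ids,
#'   values are group ids.
#' @param method `"mean"`, `"sum"` or `"taxonomic-rollup"`.
#' @param space,unit tags for the result; default keeps the input's.
#' @return A [FeatureTable-class] of group values.
#' @examples
#' m <- matrix(c(2, 4), 1, 2, dimnames = list("s1:V1", c("K1", "K2")))
#' tab <- featureTable(m, "functionalModule", "relative")
#' featureValues(binFeatures(tab, c(K1 = "M1", K2 = "M1"), "mean"))  # 3
#' @export
binFeatures <- function(table, mapping, method = c("mean", "sum", "taxonomic-rollup"),
                        space = measurementSpace(table), unit = measurementUnit(table)) {
  stopifnot(is(table, "FeatureTable"), !is.null(names(mapping)))
  method <- match.arg(method)
  groups <- split(names(mapping), unname(mapping))
  m <- table@values
  cols <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    present <- intersect(members, colnames(m))
    if (!length(present)) return(NULL)
    s <- rowSums(m[, present, drop = FALSE])
    if (method == "mean") s / length(members) else s
  })
  names(cols) <- names(groups)
  empty <- vapply(cols, is.null, logical(1))
  if (any(empty)) {
    warning("excluding group(s) with no member present: ",
            paste(names(cols)[empty], collapse = ", "))
    cols <- cols[!empty]
  }
  if (!length(cols)) stop("no group has any member present in the table")
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(m)
  featureTable(out, space, unit)
}

#' Normalize a medication ledger to baseline-referenced doses
#'
#' For each (subject, drug) trajectory the dose is divided by a reference:
#' the baseline dose when the drug was taken at baseline, otherwise the
#' lowest nonzero dose across visits (covering drugs initiated mid-study).
#' An unchanged regimen thus maps to 1 at every visit, discontinuation to 0,
#' and halving to 0.5. The per-visit sum of normalized doses over all agents
#' (`agent_sum`) is the continuous medication-load covariate used by the
#' deconfounded screen and the responder stratification.
#'
#' @param ledger data.frame with columns `subject_id`, `drug_class`, `drug`,
#'   `visit`, `dose` (long format; at most one row per subject/drug/visit;
#'   absent rows mean dose 0).
#' @param visits visit labels in temporal order; default the sorted unique
#'   visits of the ledger. The first is the baseline.
#' @param agent_sum_mode `"dose"` (default) sums normalized doses;
#'   `"count"` counts agents with nonzero dose.
#' @return list with `normalized` (subject_id, drug_class, drug, visit,
#'   normalized_dose) and `agent_sum` (subject_id, visit, agent_sum).
#' @examples
#' led <- data.frame(subject_id = "P1", drug_class = "diuretics", drug = "hct",
#'                   visit = c("V1", "V3"), dose = c(5, 10))
#' normalizeMedication(led, visits = c("V1", "V2", "V3"))$normalized
#' @export
normalizeMedication <- function(ledger, visits = NULL,
                                agent_sum_mode = c("dose", "count")) {
  agent_sum_mode <- match.arg(agent_sum_mode)
  need <- c("subject_id", "drug_class", "drug", "visit", "dose")
  if (!all(need %in% names(ledger)))
    stop("ledger must have columns: ", paste(need, collapse = ", "))
  if (any(ledger$dose < 0)) stop("negative dose in ledger")
  if (is.null(visits)) visits <- sort(unique(as.character(ledger$visit)))
  baseline <- visits[1]
  if (anyDuplicated(ledger[c("subject_id", "drug", "visit")]))
    stop("more than one record per (subject, drug, visit)")

  key <- interaction(ledger$subject_id, ledger$drug, drop = TRUE)
  parts <- split(seq_len(nrow(ledger)), key)
  rows <- lapply(parts, function(idx) {
    sub <- ledger[idx, , drop = FALSE]
    dose <- setNames(rep(0, length(visits)), visits)
    dose[as.character(sub$visit)] <- sub$dose
    if (all(dose == 0)) {
      warning(sprintf("dropping all-zero dose trajectory: %s / %s",
                      sub$subject_id[1], sub$drug[1]))
      return(NULL)
    }
    ref <- if (dose[baseline] > 0) dose[baseline] else min(dose[dose > 0])
    data.frame(subject_id = sub$subject_id[1], drug_class = sub$drug_class[1],
               drug = sub$drug[1], visit = visits,
               normalized_dose = unname(dose / ref),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  norm <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(norm))
    norm <- data.frame(subject_id = character(), drug_class = character(),
                       drug = character(), visit = character(),
                       normalized_dose = numeric())
  contrib <- if (agent_sum_mode == "dose") norm$normalized_dose
             else as.numeric(norm$normalized_dose > 0)
  if (nrow(norm)) {
    agg <- aggregate(contrib,
                     by = list(subject_id = norm$subject_id, visit = norm$visit), FUN = sum)
    names(agg)[3] <- "agent_sum"
  } else {
    agg <- data.frame(subject_id = character(), visit = character(), agent_sum = numeric())
  }
  list(normalized = norm, agent_sum = agg, visits = visits, mode = agent_sum_mode)
}

#' Classify per-subject medication change between two visits
#'
#' @param norm result of [normalizeMedication()].
#' @param from_visit,to_visit visit labels.
#' @param tol numeric tolerance for "unchanged".
#' @return named character vector (subject -> "reduced"/"unchanged"/"increased").
#'   Subjects with no ledger entries are "unchanged" (agent sum 0 at both visits).
#' @export
medicationChangeClass <- function(norm, from_visit, to_visit, tol = 1e-9) {
  agg <- norm$agent_sum
  subjects <- unique(agg$subject_id)
  get <- function(v) {
    x <- setNames(rep(0, length(subjects)), subjects)
    sel <- agg$visit == v
    x[agg$subject_id[sel]] <- agg$agent_sum[sel]
    x
  }
  d <- get(to_visit) - get(from_visit)
  setNames(ifelse(d < -tol, "reduced", ifelse(d > tol, "increased", "unchanged")),
           subjects)
}

#' Homeostasis model assessment (HOMA) index
#'
#' `insulin (µU/ml) * glucose (mmol/l) / 22.5`, the standard surrogate for
#' insulin resistance.
#'
#' @param insulin fasting blood insulin, µU/ml.
#' @param glucose fasting blood glucose, mmol/l.
#' @return dimensionless HOMA index (vectorized).
#' @examples
#' computeHoma(22.5, 1)  # 1
#' @export
computeHoma <- function(insulin, glucose) {
  if (any(insulin < 0, na.rm = TRUE) || any(glucose < 0, na.rm = TRUE))
    stop("insulin and glucose must be non-negative")
  insulin * glucose / 22.5
}

#' Export / import a cohort as a directory of TSV files
#'
#' Writes `metadata.tsv`, `taxa_counts.tsv`, `modules.tsv`, `immune.tsv`,
#' `clinical.tsv` and `medication.tsv` (long format). `importCohortTables`
#' reads them back into a list; round-trips are exact.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param directory output directory (created if needed).
#' @return `exportCohort`: the directory, invisibly. `importCohortTables`:
#'   a list with `metadata`, `taxa`, `modules`, `immune`, `clinical`,
#'   `medication`.
#' @export
exportCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) write.table(df, file.path(directory, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  w(cohort@metadata, "metadata.tsv")
  writeFeatureTable(cohort@taxa, file.path(directory, "taxa_counts.tsv"))
  writeFeatureTable(cohort@modules, file.path(directory, "modules.tsv"))
  writeFeatureTable(cohort@immune, file.path(directory, "immune.tsv"))
  writeFeatureTable(cohort@clinical, file.path(directory, "clinical.tsv"))
  w(cohort@medication, "medication.tsv")
  invisible(directory)
}

#' @rdname exportCohort
#' @export
importCohortTables <- function(directory) {
  rd <- function(f, classes = NA) read.delim(file.path(directory, f), sep = "\t",
                                             check.names = FALSE, stringsAsFactors = FALSE)
  list(metadata = rd("metadata.tsv"),
       taxa = readFeatureTable(file.path(directory, "taxa_counts.tsv"), "taxa16S", "counts"),
       modules = readFeatureTable(file.path(directory, "modules.tsv"), "functionalModule", "relative"),
       immune = readFeatureTable(file.path(directory, "immune.tsv"), "immune", "absolute"),
       clinical = readFeatureTable(file.path(directory, "clinical.tsv"), "clinical", "absolute"),
       medication = rd("medication.tsv"))
}
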