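#' @import methods
#' @importFrom stats approx aggregate anova as.formula coef complete.cases
#'   cor pchisq pnorm pt qnorm quantile rbinom rhyper rlnorm rmultinom rnorm
#'   runif sd setNames var p.adjust wilcox.test plogis logLik
#' @importFrom utils head read.delim write.table
NULL

VALID_SPACES <- c("taxa16S", "taxaShotgun", "functionalModule", "immune", "clinical")
VALID_UNITS  <- c("counts", "relative", "absolute")

#' FeatureTable: a samples-by-features measurement matrix
#'
#' The central data container: a numeric matrix with samples in rows and
#' features in columns, tagged with the measurement space it comes from
#' (16S or shotgun taxa, functional modules, immune-cell measurements,
#' clinical phenotypes) and the unit of measurement. Row names are composite
#' sample ids (`subject:visit`), column names are feature ids.
#'
#' @slot values numeric matrix, samples x features.
#' @slot space character; one of `"taxa16S"`, `"taxaShotgun"`,
#'   `"functionalModule"`, `"immune"`, `"clinical"`.
#' @slot unit character; one of `"counts"`, `"relative"`, `"absolute"`.
#'
#' @seealso [featureTable()], [rarefyTable()], [binFeatures()]
#' @export
setClass("FeatureTable",
  representation(values = "matrix", space = "character", unit = "character"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@space) != 1L || !object@space %in% VALID_SPACES)
    msg <- c(msg, sprintf("space must be one of: %s", paste(VALID_SPACES, collapse = ", ")))
  if (length(object@unit) != 1L || !object@unit %in% VALID_UNITS)
    msg <- c(msg, sprintf("unit must be one of: %s", paste(VALID_UNITS, collapse = ", ")))
  # R stores zero-length dimnames as NULL, so empty extents are exempt
  if ((nrow(v) > 0 && is.null(rownames(v))) || (ncol(v) > 0 && is.null(colnames(v))))
    msg <- c(msg, "values must have sample ids as rownames and feature ids as colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicated sample ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicated feature ids")
  }
  if (length(object@unit) == 1L && object@unit %in% c("counts", "relative") &&
      is.numeric(v) && length(v) && any(v < 0, na.rm = TRUE))
    msg <- c(msg, sprintf("negative values not allowed for unit '%s'", object@unit))
  if (length(object@unit) == 1L && object@unit == "counts" && is.numeric(v) &&
      length(v) && any(abs(v - round(v)) > 1e-9, na.rm = TRUE))
    msg <- c(msg, "unit 'counts' requires integer-valued entries")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureTable
#'
#' @param values numeric matrix (samples x features) with row and column names.
#' @param space measurement space tag.
#' @param unit measurement unit tag.
#' @return A [FeatureTable-class] object.
#' @examples
#' m <- matrix(1:4, 2, 2, dimnames = list(c("s1:V1", "s1:V2"), c("f1", "f2")))
#' featureTable(m, "immune", "absolute")
#' @export
featureTable <- function(values, space, unit) {
  new("FeatureTable", values = as.matrix(values), space = space, unit = unit)
}

#' @describeIn featureTable sample ids (rownames)
#' @param x a `FeatureTable`.
#' @export
sampleIds <- function(x) rownames(x@values)

#' @describeIn featureTable feature ids (colnames)
#' @export
featureIds <- function(x) colnames(x@values)

#' @describeIn featureTable the numeric matrix
#' @export
featureValues <- function(x) x@values

#' @describeIn featureTable the measurement-space tag
#' @export
measurementSpace <- function(x) x@space

#' @describeIn featureTable the unit tag
#' @export
measurementUnit <- function(x) x@unit

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s, %s]: %d samples x %d features\n",
              object@space, object@unit, nrow(object@values), ncol(object@values)))
  if (nrow(object@values) && ncol(object@values))
    cat("  features: ", paste(head(featureIds(object), 4L), collapse = ", "),
        if (ncol(object@values) > 4L) ", ..." else "", "\n", sep = "")
})

#' @export
setMethod("dim", "FeatureTable", function(x) dim(x@values))

#' Subset a FeatureTable by samples and/or features
#' @param x a `FeatureTable`; `i` samples, `j` features.
#' @param i,j,...,drop as in matrix subsetting; `drop` ignored.
#' @export
setMethod("[", "FeatureTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  new("FeatureTable", values = v, space = x@space, unit = x@unit)
})

#' SyntheticCohort: a simulated intervention cohort with ground truth
#'
#' Bundles the per-sample metadata, the four measurement tables, the
#' long-format medication ledger and the ground-truth record of everything
#' planted by the generator. The `latent` slot keeps the generator's latent
#' log-abundance state so that correlated triplets can be planted after the
#' fact (see [plantTriplet()]).
#'
#' @slot metadata data.frame, one row per (subject, visit).
#' @slot taxa,modules,immune,clinical [FeatureTable-class] objects.
#' @slot medication data.frame: subject_id, drug_class, drug, visit, dose.
#' @slot truth list: differential_features, confounded_features,
#'   planted_triplets, responder_labels, informative_predictors.
#' @slot latent list of internal generator state.
#' @slot design the [cohortDesign()] used.
#' @export
setClass("SyntheticCohort",
  representation(metadata = "data.frame", taxa = "FeatureTable",
                 modules = "FeatureTable", immune = "FeatureTable",
                 clinical = "FeatureTable", medication = "data.frame",
                 truth = "list", latent = "list", design = "list"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- object@metadata$sample_id
  for (slot in c("taxa", "modules", "immune", "clinical")) {
    tab <- slot(object, slot)
    if (nrow(tab@values) && !identical(sampleIds(tab), ids))
      msg <- c(msg, sprintf("sample ids of '%s' do not match metadata", slot))
  }
  if (anyDuplicated(object@metadata[c("subject_id", "visit")]))
    msg <- c(msg, "metadata must have one row per (subject, visit)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  md <- object@metadata
  cat(sprintf("SyntheticCohort: %d subjects x %d visits (%d samples)\n",
              length(unique(md$subject_id)), length(unique(md$visit)), nrow(md)))
  cat(sprintf("  arms: %s\n", paste(sprintf("%s=%d", names(table(md$arm[md$visit == md$visit[1]])),
              table(md$arm[md$visit == md$visit[1]])), collapse = ", ")))
  cat(sprintf("  tables: taxa %d, modules %d, immune %d, clinical %d features\n",
              ncol(object@taxa@values), ncol(object@modules@values),
              ncol(object@immune@values), ncol(object@clinical@values)))
  cat(sprintf("  truth: %d differential, %d confounded, %d triplets planted\n",
              nrow(object@truth$differential_features),
              length(object@truth$confounded_features),
              length(object@truth$planted_triplets)))
})

#' @describeIn simulateCohort per-sample metadata of a cohort
#' @export
cohortMetadata <- function(cohort) cohort@metadata

#' @describeIn simulateCohort one of the measurement tables
#' @param table which table: taxa, modules, immune or clinical.
#' @export
cohortTable <- function(cohort, table = c("taxa", "modules", "immune", "clinical")) {
  slot(cohort, match.arg(table))
}

#' @describeIn simulateCohort the long-format medication ledger
#' @export
cohortMedication <- function(cohort) cohort@medication

#' @describeIn simulateCohort the ground-truth record of planted structure
#' @export
cohortTruth <- function(cohort) cohort@truth

# run code under a temporary RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
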