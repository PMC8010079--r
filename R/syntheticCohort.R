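#' Describe a synthetic intervention cohort
#'
#' Collects every knob of the generator into a validated design object.
#' Defaults emulate a two-arm fasting-plus-DASH / DASH-only trial in
#' metabolic-syndrome patients: ~35 subjects per arm, three visits
#' (baseline V1, one week V2, three months V3), compositional taxon counts
#' at log-normally spread sequencing depth, within-subject correlation from
#' subject-level random intercepts, antihypertensive medication-dose changes
#' that confound a subset of features, and a responder/non-responder mixture
#' in ambulatory systolic blood pressure.
#'
#' @param n_subjects_per_arm subjects per arm (default 35).
#' @param visits ordered visit labels; exactly three.
#' @param n_taxa,n_modules,n_immune,n_clinical features per table.
#' @param sequencing_depth_mean mean library size (reads) for taxon counts.
#' @param sequencing_depth_sdlog log-normal spread of library sizes.
#' @param within_subject_corr fraction of latent variance carried by the
#'   subject random intercept, in [0, 1).
#' @param med_confounded_features number of taxa whose latent abundance
#'   tracks a medication dose (dose-proportional shift).
#' @param confound_strength latent shift (in total-SD units) per unit change
#'   in the subject's summed normalized medication dose, for confounded
#'   features.
#' @param planted_effects list of [plantedEffect()] records.
#' @param responder_fraction fraction of fasting-arm subjects that are
#'   blood-pressure responders (default 0.69, i.e. 22 of 32).
#' @param responder_sbp_drop_mmhg planted V3-V1 24h-ambulatory SBP drop for
#'   responders, mmHg (default 8, the responder median).
#' @param informative_predictors number of immune features whose baseline
#'   level separates responders from non-responders.
#' @param informative_separation standardized responder/non-responder
#'   separation of those features (default 1.5 SD).
#' @param seed integer; single global seed, all draws flow from it.
#' @return A list of class `CohortDesign`.
#' @seealso [simulateCohort()]
#' @export
cohortDesign <- function(n_subjects_per_arm = 35L,
                         visits = c("V1", "V2", "V3"),
                         n_taxa = 200L, n_modules = 80L, n_immune = 120L,
                         n_clinical = 12L,
                         sequencing_depth_mean = 20000,
                         sequencing_depth_sdlog = 0.25,
                         within_subject_corr = 0.5,
                         med_confounded_features = 20L,
                         confound_strength = 4,
                         planted_effects = list(),
                         responder_fraction = 0.69,
                         responder_sbp_drop_mmhg = 8,
                         informative_predictors = 0L,
                         informative_separation = 1.5,
                         seed = 1L) {
  d <- list(n_subjects_per_arm = as.integer(n_subjects_per_arm), visits = visits,
            n_taxa = as.integer(n_taxa), n_modules = as.integer(n_modules),
            n_immune = as.integer(n_immune), n_clinical = as.integer(n_clinical),
            sequencing_depth_mean = sequencing_depth_mean,
            sequencing_depth_sdlog = sequencing_depth_sdlog,
            within_subject_corr = within_subject_corr,
            med_confounded_features = as.integer(med_confounded_features),
            confound_strength = confound_strength,
            planted_effects = planted_effects,
            responder_fraction = responder_fraction,
            responder_sbp_drop_mmhg = responder_sbp_drop_mmhg,
            informative_predictors = as.integer(informative_predictors),
            informative_separation = informative_separation,
            seed = as.integer(seed))
  stopifnot(length(d$visits) == 3L,
            d$n_subjects_per_arm >= 0L, d$n_taxa >= 0L, d$n_modules >= 0L,
            d$n_immune >= 0L, d$n_clinical >= 0L,
            d$within_subject_corr >= 0, d$within_subject_corr < 1,
            d$responder_fraction >= 0, d$responder_fraction <= 1,
            d$med_confounded_features >= 0L)
  for (pe in d$planted_effects) {
    if (!inherits(pe, "PlantedEffect")) stop("planted_effects must be plantedEffect() records")
    if (!pe$visit_of_onset %in% d$visits) stop("visit_of_onset not among visits")
  }
  class(d) <- "CohortDesign"
  d
}

#' Describe one planted intervention effect
#'
#' A `reversible` effect shifts the feature at the onset visit only (the
#' fasting signature that reverts on refeeding); a `sustained` effect
#' persists from the onset visit through the final visit. The shift is
#' applied in latent log space to fasting-arm samples and calibrated so the
#' unpaired V(onset)-vs-V1 Cliff's delta matches `target_cliffs_delta`.
#'
#' @param feature_id feature to shift: a feature id, a column index, or `NA`
#'   (default) to let the generator pick a reliably observed feature.
#' @param space one of `"taxa"`, `"module"`, `"immune"`, `"clinical"`.
#' @param pattern `"reversible"` or `"sustained"`.
#' @param target_cliffs_delta signed target effect size in [-1, 1].
#' @param visit_of_onset visit at which the shift starts (default `"V2"`).
#' @return list of class `PlantedEffect`.
#' @export
plantedEffect <- function(feature_id = NA, space = c("taxa", "module", "immune", "clinical"),
                          pattern = c("reversible", "sustained"),
                          target_cliffs_delta, visit_of_onset = "V2") {
  space <- match.arg(space)
  pattern <- match.arg(pattern)
  stopifnot(abs(target_cliffs_delta) <= 1)
  structure(list(feature_id = feature_id, space = space, pattern = pattern,
                 target_cliffs_delta = target_cliffs_delta,
                 visit_of_onset = visit_of_onset),
            class = "PlantedEffect")
}

# latent shift (in units of total latent SD) giving an expected unpaired
# two-normal-samples Cliff's delta of target
delta_to_shift <- function(target, sigma_tot) {
  sign(target) * sqrt(2) * sigma_tot * qnorm((abs(target) + 1) / 2)
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates metadata, a compositional taxon count table (latent log-normal
#' abundances, multinomial sampling at log-normally distributed depth),
#' continuous functional-module / immune / clinical tables, a medication
#' ledger with dose reductions concentrated in the fasting arm, and a ground
#' truth record of every planted signal. Within-subject correlation is
#' induced by Gaussian subject-level random intercepts on the latent scale.
#' Deterministic given `design$seed`.
#'
#' @param design a [cohortDesign()].
#' @return A [SyntheticCohort-class].
#' @examples
#' co <- simulateCohort(cohortDesign(n_subjects_per_arm = 6, n_taxa = 30,
#'                                   n_modules = 10, n_immune = 10, seed = 7))
#' co
#' @export
simulateCohort <- function(design) {
  stopifnot(inherits(design, "CohortDesign"))
  for (sp in c("taxa", "module", "immune", "clinical")) {
    n_sp <- switch(sp, taxa = design$n_taxa, module = design$n_modules,
                   immune = design$n_immune, clinical = design$n_clinical)
    n_planted <- sum(vapply(design$planted_effects, function(pe) pe$space == sp, logical(1)))
    if (n_planted > n_sp)
      stop("more planted effects in space '", sp, "' than features")
  }
  with_local_seed(design$seed, simulate_cohort_impl(design))
}

simulate_cohort_impl <- function(design) {
  visits <- design$visits
  npa <- design$n_subjects_per_arm
  subjects <- c(sprintf("F%02d", seq_len(npa)), sprintf("D%02d", seq_len(npa)))
  arm <- rep(c("fasting+DASH", "DASH"), each = npa)
  ns <- length(subjects)
  nv <- length(visits)

  md <- data.frame(
    subject_id = rep(subjects, each = nv),
    visit = rep(visits, ns),
    arm = rep(arm, each = nv),
    stringsAsFactors = FALSE)
  md$sample_id <- paste(md$subject_id, md$visit, sep = ":")

  age <- round(rnorm(ns, 60, 8)); age <- pmax(age, 35)
  sex <- sample(c("F", "M"), ns, replace = TRUE, prob = c(0.6, 0.4))
  height <- round(rnorm(ns, 171, 8), 1)
  weight0 <- round(rnorm(ns, 97, 15), 1)
  md$age <- rep(age, each = nv); md$sex <- rep(sex, each = nv)
  md$height <- rep(height, each = nv)

  # responder latent class (fasting arm)
  fasting <- arm == "fasting+DASH"
  responder <- rep(NA, ns)
  responder[fasting] <- runif(sum(fasting)) < design$responder_fraction
  resp_labels <- setNames(ifelse(responder[fasting], "responder", "non-responder"),
                          subjects[fasting])

  # weight trajectories: fasting arm loses weight and keeps most of it off
  wchange <- matrix(0, ns, nv, dimnames = list(subjects, visits))
  wchange[fasting, 2] <- rnorm(sum(fasting), -3.5, 1.0)
  wchange[fasting, 3] <- wchange[fasting, 2] + rnorm(sum(fasting), -0.5, 1.2)
  wchange[!fasting, 2] <- rnorm(sum(!fasting), -0.7, 1.0)
  wchange[!fasting, 3] <- wchange[!fasting, 2] + rnorm(sum(!fasting), -0.3, 1.2)
  md$weight <- round(rep(weight0, each = nv) + as.vector(t(wchange)), 1)
  md$bmi <- md$weight / (md$height / 100)^2

  # 24h ambulatory blood pressure with the planted responder drop at V3
  sbp0 <- rnorm(ns, 132, 9)
  sbp <- matrix(rep(sbp0, nv), ns, nv, dimnames = list(subjects, visits))
  sbp[fasting, 2] <- sbp[fasting, 2] + rnorm(sum(fasting), -5, 3)
  sbp[!fasting, 2] <- sbp[!fasting, 2] + rnorm(sum(!fasting), -1, 2.5)
  drop3 <- numeric(ns)
  drop3[fasting] <- ifelse(responder[fasting],
                           rnorm(sum(fasting), -design$responder_sbp_drop_mmhg, 2.5),
                           rnorm(sum(fasting), -0.3, 1.5))
  drop3[!fasting] <- rnorm(sum(!fasting), -2, 3)
  sbp[, 3] <- sbp[, 3] + drop3
  dbp0 <- rnorm(ns, 81, 8)
  dbp <- matrix(rep(dbp0, nv), ns, nv) + matrix(rnorm(ns * nv, 0, 2), ns, nv) +
    0.35 * (sbp - sbp0)
  md$sbp_24h <- round(as.vector(t(sbp)), 1)
  md$dbp_24h <- round(as.vector(t(dbp)), 1)
  md$map_24h <- round(md$dbp_24h + (md$sbp_24h - md$dbp_24h) / 3, 1)
  md$insulin <- round(rlnorm(nrow(md), log(10), 0.5), 1)
  md$glucose <- round(rnorm(nrow(md), 5.8, 0.8), 2)
  md$homa <- computeHoma(md$insulin, md$glucose)

  # --- medication ledger -----------------------------------------------
  classes <- c("diuretics", "beta-blockers", "calcium-channel blockers",
               "RAS agents", "other antihypertensives")
  led <- list()
  med_change <- rep(FALSE, ns)
  for (i in seq_len(ns)) {
    ndrug <- sample(0:3, 1L, prob = c(0.05, 0.4, 0.35, 0.2))
    if (ndrug == 0) next
    cls <- sample(classes, ndrug)
    dose0 <- sample(c(5, 10, 20), ndrug, replace = TRUE)
    doses <- matrix(rep(dose0, nv), ndrug, nv, dimnames = list(cls, visits))
    p_change <- if (fasting[i]) 0.6 else 0.25
    if (runif(1) < p_change) {
      k <- sample.int(ndrug, 1L)
      f <- if (runif(1) < 0.6) 0.5 else 0
      doses[k, 2:3] <- dose0[k] * f
      med_change[i] <- TRUE
    }
    if (fasting[i] && isTRUE(responder[i]) && runif(1) < 0.5) {
      k <- sample.int(ndrug, 1L)
      doses[k, 3] <- doses[k, 3] * 0.5   # extra reduction at follow-up
    }
    led[[i]] <- data.frame(subject_id = subjects[i],
                           drug_class = rep(cls, nv),
                           drug = rep(paste0(gsub(" .*", "", cls), "_a"), nv),
                           visit = rep(visits, each = ndrug),
                           dose = as.vector(doses), stringsAsFactors = FALSE)
  }
  medication <- if (length(led)) do.call(rbind, led) else
    data.frame(subject_id = character(), drug_class = character(),
               drug = character(), visit = character(), dose = numeric())
  rownames(medication) <- NULL  # zero-dose rows kept: explicit discontinuation

  # per-sample normalized class-dose matrix (for confounding shifts)
  norm <- if (nrow(medication)) normalizeMedication(medication, visits = visits) else NULL
  class_dose <- matrix(0, nrow(md), length(classes),
                       dimnames = list(md$sample_id, classes))
  if (!is.null(norm) && nrow(norm$normalized)) {
    nn <- norm$normalized
    for (r in seq_len(nrow(nn))) {
      sid <- paste(nn$subject_id[r], nn$visit[r], sep = ":")
      class_dose[sid, nn$drug_class[r]] <- class_dose[sid, nn$drug_class[r]] +
        nn$normalized_dose[r]
    }
  }

  sigma_tot <- 1
  rho <- design$within_subject_corr
  sd_b <- sqrt(rho) * sigma_tot
  sd_e <- sqrt(1 - rho) * sigma_tot
  subj_of_sample <- match(md$subject_id, subjects)

  latent_z <- function(nfeat) {
    b <- matrix(rnorm(ns * nfeat, 0, sd_b), ns, nfeat)
    e <- matrix(rnorm(nrow(md) * nfeat, 0, sd_e), nrow(md), nfeat)
    b[subj_of_sample, , drop = FALSE] + e
  }

  # deterministic latent mean: base abundance + planted effects + confounds
  affected_visits <- function(pe) {
    io <- match(pe$visit_of_onset, visits)
    if (pe$pattern == "reversible") visits[io] else visits[io:nv]
  }

  spaces <- list(
    taxa = list(n = design$n_taxa, prefix = "taxon", base = function(n) rnorm(n, 0, 1.5)),
    module = list(n = design$n_modules, prefix = "module", base = function(n) rnorm(n, 0, 1)),
    immune = list(n = design$n_immune, prefix = "imm", base = function(n) rnorm(n, 2, 1)),
    clinical = list(n = design$n_clinical, prefix = "clin", base = function(n) rnorm(n, 0, 1)))

  truth_diff <- list()
  mu <- list(); ids <- list(); base_mean <- list()
  for (sp in names(spaces)) {
    n_sp <- spaces[[sp]]$n
    fid <- sprintf("%s_%03d", spaces[[sp]]$prefix, seq_len(n_sp))
    m0 <- spaces[[sp]]$base(n_sp)
    mu_sp <- matrix(rep(m0, each = nrow(md)), nrow(md), n_sp,
                    dimnames = list(md$sample_id, fid))
    ids[[sp]] <- fid; base_mean[[sp]] <- m0; mu[[sp]] <- mu_sp
  }

  # planted intervention effects: latent shift on fasting-arm samples,
  # restricted to reliably observed features (upper half of base abundance)
  used <- list(taxa = integer(), module = integer(), immune = integer(), clinical = integer())
  for (pe in design$planted_effects) {
    sp <- pe$space
    if (is.character(pe$feature_id)) {
      j <- match(pe$feature_id, ids[[sp]])
      if (is.na(j)) stop("unknown feature id: ", pe$feature_id)
    } else if (is.na(pe$feature_id)) {
      elig <- setdiff(which(base_mean[[sp]] >= stats::median(base_mean[[sp]])), used[[sp]])
      if (!length(elig)) stop("no eligible feature left to plant in space ", sp)
      j <- sample(elig, 1L)
    } else j <- as.integer(pe$feature_id)
    used[[sp]] <- c(used[[sp]], j)
    shift <- delta_to_shift(pe$target_cliffs_delta, sigma_tot)
    rows <- md$arm == "fasting+DASH" & md$visit %in% affected_visits(pe)
    mu[[sp]][rows, j] <- mu[[sp]][rows, j] + shift
    truth_diff[[length(truth_diff) + 1L]] <-
      data.frame(feature_id = ids[[sp]][j], space = sp, pattern = pe$pattern,
                 sign = sign(pe$target_cliffs_delta),
                 target_cliffs_delta = pe$target_cliffs_delta,
                 visit_of_onset = pe$visit_of_onset, stringsAsFactors = FALSE)
  }
  truth_diff <- if (length(truth_diff)) do.call(rbind, truth_diff) else
    data.frame(feature_id = character(), space = character(), pattern = character(),
               sign = numeric(), target_cliffs_delta = numeric(),
               visit_of_onset = character())

  # medication-confounded taxa: latent mean tracks change in normalized
  # class dose (linear, dose-proportional)
  confounded <- character()
  if (design$med_confounded_features > 0 && design$n_taxa > 0) {
    elig <- setdiff(which(base_mean$taxa >= stats::median(base_mean$taxa)), used$taxa)
    if (length(elig) < design$med_confounded_features)
      stop("not enough eligible taxa for the requested confounded set")
    conf_j <- sample(elig, design$med_confounded_features)
    conf_sign <- sample(c(-1, 1), design$med_confounded_features, replace = TRUE)
    base_rows <- match(paste(md$subject_id, visits[1], sep = ":"), rownames(class_dose))
    agent_change <- rowSums(class_dose) - rowSums(class_dose[base_rows, , drop = FALSE])
    for (q in seq_along(conf_j)) {
      mu$taxa[, conf_j[q]] <- mu$taxa[, conf_j[q]] +
        conf_sign[q] * design$confound_strength * agent_change
    }
    confounded <- ids$taxa[conf_j]
  }

  # responder-informative immune features: baseline (all-visit) separation
  informative <- character()
  if (design$informative_predictors > 0 && design$n_immune > 0) {
    elig <- setdiff(seq_len(design$n_immune), used$immune)
    inf_j <- sample(elig, design$informative_predictors)
    inf_sign <- sample(c(-1, 1), design$informative_predictors, replace = TRUE)
    is_resp_sample <- md$subject_id %in% names(resp_labels)[resp_labels == "responder"]
    for (q in seq_along(inf_j)) {
      mu$immune[is_resp_sample, inf_j[q]] <- mu$immune[is_resp_sample, inf_j[q]] +
        inf_sign[q] * design$informative_separation * sigma_tot
    }
    informative <- ids$immune[inf_j]
  }

  # stochastic latent parts and realized tables
  z <- lapply(names(spaces), function(sp) latent_z(spaces[[sp]]$n))
  names(z) <- names(spaces)
  depths <- round(rlnorm(nrow(md), log(design$sequencing_depth_mean),
                         design$sequencing_depth_sdlog))

  realize <- function(mu, z, sp, depths = NULL) {
    L <- mu + z
    if (sp == "taxa") {
      if (ncol(L) == 0 || nrow(L) == 0)
        return(matrix(0L, nrow(L), ncol(L), dimnames = dimnames(L)))
      counts <- t(vapply(seq_len(nrow(L)), function(i) {
        p <- exp(L[i, ] - max(L[i, ])); p <- p / sum(p)
        as.integer(rmultinom(1L, depths[i], p))
      }, integer(ncol(L))))
      dimnames(counts) <- dimnames(L)
      counts
    } else if (sp == "clinical") L else exp(L)
  }
  taxa_m <- realize(mu$taxa, z$taxa, "taxa", depths)
  module_m <- realize(mu$module, z$module, "module")
  immune_m <- realize(mu$immune, z$immune, "immune")
  clinical_m <- realize(mu$clinical, z$clinical, "clinical")
  dimnames(taxa_m) <- list(md$sample_id, ids$taxa)
  dimnames(module_m) <- list(md$sample_id, ids$module)
  dimnames(immune_m) <- list(md$sample_id, ids$immune)
  dimnames(clinical_m) <- list(md$sample_id, ids$clinical)

  truth <- list(differential_features = truth_diff,
                confounded_features = confounded,
                planted_triplets = list(),
                responder_labels = resp_labels,
                informative_predictors = informative)

  new("SyntheticCohort",
      metadata = md,
      taxa = featureTable(taxa_m, "taxa16S", "counts"),
      modules = featureTable(module_m, "functionalModule", "relative"),
      immune = featureTable(immune_m, "immune", "absolute"),
      clinical = featureTable(clinical_m, "clinical", "absolute"),
      medication = medication,
      truth = truth,
      latent = list(mu = mu, z = z, depths = depths, sigma_tot = sigma_tot,
                    subjects = subjects, subj_of_sample = subj_of_sample),
      design = unclass(design))
}

#' Plant a correlated clinical-immune-microbiome triplet
#'
#' Injects a shared latent factor (with the cohort's within-subject
#' correlation structure) into one clinical, one immune and one microbiome
#' (taxon or module) feature so that each pairwise pooled Spearman
#' correlation approaches `rho_target`. For negative targets the three
#' features load on two factors at 120 degrees: three mutual correlations
#' below -0.5 are impossible for a valid correlation matrix, so the planted
#' magnitude is capped at 0.5 while the sign is always honored.
#'
#' @param cohort a [SyntheticCohort-class] from [simulateCohort()].
#' @param rho_target target pairwise Spearman correlation in [-1, 1].
#' @param ids named character vector with elements `clinical`, `immune` and
#'   `microbiome` giving one feature id per space.
#' @param seed integer seed for the factor draw and count re-realization.
#' @return The modified cohort; `cohortTruth(cohort)$planted_triplets` gains
#'   one record.
#' @export
plantTriplet <- function(cohort, rho_target, ids, seed = 1L) {
  stopifnot(is(cohort, "SyntheticCohort"), abs(rho_target) <= 1,
            all(c("clinical", "immune", "microbiome") %in% names(ids)))
  lat <- cohort@latent
  md <- cohort@metadata
  loc <- list(clinical = match(ids[["clinical"]], featureIds(cohort@clinical)),
              immune = match(ids[["immune"]], featureIds(cohort@immune)))
  mic_space <- if (ids[["microbiome"]] %in% featureIds(cohort@taxa)) "taxa"
               else if (ids[["microbiome"]] %in% featureIds(cohort@modules)) "module"
               else NA
  if (is.na(mic_space)) stop("microbiome member '", ids[["microbiome"]],
                             "' not found among taxa or modules")
  loc$microbiome <- match(ids[["microbiome"]],
                          if (mic_space == "taxa") featureIds(cohort@taxa)
                          else featureIds(cohort@modules))
  if (anyNA(unlist(loc))) stop("feature id not found in its declared space")

  rec <- list(clinical = ids[["clinical"]], immune = ids[["immune"]],
              microbiome = ids[["microbiome"]], rho_target = rho_target)
  cohort@truth$planted_triplets <- c(cohort@truth$planted_triplets, list(rec))
  if (rho_target == 0) return(cohort)   # bookkeeping only

  rho_p <- 2 * sin(pi * rho_target / 6)   # Spearman -> Pearson (Gaussian copula)
  sigma <- lat$sigma_tot
  w <- cohort@design$within_subject_corr
  ns <- length(lat$subjects)
  nsamp <- nrow(md)

  cohort <- with_local_seed(seed + 7L * nsamp, {
    gfac <- function() {
      gs <- rnorm(ns, 0, sqrt(w))
      gs[lat$subj_of_sample] + rnorm(nsamp, 0, sqrt(1 - w))
    }
    spaces3 <- c(clinical = "clinical", immune = "immune", microbiome = mic_space)
    # deterministic latent-mean variation (planted shifts) dilutes the
    # observed correlation; inflate the factor loading to compensate
    mu_var <- vapply(seq_along(spaces3), function(k) {
      sp <- spaces3[k]; j <- loc[[names(spaces3)[k]]]
      var(lat$mu[[sp]][, j]) / sigma^2
    }, numeric(1))
    # per-feature loading: cor(a,b) = lam_a lam_b / sqrt((1+v_a)(1+v_b)),
    # so lam_k = sqrt(rho (1+v_k)) (capped at 1) hits the target pairwise
    lams <- pmin(1, sqrt(abs(rho_p) * (1 + mu_var)))
    if (rho_p > 0) {
      g <- gfac()
      load <- function(k) lams[k] * g
    } else {
      g1 <- gfac(); g2 <- gfac()
      pair <- min(abs(rho_p), 0.5)                  # PSD cap on mutual negatives
      lams <- pmin(1, sqrt(2 * pair * (1 + mu_var)))
      u <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2))
      load <- function(k) lams[k] * (u[k, 1] * g1 + u[k, 2] * g2)
    }
    for (k in seq_along(spaces3)) {
      sp <- spaces3[k]; j <- loc[[names(spaces3)[k]]]
      zj <- lat$z[[sp]][, j]
      lat$z[[sp]][, j] <- sigma * load(k) + sqrt(max(0, 1 - lams[k]^2)) * zj
    }
    cohort@latent <- lat
    # re-realize affected tables
    for (k in seq_along(spaces3)) {
      sp <- spaces3[k]; j <- loc[[names(spaces3)[k]]]
      L <- lat$mu[[sp]] + lat$z[[sp]]
      if (sp == "taxa") {
        counts <- t(vapply(seq_len(nsamp), function(i) {
          p <- exp(L[i, ] - max(L[i, ])); p <- p / sum(p)
          as.integer(rmultinom(1L, lat$depths[i], p))
        }, integer(ncol(L))))
        dimnames(counts) <- dimnames(L)
        cohort@taxa <- featureTable(counts, cohort@taxa@space, "counts")
      } else if (sp == "module") {
        cohort@modules@values[, j] <- exp(L[, j])
      } else if (sp == "immune") {
        cohort@immune@values[, j] <- exp(L[, j])
      } else {
        cohort@clinical@values[, j] <- L[, j]
      }
    }
    cohort
  })
  cohort
}
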