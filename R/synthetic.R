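#' Boar station group sizes
#'
#' The per-station breed composition of the surveyed commercial boar
#' populations: two stations (A1, A2) run by company A and one (B1) by
#' company B, each housing Duroc, Landrace and Large White boars in highly
#' imbalanced numbers. These counts are the default cohort design of
#' [cohortDesign()].
#'
#' @return data.frame with columns company, farm, breed, n
#' @examples
#' sum(boarStationGroups()$n)  # total cohort size
#' @export
boarStationGroups <- function() {
  data.frame(
    company = rep(c("A", "A", "B"), each = 3),
    farm    = rep(c("A1", "A2", "B1"), each = 3),
    breed   = rep(c("Duroc", "Landrace", "LargeWhite"), times = 3),
    n       = c(34L, 113L, 338L, 8L, 108L, 301L, 498L, 166L, 85L),
    stringsAsFactors = FALSE)
}

#' Cohort design for the synthetic generator
#'
#' Describes the sampling frame of a simulated cohort: breed-by-farm group
#' sizes, the age span in days, and the number of rearing batches per farm.
#' Defaults reproduce the surveyed station structure (nine groups, 1,651
#' boars, ages 257-1,906 days, batches as within-farm nuisance levels).
#'
#' @param groups data.frame with columns company, farm, breed, n; each
#'   (farm, breed) pair must be unique and every n >= 1.
#' @param age_range integer pair, admissible ages in days (within 1..4000).
#' @param n_batches batches per farm; batch labels are farm-qualified
#'   (e.g. "A1_b2"), i.e. batch is nested within farm.
#' @param seed integer seed driving every random draw of the cohort.
#' @return object of class `cohortDesign`
#' @export
cohortDesign <- function(groups = boarStationGroups(),
                         age_range = c(257L, 1906L),
                         n_batches = 4L, seed = 1L) {
  stopifnot(is.data.frame(groups),
            all(c("company", "farm", "breed", "n") %in% colnames(groups)))
  if (any(groups$n < 1)) stop("all group sizes must be >= 1")
  if (anyDuplicated(groups[, c("farm", "breed")]))
    stop("duplicated (farm, breed) pair in design")
  age_range <- as.integer(age_range)
  if (length(age_range) != 2L || age_range[1] > age_range[2] ||
      age_range[1] < 1L || age_range[2] > 4000L)
    stop("age_range must be an increasing pair within [1, 4000] days")
  if (n_batches < 1) stop("n_batches must be >= 1")
  structure(list(groups = groups, age_range = age_range,
                 n_batches = as.integer(n_batches),
                 seed = as.integer(seed)),
            class = "cohortDesign")
}

.emptyEffects <- function() {
  data.frame(taxon = integer(), level = character(), shift = numeric(),
             stringsAsFactors = FALSE)
}

.checkEffects <- function(eff, what, n_taxa) {
  if (is.null(eff) || !nrow(eff)) return(.emptyEffects())
  stopifnot(all(c("taxon", "level", "shift") %in% colnames(eff)))
  bad <- eff$taxon < 1 | eff$taxon > n_taxa
  if (any(bad))
    stop(sprintf("%s references taxa outside 1..%d: %s", what, n_taxa,
                 paste(eff$taxon[bad], collapse = ", ")))
  eff[, c("taxon", "level", "shift")]
}

#' Effect model for the synthetic generator
#'
#' Log-normal additive model of community composition: per-taxon baseline
#' log intensities plus sparse additive log-scale shifts attached to breed,
#' farm, age-stage and batch levels, plus Gaussian noise. Samples are
#' closed to the TPM total after exponentiation, so planted shifts act on
#' relative abundance. An additive log-scale model is used (rather than a
#' Dirichlet-multinomial) because the downstream enrichment models are
#' linear on log relative abundance.
#'
#' Baseline intensities, when not supplied, are drawn at simulation time:
#' taxa are assigned to synthetic phyla with two dominant ones
#' (Firmicutes-like and Bacteroidota-like) receiving higher baselines, so
#' generated communities show the two-phylum dominance typical of the pig
#' hindgut.
#'
#' @param n_taxa number of species (>= 2)
#' @param base_logmean optional numeric vector of per-taxon baseline log
#'   intensities (length n_taxa); default drawn at simulation time.
#' @param breed_effects,farm_effects,stage_effects,batch_effects data.frames
#'   (taxon, level, shift) of planted log-scale shifts; batch levels are
#'   farm-qualified ("A1_b1"); stage levels are "young"/"mid"/"aged".
#' @param dispersion sd of the per-(sample, taxon) Gaussian log-scale noise
#' @param depth_factor scales reads-per-base so presence gating at 1x
#'   effective coverage is exercised on both sides of the threshold
#' @param coverage_jitter_sd sdlog of the per-sample lognormal depth jitter
#' @return object of class `effectModel`
#' @export
effectModel <- function(n_taxa = 300L, base_logmean = NULL,
                        breed_effects = NULL, farm_effects = NULL,
                        stage_effects = NULL, batch_effects = NULL,
                        dispersion = 1, depth_factor = 3,
                        coverage_jitter_sd = 0.3) {
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (!is.null(base_logmean) && length(base_logmean) != n_taxa)
    stop("base_logmean must have length n_taxa")
  structure(list(
    n_taxa = n_taxa, base_logmean = base_logmean,
    breed_effects = .checkEffects(breed_effects, "breed_effects", n_taxa),
    farm_effects  = .checkEffects(farm_effects, "farm_effects", n_taxa),
    stage_effects = .checkEffects(stage_effects, "stage_effects", n_taxa),
    batch_effects = .checkEffects(batch_effects, "batch_effects", n_taxa),
    dispersion = dispersion, depth_factor = depth_factor,
    coverage_jitter_sd = coverage_jitter_sd), class = "effectModel")
}

#' Assign boar age stage
#'
#' Maps age in days to the three developmental strata used throughout the
#' analyses: young (<= 12 months), mid (12-36 months) and aged
#' (> 36 months), with year boundaries taken as whole days (12 months =
#' 365 d, 36 months = 1095 d).
#'
#' @param age_days integer vector of ages, all >= 1
#' @return factor with levels young, mid, aged
#' @examples
#' assignAgeStage(c(257, 365, 366, 1095, 1096, 1906))
#' @export
assignAgeStage <- function(age_days) {
  if (any(age_days < 1)) stop("age_days must be positive")
  factor(ifelse(age_days <= 365, "young",
                ifelse(age_days <= 1095, "mid", "aged")),
         levels = c("young", "mid", "aged"))
}

.effectLookup <- function(eff, n_taxa, levels) {
  E <- matrix(0, n_taxa, length(levels), dimnames = list(NULL, levels))
  if (nrow(eff)) {
    bad <- !(eff$level %in% levels)
    if (any(bad))
      stop(sprintf("effect references unknown level(s): %s (taxa %s)",
                   paste(unique(eff$level[bad]), collapse = ", "),
                   paste(eff$taxon[bad], collapse = ", ")))
    E[cbind(eff$taxon, match(eff$level, levels))] <- eff$shift
  }
  E
}

.syntheticTaxonomy <- function(n_taxa) {
  # two dominant phyla plus a minor tail; lineages are synthetic 7-rank strings
  phyla <- c("Firmicutes", "Bacteroidota", "Proteobacteria",
             "Actinobacteriota", "Spirochaetota", "Verrucomicrobiota")
  probs <- c(0.45, 0.30, 0.08, 0.07, 0.06, 0.04)
  idx <- sample.int(length(phyla), n_taxa, replace = TRUE, prob = probs)
  list(phylum = phyla[idx],
       lineage = sprintf(
         "d__Bacteria;p__%s;c__C%02d;o__O%02d;f__F%03d;g__G%03d;s__S%04d",
         phyla[idx], idx, idx, seq_len(n_taxa) %% 97, seq_len(n_taxa) %% 211,
         seq_len(n_taxa)))
}

.truthFromEffects <- function(model, taxon_ids) {
  parts <- Map(function(eff, fac) {
    if (!nrow(eff)) return(NULL)
    data.frame(taxon = taxon_ids[eff$taxon], factor = fac,
               level = eff$level, sign = ifelse(eff$shift >= 0, 1L, -1L),
               stringsAsFactors = FALSE)
  }, list(model$breed_effects, model$farm_effects, model$stage_effects,
          model$batch_effects),
     c("breed", "farm", "age_stage", "batch"))
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(taxon = character(), factor = character(),
                      level = character(), sign = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a boar gut metagenome cohort
#'
#' Draws a full synthetic cohort under `design` and `model`: per sample,
#' log-scale taxon intensities are baseline + breed + farm + age-stage +
#' batch shifts + Gaussian noise, exponentiated and closed to the TPM total
#' of 1e6; reads-per-base coverage is proportional to relative abundance
#' times a depth factor with per-sample lognormal jitter. The same
#' (design, model) with the same seed reproduces the cohort bit for bit.
#'
#' @param design a [cohortDesign()]
#' @param model an [effectModel()]
#' @return a [CohortExperiment-class] carrying the planted-truth table
#' @examples
#' des <- cohortDesign(data.frame(company = "A", farm = "A1",
#'                                breed = c("Duroc", "Landrace"),
#'                                n = c(5, 5)), seed = 7)
#' sc <- simulateCohort(des, effectModel(n_taxa = 20))
#' range(colSums(SummarizedExperiment::assay(sc, "tpm")))
#' @export
simulateCohort <- function(design, model) {
  stopifnot(inherits(design, "cohortDesign"), inherits(model, "effectModel"))
  g <- design$groups
  n_total <- sum(g$n)
  n_taxa <- model$n_taxa
  set.seed(design$seed)

  breed <- rep(g$breed, g$n)
  farm <- rep(g$farm, g$n)
  company <- rep(g$company, g$n)
  sample_id <- sprintf("S%05d", seq_len(n_total))
  age_days <- sample(seq(design$age_range[1], design$age_range[2]),
                     n_total, replace = TRUE)
  batch_levels <- as.vector(t(outer(unique(g$farm),
                                    sprintf("b%d", seq_len(design$n_batches)),
                                    paste, sep = "_")))
  batch <- paste(farm, sprintf("b%d", sample.int(design$n_batches, n_total,
                                                 replace = TRUE)), sep = "_")
  stage <- assignAgeStage(age_days)

  tax <- .syntheticTaxonomy(n_taxa)
  base <- model$base_logmean
  if (is.null(base)) {
    phylum_shift <- c(Firmicutes = 2.0, Bacteroidota = 1.5)[tax$phylum]
    phylum_shift[is.na(phylum_shift)] <- 0
    base <- stats::rnorm(n_taxa, 0, 1.5) + phylum_shift
  }

  Ebreed <- .effectLookup(model$breed_effects, n_taxa, unique(g$breed))
  Efarm  <- .effectLookup(model$farm_effects, n_taxa, unique(g$farm))
  Estage <- .effectLookup(model$stage_effects, n_taxa,
                          c("young", "mid", "aged"))
  Ebatch <- .effectLookup(model$batch_effects, n_taxa, batch_levels)

  # deterministic per-sample sub-streams derived from the cohort stream
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

  ab <- matrix(0, n_total, n_taxa,
               dimnames = list(sample_id, sprintf("t%04d", seq_len(n_taxa))))
  cov <- ab
  for (i in seq_len(n_total)) {
    set.seed(sub_seeds[i])
    mu <- base + Ebreed[, breed[i]] + Efarm[, farm[i]] +
      Estage[, as.character(stage[i])] + Ebatch[, batch[i]]
    x <- exp(mu + stats::rnorm(n_taxa, 0, model$dispersion))
    rel <- x / sum(x)
    ab[i, ] <- rel * 1e6
    jit <- stats::rlnorm(1, 0, model$coverage_jitter_sd)
    cov[i, ] <- model$depth_factor * rel * jit
  }

  meta <- data.frame(sample_id = sample_id, breed = breed, farm = farm,
                     company = company, batch = batch, age_days = age_days,
                     stringsAsFactors = FALSE, row.names = sample_id)
  CohortExperiment(tpm = ab, coverage = cov, sample_data = meta,
                   taxonomy = tax$lineage,
                   truth = .truthFromEffects(model, colnames(ab)))
}

#' Write a cohort to tab-separated files
#'
#' Emits `abundance.tsv`, `coverage.tsv`, `metadata.tsv` and `truth.tsv`
#' into `dir`. Matrices are written samples-in-rows with a leading
#' `sample_id` column; the files round-trip losslessly through
#' [readCohort()].
#'
#' @param cohort a [CohortExperiment-class]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "CohortExperiment"))
  validObject(cohort)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .writeMatrixTSV(tpm(cohort), file.path(dir, "abundance.tsv"))
  .writeMatrixTSV(coverage(cohort), file.path(dir, "coverage.tsv"))
  md <- sampleData(cohort)
  md$age_stage <- NULL  # derived column, recomputed on read
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- plantedTruth(cohort)
  if (is.null(tr))
    tr <- data.frame(taxon = character(), factor = character(),
                     level = character(), sign = integer())
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("abundance.tsv", "coverage.tsv",
                             "metadata.tsv", "truth.tsv")))
}

.writeMatrixTSV <- function(m, path) {
  df <- data.frame(sample_id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readMatrixTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a cohort from tab-separated files
#'
#' Counterpart of [writeCohort()]: loads abundance, coverage and metadata
#' (plus truth.tsv when present) and rebuilds the
#' [CohortExperiment-class], re-deriving the age stage from age in days.
#'
#' @param dir directory holding abundance.tsv, coverage.tsv, metadata.tsv
#' @param read_length average read length in bp
#' @return a [CohortExperiment-class]
#' @export
readCohort <- function(dir, read_length = 151L) {
  ab <- .readMatrixTSV(file.path(dir, "abundance.tsv"))
  cov <- .readMatrixTSV(file.path(dir, "coverage.tsv"))
  md <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  tr <- if (file.exists(truth_path))
    utils::read.table(truth_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = c("character", "character", "character",
                                     "integer")) else NULL
  CohortExperiment(tpm = ab, coverage = cov, sample_data = md, truth = tr,
                   read_length = read_length)
}
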