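#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' CohortExperiment: a metagenomic boar cohort
#'
#' Container for one cohort of shotgun-metagenome profiles: a TPM-scale
#' species abundance matrix, the matching per-(sample, taxon) reads-per-base
#' coverage statistics used for presence gating, and per-sample metadata
#' (breed, farm, company, batch, age). Extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with taxa as rows and
#' samples as columns; assays are \code{"tpm"} and \code{"coverage"}.
#'
#' Required \code{colData} columns: \code{breed}, \code{farm},
#' \code{company}, \code{batch}, \code{age_days}, \code{age_stage}.
#' \code{metadata()} carries \code{read_length} (bp, default 151) and,
#' for simulated cohorts, \code{truth} — the planted-effect table.
#'
#' @seealso [simulateCohort()], [readCohort()], [tpm()], [coverage()]
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

.REQUIRED_METADATA_COLS <- c("breed", "farm", "company", "batch",
                             "age_days", "age_stage")

setValidity("CohortExperiment", function(object) {
  msgs <- character()
  an <- assayNames(object)
  if (!all(c("tpm", "coverage") %in% an))
    return("assays must include 'tpm' and 'coverage'")
  tp <- assay(object, "tpm")
  cv <- assay(object, "coverage")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msgs <- c(msgs, "taxa and samples must be named")
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicated taxon ids")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicated sample ids")
  if (any(tp < 0)) msgs <- c(msgs, "negative TPM values")
  if (any(cv < 0)) msgs <- c(msgs, "negative reads-per-base values")
  cs <- colSums(tp)
  if (any(abs(cs - 1e6) > 1e-4 * 1e6))
    msgs <- c(msgs, "per-sample TPM totals must equal 1e6 within 1e-4 relative")
  miss <- setdiff(.REQUIRED_METADATA_COLS, colnames(colData(object)))
  if (length(miss))
    msgs <- c(msgs, paste0("missing metadata columns: ",
                           paste(miss, collapse = ", ")))
  if (!length(miss)) {
    age <- colData(object)$age_days
    if (any(age < 1)) msgs <- c(msgs, "age_days must be >= 1")
    stage <- as.character(colData(object)$age_stage)
    if (!identical(stage, as.character(assignAgeStage(age))))
      msgs <- c(msgs, "age_stage inconsistent with age_days")
  }
  rl <- metadata(object)$read_length
  if (!is.null(rl) && (!is.numeric(rl) || rl <= 0))
    msgs <- c(msgs, "read_length must be a positive number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CohortExperiment
#'
#' @param tpm numeric sample-by-taxon matrix on the TPM scale (rows are
#'   samples, matching the on-disk layout); stored transposed internally.
#' @param coverage numeric sample-by-taxon matrix of reads-per-base values,
#'   same dimnames as `tpm`.
#' @param sample_data data.frame with one row per sample (rownames or a
#'   `sample_id` column) holding breed, farm, company, batch, age_days;
#'   `age_stage` is derived if absent.
#' @param taxonomy optional character vector of semicolon-delimited 7-rank
#'   lineage strings, one per taxon.
#' @param truth optional planted-effect table (columns taxon, factor,
#'   level, sign) for simulated cohorts.
#' @param read_length average read length in bp used for effective coverage.
#' @return a [CohortExperiment-class] object.
#' @export
CohortExperiment <- function(tpm, coverage, sample_data, taxonomy = NULL,
                             truth = NULL, read_length = 151L) {
  tpm <- as.matrix(tpm); coverage <- as.matrix(coverage)
  if (!identical(dim(tpm), dim(coverage)))
    stop("tpm and coverage must have identical dimensions")
  if (!identical(rownames(tpm), rownames(coverage)) ||
      !identical(colnames(tpm), colnames(coverage)))
    stop("tpm and coverage dimnames disagree")
  if (!is.null(sample_data$sample_id)) {
    rownames(sample_data) <- sample_data$sample_id
    sample_data$sample_id <- NULL
  }
  if (!setequal(rownames(sample_data), rownames(tpm)))
    stop("sample ids differ between abundance table and metadata")
  sample_data <- sample_data[rownames(tpm), , drop = FALSE]
  if (is.null(sample_data$age_stage))
    sample_data$age_stage <- assignAgeStage(sample_data$age_days)
  rd <- if (is.null(taxonomy)) NULL else {
    if (length(taxonomy) != ncol(tpm))
      stop("taxonomy must have one lineage per taxon")
    DataFrame(lineage = taxonomy, row.names = colnames(tpm))
  }
  se <- SummarizedExperiment(
    assays = list(tpm = t(tpm), coverage = t(coverage)),
    colData = DataFrame(sample_data),
    rowData = rd)
  metadata(se)$read_length <- as.integer(read_length)
  metadata(se)$truth <- truth
  new("CohortExperiment", se)
}

#' @describeIn CohortExperiment compact summary of the cohort design
#' @param object a CohortExperiment
#' @export
setMethod("show", "CohortExperiment", function(object) {
  cat(sprintf("CohortExperiment: %d taxa x %d samples\n",
              nrow(object), ncol(object)))
  cd <- colData(object)
  tab <- table(breed = cd$breed, farm = cd$farm)
  cat("samples per breed x farm:\n")
  print(tab)
  cat(sprintf("age range: %d-%d days; stages: %s\n",
              min(cd$age_days), max(cd$age_days),
              paste(sprintf("%s=%d", names(table(cd$age_stage)),
                            as.integer(table(cd$age_stage))),
                    collapse = ", ")))
  tr <- metadata(object)$truth
  if (!is.null(tr) && nrow(tr))
    cat(sprintf("planted effects: %d records\n", nrow(tr)))
  invisible(NULL)
})
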