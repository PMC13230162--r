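#' Abundance matrix accessor
#'
#' Returns the TPM-scale abundance matrix with samples as rows and taxa as
#' columns — the orientation every analysis function in the package takes,
#' matching the on-disk tables (internally the assay is stored taxa x
#' samples per SummarizedExperiment convention).
#'
#' @param x a [CohortExperiment-class]
#' @return numeric sample-by-taxon matrix
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))

#' @rdname tpm
#' @export
setMethod("tpm", "CohortExperiment", function(x) t(assay(x, "tpm")))

#' Coverage matrix accessor
#'
#' Per-(sample, taxon) reads-per-base values, samples as rows.
#'
#' @param x a [CohortExperiment-class]
#' @return numeric sample-by-taxon matrix of reads-per-base
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname coverage
#' @export
setMethod("coverage", "CohortExperiment", function(x) t(assay(x, "coverage")))

#' Sample metadata accessor
#'
#' @param x a [CohortExperiment-class]
#' @return data.frame with sample_id, breed, farm, company, batch,
#'   age_days, age_stage
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "CohortExperiment", function(x) {
  df <- as.data.frame(colData(x))
  data.frame(sample_id = rownames(df), df, row.names = rownames(df),
             stringsAsFactors = FALSE)
})

#' Taxonomy accessor
#'
#' @param x a [CohortExperiment-class]
#' @return named character vector of 7-rank lineage strings, or NULL
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname taxonomy
#' @export
setMethod("taxonomy", "CohortExperiment", function(x) {
  rd <- rowData(x)
  if ("lineage" %in% colnames(rd))
    stats::setNames(as.character(rd$lineage), rownames(x)) else NULL
})

#' Planted-truth accessor
#'
#' For simulated cohorts, the table of effects planted by the generator
#' (columns taxon, factor, level, sign); NULL for cohorts read from data
#' lacking a truth table.
#'
#' @param x a [CohortExperiment-class]
#' @return data.frame or NULL
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' @rdname plantedTruth
#' @export
setMethod("plantedTruth", "CohortExperiment", function(x) metadata(x)$truth)

#' Read length accessor
#'
#' @param x a [CohortExperiment-class]
#' @return integer average read length in bp (default 151)
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname readLength
#' @export
setMethod("readLength", "CohortExperiment", function(x) {
  rl <- metadata(x)$read_length
  if (is.null(rl)) 151L else as.integer(rl)
})

#' Coverage-gate a cohort
#'
#' Applies the presence rule of the profiling pipeline: a species is kept in
#' a sample only when its effective genome coverage (reads-per-base times
#' read length) strictly exceeds `threshold` (1x by default). Abundances of
#' absent species are zeroed and each sample is re-normalised to the TPM
#' total of 1e6.
#'
#' @param x a [CohortExperiment-class]
#' @param threshold effective-coverage cutoff; strict `>` comparison
#' @return a [CohortExperiment-class] with gated, renormalised tpm
#' @export
setGeneric("gateByCoverage", function(x, threshold = 1)
  standardGeneric("gateByCoverage"))

#' @rdname gateByCoverage
#' @export
setMethod("gateByCoverage", "CohortExperiment", function(x, threshold = 1) {
  pres <- presenceByCoverage(coverage(x), read_length = readLength(x),
                             threshold = threshold)
  ab <- tpm(x)
  ab[!pres] <- 0
  ab <- normalizeTPM(ab)
  out <- x
  SummarizedExperiment::assay(out, "tpm") <- t(ab)
  validObject(out)
  out
})
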