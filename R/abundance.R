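#' Normalise a sample-by-taxon matrix to the TPM scale
#'
#' Scales each sample (row) so its values sum to 1e6. Zero entries stay
#' zero; the operation is idempotent and invariant to positive per-row
#' rescaling of the input.
#'
#' @param x nonnegative numeric matrix, samples in rows
#' @return matrix of the same shape on the TPM scale
#' @examples
#' normalizeTPM(rbind(s1 = c(1, 1, 2)))
#' @export
normalizeTPM <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("negative abundances")
  rs <- rowSums(x)
  zero <- rs == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(if (is.null(rownames(x))) which(zero) else
           rownames(x)[zero], collapse = ", "))
  x / rs * 1e6
}

#' Effective genome coverage
#'
#' Converts reads-per-base values to effective coverage by multiplying by
#' the average read length (151 bp for the profiling pipeline emulated
#' here).
#'
#' @param reads_per_base nonnegative numeric matrix or vector
#' @param read_length average read length in bp
#' @return effective coverage, same shape as the input
#' @examples
#' effectiveCoverage(0.02)          # 3.02
#' effectiveCoverage(1 / 151)       # exactly 1x
#' @export
effectiveCoverage <- function(reads_per_base, read_length = 151L) {
  if (any(reads_per_base < 0)) stop("negative reads-per-base values")
  if (read_length <= 0) stop("read_length must be positive")
  reads_per_base * read_length
}

#' Presence calling by effective coverage
#'
#' A species is called present in a sample only when its effective genome
#' coverage strictly exceeds `threshold` (the 1x rule): coverage of exactly
#' 1.0 is absent.
#'
#' @param reads_per_base sample-by-taxon matrix of reads-per-base
#' @param read_length average read length in bp
#' @param threshold effective-coverage cutoff (strict `>`)
#' @return logical presence matrix of the same shape
#' @export
presenceByCoverage <- function(reads_per_base, read_length = 151L,
                               threshold = 1) {
  effectiveCoverage(reads_per_base, read_length) > threshold
}

#' Presence calling by relative abundance
#'
#' A species is present in a sample when its relative abundance strictly
#' exceeds `threshold` (default 1e-5, i.e. TPM > 10) — the rule used to
#' build presence-absence matrices for the shared-taxa analysis.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param threshold relative-abundance cutoff in (0, 1); strict `>`
#' @return logical presence matrix of the same shape
#' @export
presenceByAbundance <- function(tpm, threshold = 1e-5) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  tpm / 1e6 > threshold
}

#' Prevalence filter
#'
#' Retains taxa present in at least `min_prevalence` of the samples of a
#' group (inclusive `>=`, so exactly 10% passes the default cutoff).
#'
#' @param presence logical sample-by-taxon matrix
#' @param samples optional subset of sample ids (or logical/integer index)
#'   defining the group; default all samples
#' @param min_prevalence required fraction in [0, 1]
#' @return character vector of retained taxon ids
#' @export
prevalenceFilter <- function(presence, samples = NULL,
                             min_prevalence = 0.10) {
  if (min_prevalence < 0 || min_prevalence > 1)
    stop("min_prevalence must lie in [0, 1]")
  if (!is.null(samples)) presence <- presence[samples, , drop = FALSE]
  if (nrow(presence) == 0L) stop("empty sample group")
  prev <- colMeans(presence)
  colnames(presence)[prev >= min_prevalence]
}

#' Abundance filter for enrichment modelling
#'
#' Drops taxa detected (abundance > 0) in fewer than `min_prev` of all
#' samples or with mean relative abundance below `min_mean_relabund`;
#' both boundaries are kept (inclusive `>=`).
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param min_prev minimum detection prevalence over all samples
#' @param min_mean_relabund minimum mean relative abundance
#' @return the filtered tpm matrix (same samples, fewer taxa)
#' @export
enrichmentInputFilter <- function(tpm, min_prev = 0.05,
                                  min_mean_relabund = 1e-5) {
  detected <- tpm > 0
  prev <- colMeans(detected)
  mean_rel <- colMeans(tpm / 1e6)
  keep <- prev >= min_prev & mean_rel >= min_mean_relabund
  if (!any(keep))
    stop(sprintf(
      "no taxa pass the filter (%d fail prevalence %.3g, %d fail mean abundance %.3g)",
      sum(prev < min_prev), min_prev,
      sum(mean_rel < min_mean_relabund), min_mean_relabund))
  tpm[, keep, drop = FALSE]
}
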