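.bootstrapSummary <- function(p, subsample_size, seed, stable_cutoff) {
  p <- as.matrix(p)
  structure(list(
    p_values = p,
    stability_fraction = colMeans(p < 0.05),
    median_p = apply(p, 2, stats::median),
    p_interval = apply(p, 2, stats::quantile, probs = c(0.025, 0.975)),
    subsample_size = subsample_size,
    n_iterations = nrow(p),
    stable_cutoff = stable_cutoff,
    seed = seed), class = "bootstrapSummary")
}

#' @export
print.bootstrapSummary <- function(x, ...) {
  cat(sprintf("bootstrap: %d iterations, %d per group\n",
              x$n_iterations, x$subsample_size))
  for (nm in colnames(x$p_values))
    cat(sprintf("  %-10s stability (p<0.05): %.3f  median p: %.4g  [%.3g, %.3g]%s\n",
                nm, x$stability_fraction[nm], x$median_p[nm],
                x$p_interval[1, nm], x$p_interval[2, nm],
                if (x$stability_fraction[nm] >= x$stable_cutoff)
                  "  (stable)" else ""))
  invisible(x)
}

.drawBalanced <- function(groups, size) {
  idx <- unlist(lapply(split(seq_along(groups), groups), sample, size = size),
                use.names = FALSE)
  stopifnot(all(table(groups[idx]) == size))  # every iteration is balanced
  idx
}

#' Bootstrap robustness of alpha-diversity comparisons
#'
#' Within each stratum (farm), repeatedly subsamples every group (breed)
#' without replacement down to the smallest group's size, recomputes the
#' three alpha-diversity indices on the subsample and runs the omnibus
#' non-parametric test (Kruskal-Wallis for three or more groups, Wilcoxon
#' rank-sum for two). The distribution of per-iteration p-values, and the
#' fraction below 0.05, measure whether a diversity difference survives
#' the group-size imbalance. The declare-stable cutoff on that fraction is
#' a reporting choice (default 0.95), not part of the per-iteration test.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param meta sample metadata aligned with `tpm` rows
#' @param group_by grouping factor column (default breed)
#' @param stratify_by stratum column (default farm); `NULL` treats all
#'   samples as one stratum
#' @param n_iterations resampling iterations (study default 1000)
#' @param stable_cutoff reporting threshold on the stability fraction
#' @param seed integer seed for the whole resampling stream
#' @return named list (one per stratum) of `bootstrapSummary` objects,
#'   each with a p-value matrix of n_iterations x 3 indices
#' @export
bootstrapAlpha <- function(tpm, meta, group_by = "breed",
                           stratify_by = "farm", n_iterations = 1000L,
                           stable_cutoff = 0.95, seed = NULL) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  alpha <- alphaDiversity(tpm)
  strata <- if (is.null(stratify_by)) factor(rep("all", nrow(meta)))
  else droplevels(factor(meta[[stratify_by]]))
  out <- list()
  for (s in levels(strata)) {
    in_s <- which(strata == s)
    g <- droplevels(factor(meta[[group_by]][in_s]))
    if (nlevels(g) < 2L) stop("stratum ", s, " has fewer than 2 groups")
    size <- min(table(g))
    if (size < 2L) stop("smallest group in stratum ", s, " has < 2 samples")
    pmat <- matrix(NA_real_, n_iterations, 3,
                   dimnames = list(NULL, c("richness", "shannon", "simpson")))
    for (b in seq_len(n_iterations)) {
      idx <- in_s[.drawBalanced(g, size)]
      gg <- g[match(idx, in_s)]
      for (ind in colnames(pmat)) {
        v <- alpha[[ind]][idx]
        pmat[b, ind] <- if (nlevels(g) >= 3L) .kruskalP(v, gg)
        else .rankSumP(v[gg == levels(gg)[1]], v[gg == levels(gg)[2]])
      }
    }
    out[[s]] <- .bootstrapSummary(pmat, size, seed, stable_cutoff)
  }
  out
}

#' Bootstrap robustness of community-composition differences
#'
#' Global resampling across all breed-by-farm groups: every group is
#' subsampled without replacement to the size of the smallest group, a
#' Bray-Curtis matrix is computed on the subsample, and a one-term
#' PERMANOVA on the grouping factor (breed) with `inner_permutations`
#' permutations yields one p-value per iteration.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param meta sample metadata aligned with `tpm` rows
#' @param group_by factor tested by the inner PERMANOVA (default breed)
#' @param balance_by column(s) whose cross-classification with `group_by`
#'   defines the cells equalised by subsampling (default farm)
#' @param n_iterations resampling iterations (study default 1000)
#' @param inner_permutations permutations of each inner PERMANOVA
#' @param stable_cutoff reporting threshold on the stability fraction
#' @param seed integer seed
#' @return a `bootstrapSummary` with one p-value column ("permanova")
#' @export
bootstrapBeta <- function(tpm, meta, group_by = "breed",
                          balance_by = "farm", n_iterations = 1000L,
                          inner_permutations = 999L, stable_cutoff = 0.95,
                          seed = NULL) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cells <- droplevels(interaction(
    meta[, c(group_by, balance_by), drop = FALSE], drop = TRUE))
  size <- min(table(cells))
  if (size < 2L) stop("smallest group has < 2 samples")
  pvec <- numeric(n_iterations)
  for (b in seq_len(n_iterations)) {
    idx <- .drawBalanced(cells, size)
    d <- brayCurtis(tpm[idx, , drop = FALSE])
    md <- data.frame(g = factor(meta[[group_by]][idx]))
    fml <- d ~ g
    environment(fml) <- environment()
    pvec[b] <- permanova(fml, md, permutations = inner_permutations)["g", "p"]
  }
  .bootstrapSummary(matrix(pvec, ncol = 1,
                           dimnames = list(NULL, "permanova")),
                    size, seed, stable_cutoff)
}
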