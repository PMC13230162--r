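#' Alpha diversity indices
#'
#' Observed richness (taxa with abundance > 0), Shannon index (natural
#' log) and Simpson index (1 - sum p^2) per sample, computed on the
#' relative-abundance matrix. Richness on a coverage-gated table equals
#' the detected-species count.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @return data.frame with sample_id, richness, shannon, simpson
#' @examples
#' alphaDiversity(rbind(u = rep(250000, 4)))  # shannon = log(4)
#' @export
alphaDiversity <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (any(rowSums(tpm) == 0)) stop("empty sample(s)")
  data.frame(
    sample_id = if (is.null(rownames(tpm)))
      as.character(seq_len(nrow(tpm))) else rownames(tpm),
    richness = rowSums(tpm > 0),
    shannon = vegan::diversity(tpm, index = "shannon"),
    simpson = vegan::diversity(tpm, index = "simpson"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over taxa; bounded in
#' [0, 1], zero for identical profiles, one for disjoint supports. Not a
#' metric (the triangle inequality can fail), which is why ordination goes
#' through PCoA rather than a metric embedding.
#'
#' @param tpm sample-by-taxon matrix, rows normalised and nonnegative
#' @return a `dist` object over samples
#' @export
brayCurtis <- function(tpm) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("negative abundances")
  if (any(rowSums(tpm) == 0)) stop("all-zero sample(s): distance undefined")
  vegan::vegdist(tpm, method = "bray")
}

#' Principal coordinates analysis
#'
#' Classical scaling of a dissimilarity matrix: the squared distances are
#' double-centred (Gower), eigendecomposed, and coordinates formed as
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues — expected for Bray-Curtis — are reported but
#' contribute no axes and no correction (Cailliez/Lingoes) is applied;
#' proportions explained are over the positive-eigenvalue sum. Axis signs
#' are fixed so each axis's largest-magnitude loading is positive.
#'
#' @param d a `dist` or symmetric matrix of dissimilarities
#' @param n_axes number of axes requested (>= 2); if fewer positive
#'   eigenvalues exist, fewer axes are returned with `axes_truncated` set
#' @return object of class `pcoaResult`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all, descending),
#'   `proportion_explained` (per returned axis), `negative_eigenvalues`,
#'   `axes_truncated`
#' @export
pcoa <- function(d, n_axes = 2L) {
  if (n_axes < 2L) stop("n_axes must be >= 2")
  m <- as.matrix(d)
  G <- gowerCenter(m)
  e <- eigen(G, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- which(e$values > tol)
  truncated <- length(pos) < n_axes
  if (truncated)
    warning(sprintf("only %d positive eigenvalue(s); returning %d axes",
                    length(pos), length(pos)))
  k <- min(n_axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(rownames(m), sprintf("Axis%d", seq_len(k)))
  structure(list(
    coordinates = coords,
    eigenvalues = e$values,
    proportion_explained = e$values[pos[seq_len(k)]] / sum(e$values[pos]),
    negative_eigenvalues = e$values[e$values < -tol],
    axes_truncated = truncated), class = "pcoaResult")
}

#' @export
print.pcoaResult <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes (%s of positive-eigenvalue variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$proportion_explained),
                    collapse = " + ")))
  if (length(x$negative_eigenvalues))
    cat(sprintf("%d negative eigenvalue(s), min %.3g (no correction applied)\n",
                length(x$negative_eigenvalues), min(x$negative_eigenvalues)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector. Thin,
#' validating wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return vector of BH-adjusted q-values, same order as `p`
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

.rankSumP <- function(x, y) {
  # exact p for small untied samples, normal approximation with tie
  # correction otherwise
  exact <- (length(x) + length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                           correct = TRUE)$p.value)
  if (!is.finite(p)) 1 else p  # fully tied samples carry no evidence
}

.kruskalP <- function(v, g) {
  p <- suppressWarnings(stats::kruskal.test(v, g)$p.value)
  if (!is.finite(p)) 1 else p
}

#' Pairwise alpha-diversity comparisons between groups
#'
#' Two-sided Wilcoxon rank-sum tests for every group pair and every index
#' (richness, Shannon, Simpson), BH-adjusted within each index family;
#' with three or more groups an omnibus Kruskal-Wallis p per index is
#' attached as the `omnibus` attribute (this is the per-iteration test the
#' bootstrap machinery uses).
#'
#' @param alpha data.frame from [alphaDiversity()]
#' @param groups factor (or coercible) aligned with the rows of `alpha`
#' @return data.frame (index, group1, group2, n1, n2, p, q) with attribute
#'   `omnibus`, a named numeric vector of per-index omnibus p-values
#' @export
compareGroupsAlpha <- function(alpha, groups) {
  groups <- droplevels(factor(groups))
  if (length(groups) != nrow(alpha))
    stop("groups must align with the rows of alpha")
  lv <- levels(groups)
  if (length(lv) < 2L) stop("need at least two groups")
  small <- table(groups) < 2
  if (any(small))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(which(small)), collapse = ", "))
  idx <- c("richness", "shannon", "simpson")
  pairs <- utils::combn(lv, 2)
  rows <- list()
  omnibus <- numeric(0)
  for (ind in idx) {
    v <- alpha[[ind]]
    p <- apply(pairs, 2, function(pr)
      .rankSumP(v[groups == pr[1]], v[groups == pr[2]]))
    rows[[ind]] <- data.frame(
      index = ind, group1 = pairs[1, ], group2 = pairs[2, ],
      n1 = as.integer(table(groups)[pairs[1, ]]),
      n2 = as.integer(table(groups)[pairs[2, ]]),
      p = p, q = bhAdjust(p), stringsAsFactors = FALSE)
    omnibus[ind] <- if (length(lv) >= 3L) .kruskalP(v, groups) else p[1]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omnibus") <- omnibus
  out
}
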