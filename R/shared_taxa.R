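#' Build per-group taxon sets
#'
#' For each level of `group_by` (optionally within one stratum, e.g. the
#' breeds within one farm), calls presence by the relative-abundance rule
#' (> `abund_threshold`) and keeps taxa with prevalence >=
#' `min_prevalence` inside that group — the set-construction rule of the
#' shared-taxa analysis. Thresholds used are recorded as attributes.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale (coverage-gated
#'   upstream)
#' @param meta sample metadata aligned with `tpm` rows
#' @param group_by metadata column defining the sets
#' @param within optional named character like `c(farm = "A1")` selecting
#'   one stratum before grouping
#' @param min_prevalence within-group prevalence cutoff (inclusive)
#' @param abund_threshold relative-abundance presence cutoff (strict)
#' @return a `taxonSetFamily`: named list of taxon-id character vectors
#'   with attributes `min_prevalence`, `abund_threshold`, `group_sizes`
#' @export
buildGroupSets <- function(tpm, meta, group_by, within = NULL,
                           min_prevalence = 0.10, abund_threshold = 1e-5) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(within)) {
    for (f in names(within)) keep <- keep & meta[[f]] == within[[f]]
    if (!any(keep))
      stop("empty stratum: ", paste(names(within), within, sep = "=",
                                    collapse = ", "))
  }
  tpm <- tpm[keep, , drop = FALSE]
  g <- droplevels(factor(meta[[group_by]][keep]))
  if (nlevels(g) < 1L) stop("no groups found")
  pres <- presenceByAbundance(tpm, abund_threshold)
  sets <- lapply(levels(g), function(lv)
    prevalenceFilter(pres, samples = which(g == lv),
                     min_prevalence = min_prevalence))
  names(sets) <- levels(g)
  structure(sets, class = "taxonSetFamily",
            min_prevalence = min_prevalence,
            abund_threshold = abund_threshold,
            group_sizes = as.integer(table(g)))
}

#' UpSet-style intersection report
#'
#' Tallies, for every non-empty subset of the groups, the number of taxa
#' belonging to exactly that subset (exclusive intersections — the bars of
#' an UpSet plot). Also reports total set sizes, the shared-by-all count,
#' per-group unique counts, and the inclusive pairwise overlap matrix
#' (|A intersect B|), since "shared between two groups" is sometimes read
#' inclusively.
#'
#' @param family a `taxonSetFamily` (or plain named list of character
#'   vectors), 2 to 20 groups
#' @return an `intersectionReport`: list with `exclusive` (data.frame
#'   groups, degree, count over all 2^k - 1 subsets), `set_sizes`,
#'   `shared_all`, `unique_counts`, `pairwise_inclusive`, `union_size`
#' @export
intersectReport <- function(family) {
  sets <- lapply(family, unique)
  k <- length(sets)
  if (k < 2L) stop("need at least 2 groups")
  if (k > 20L) stop("more than 20 groups: intersection table too large")
  nms <- names(sets)
  univ <- unique(unlist(sets, use.names = FALSE))
  M <- if (length(univ) == 0L) matrix(FALSE, 0, k, dimnames = list(NULL, nms))
  else vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) M <- matrix(M, nrow = 1, dimnames = list(NULL, nms))
  pattern <- as.integer(M %*% 2^(seq_len(k) - 1))
  counts <- tabulate(pattern, nbins = 2^k - 1)
  masks <- seq_len(2^k - 1)
  in_subset <- function(mask) nms[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
  excl <- data.frame(
    groups = vapply(masks, function(m) paste(in_subset(m), collapse = "&"),
                    character(1)),
    degree = vapply(masks, function(m) length(in_subset(m)), integer(1)),
    count = counts, stringsAsFactors = FALSE)
  excl <- excl[order(-excl$degree, -excl$count), ]
  rownames(excl) <- NULL
  stopifnot(sum(excl$count) == length(univ))  # exclusive counts tile the union
  pw <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
    length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pw) <- list(nms, nms)
  structure(list(
    exclusive = excl,
    set_sizes = vapply(sets, length, integer(1)),
    shared_all = counts[2^k - 1],
    unique_counts = stats::setNames(counts[2^(seq_len(k) - 1)], nms),
    pairwise_inclusive = pw,
    union_size = length(univ)), class = "intersectionReport")
}

#' @export
print.intersectionReport <- function(x, ...) {
  k <- length(x$set_sizes)
  cat(sprintf("intersection report: %d groups, union of %d taxa\n",
              k, x$union_size))
  cat("set sizes: ", paste(names(x$set_sizes), x$set_sizes, sep = "=",
                           collapse = ", "), "\n")
  cat(sprintf("shared by all %d groups: %d\n", k, x$shared_all))
  cat("unique:    ", paste(names(x$unique_counts), x$unique_counts,
                           sep = "=", collapse = ", "), "\n")
  top <- utils::head(x$exclusive[x$exclusive$count > 0, ], 10)
  print(top, row.names = FALSE)
  invisible(x)
}
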