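#' Gower double-centring of a distance matrix
#'
#' Forms G = -1/2 J (D o D) J with J the centring projector
#' I - 11'/n. G is the inner-product matrix underlying both PCoA and
#' distance-based variance partitioning: its trace is the total sum of
#' squares of the point configuration and its rows sum to zero.
#'
#' @param d symmetric distance matrix (or `dist`) with zero diagonal
#' @return centred inner-product matrix G
#' @export
gowerCenter <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  A <- -0.5 * m * m
  rm_ <- rowMeans(A)
  A - rm_ - rep(colMeans(A), each = nrow(A)) + mean(A)
}

# hat (projection) matrix of a design, via thin QR of the rank-revealing
# pivoted decomposition
.hatMatrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  list(H = tcrossprod(Q), rank = qx$rank)
}

.termDesigns <- function(terms, data) {
  lapply(terms, function(tm) {
    f <- data[[tm]]
    if (is.null(f)) stop("term not found in metadata: ", tm)
    f <- droplevels(factor(f))
    if (nlevels(f) < 2L)
      stop(sprintf("term '%s' has fewer than 2 observed levels", tm))
    stats::model.matrix(~f)[, -1, drop = FALSE]
  })
}

#' Distance-based multivariate variance partitioning (PERMANOVA)
#'
#' Partitions the variation of a dissimilarity matrix among categorical
#' model terms by projecting the Gower-centred inner-product matrix onto
#' nested dummy-coded design spaces. `mode = "sequential"` conditions each
#' term on the preceding ones (order-dependent; terms + residual sum
#' exactly to the total SS); `mode = "marginal"` conditions each term on
#' all others (SS_term = SS_full - SS_without_term). Pseudo-F uses the
#' full-model residual in both modes, and significance comes from freely
#' permuting sample rows, with p = (1 + #\{F* >= F\}) / (1 + permutations)
#' so p can never be zero.
#'
#' @param formula model formula whose left side evaluates to a `dist` or
#'   symmetric matrix and whose right side lists categorical terms found in
#'   `data`, e.g. `d ~ breed + age_stage + batch`
#' @param data data.frame of sample metadata, rows aligned with `d`
#' @param permutations number of free row permutations (default 999; 0
#'   skips the permutation test and reports NA p-values)
#' @param mode "sequential" (in formula order) or "marginal"
#' @param seed optional integer seed for the permutation stream
#' @return a `permanovaTable`: data.frame with one row per term plus
#'   Residual and Total (columns Df, SumOfSqs, R2, F, p), attributes
#'   `mode`, `permutations`, `seed`, `confounded`
#' @examples
#' md <- data.frame(g = rep(c("a", "b"), each = 4))
#' y <- c(rnorm(4), rnorm(4) + 2)
#' d <- dist(y)
#' permanova(d ~ g, md, permutations = 199, seed = 1)
#' @export
permanova <- function(formula, data, permutations = 999,
                      mode = c("sequential", "marginal"), seed = NULL) {
  mode <- match.arg(mode)
  d <- eval(formula[[2]], envir = environment(formula))
  G <- gowerCenter(d)
  n <- nrow(G)
  if (nrow(data) != n) stop("metadata does not cover all samples in d")
  term_labels <- attr(stats::terms(formula), "term.labels")
  if (!length(term_labels)) stop("formula has no terms")
  if (any(grepl(":", term_labels, fixed = TRUE)))
    stop("interaction terms are not supported")
  designs <- .termDesigns(term_labels, data)
  K <- length(designs)

  ones <- matrix(1, n, 1)
  # cumulative hat matrices H_0 (intercept) .. H_K (full model)
  hats <- vector("list", K + 1L)
  hats[[1]] <- .hatMatrix(ones)
  for (k in seq_len(K))
    hats[[k + 1]] <- .hatMatrix(do.call(cbind, c(list(ones), designs[seq_len(k)])))
  rank_full <- hats[[K + 1]]$rank
  df_resid <- n - rank_full
  if (df_resid < 1L)
    stop("fewer distinct samples than model degrees of freedom + 2")

  df_seq <- vapply(seq_len(K), function(k)
    hats[[k + 1]]$rank - hats[[k]]$rank, integer(1))
  confounded <- df_seq == 0L
  if (any(confounded))
    warning("confounded term(s) with 0 df: ",
            paste(term_labels[confounded], collapse = ", "))

  # hat matrices for "all terms but one" (marginal mode)
  drop_hats <- if (mode == "marginal") lapply(seq_len(K), function(k) {
    .hatMatrix(do.call(cbind, c(list(ones), designs[-k])))
  }) else NULL
  df_marg <- if (mode == "marginal") vapply(seq_len(K), function(k)
    rank_full - drop_hats[[k]]$rank, integer(1)) else NULL

  trHG <- function(H, Gm) sum(H * Gm)
  ssFor <- function(Gm) {
    tr_cum <- vapply(hats, function(h) trHG(h$H, Gm), numeric(1))
    ss_res <- sum(diag(Gm)) - tr_cum[K + 1]
    ss <- if (mode == "sequential") diff(tr_cum)
    else vapply(seq_len(K), function(k)
      tr_cum[K + 1] - trHG(drop_hats[[k]]$H, Gm), numeric(1))
    list(ss = ss, res = ss_res)
  }

  obs <- ssFor(G)
  ss_total <- sum(diag(G))
  dfs <- if (mode == "sequential") df_seq else df_marg
  f_obs <- (obs$ss / pmax(dfs, 1L)) / (obs$res / df_resid)
  f_obs[dfs == 0L] <- NA_real_

  p <- rep(NA_real_, K)
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    counts <- numeric(K)
    # tolerance so permutations that tie the observed statistic exactly
    # (e.g. relabelings of the same partition) count as >= despite
    # floating-point noise
    eps <- 1e-8 * (1 + abs(f_obs))
    for (b in seq_len(permutations)) {
      prm <- sample.int(n)
      Gp <- G[prm, prm]
      pb <- ssFor(Gp)
      fp <- (pb$ss / pmax(dfs, 1L)) / (pb$res / df_resid)
      counts <- counts + as.numeric(fp >= f_obs - eps)
    }
    p <- (1 + counts) / (1 + permutations)
    p[dfs == 0L] <- NA_real_
  }

  out <- data.frame(
    Df = c(dfs, df_resid, n - 1L),
    SumOfSqs = c(obs$ss, obs$res, ss_total),
    R2 = c(obs$ss, obs$res, ss_total) / ss_total,
    F = c(f_obs, NA, NA),
    p = c(p, NA, NA),
    row.names = c(term_labels, "Residual", "Total"))
  attr(out, "mode") <- mode
  attr(out, "permutations") <- permutations
  attr(out, "seed") <- seed
  attr(out, "confounded") <- stats::setNames(confounded, term_labels)
  class(out) <- c("permanovaTable", "data.frame")
  out
}

#' @export
print.permanovaTable <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s SS, %d permutations)\n",
              attr(x, "mode"), attr(x, "permutations")))
  df <- as.data.frame(x)
  df$SumOfSqs <- signif(df$SumOfSqs, 6)
  df$R2 <- signif(df$R2, 4)
  df$F <- signif(df$F, 4)
  print(df)
  invisible(x)
}

#' Stratified variance partitioning with small-group exclusion
#'
#' Fits a PERMANOVA within each stratum (e.g. each farm, or each age
#' stage), first excluding samples belonging to levels of any modelled
#' factor observed fewer than `min_group_size` times within the stratum —
#' the rule under which a breed group of n = 8 is dropped at the default
#' minimum of 10. Strata whose remaining design is degenerate (fewer than
#' two levels of the primary term, or too few samples) are skipped with a
#' recorded reason. Dissimilarities are computed within each stratum after
#' exclusion.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param meta data.frame of sample metadata aligned with `tpm` rows
#' @param stratify_by metadata column defining strata
#' @param terms character vector of model terms, first = primary factor
#' @param min_group_size smallest admissible factor-level size (default 10)
#' @param permutations,mode,seed passed to [permanova()]; per-stratum
#'   permutation seeds are derived deterministically from `seed`
#' @return list with `results` (named list of `permanovaTable`),
#'   `skipped` (data.frame stratum, reason) and `dropped`
#'   (data.frame stratum, term, level, n of excluded levels)
#' @export
permanovaByStratum <- function(tpm, meta, stratify_by, terms,
                               min_group_size = 10L, permutations = 999,
                               mode = "sequential", seed = NULL) {
  strata <- droplevels(factor(meta[[stratify_by]]))
  if (is.null(meta[[stratify_by]])) stop("unknown stratify_by column")
  lv <- levels(strata)
  if (!is.null(seed)) set.seed(seed)
  stratum_seeds <- sample.int(.Machine$integer.max - 1L, length(lv))
  results <- list()
  skipped <- dropped <- NULL
  for (i in seq_along(lv)) {
    s <- lv[i]
    keep <- which(strata == s)
    # iteratively drop samples in under-sized levels of any modelled term
    repeat {
      changed <- FALSE
      for (tm in terms) {
        tab <- table(meta[[tm]][keep])
        small <- names(tab)[tab > 0 & tab < min_group_size]
        if (length(small)) {
          for (lvl in small)
            dropped <- rbind(dropped, data.frame(
              stratum = s, term = tm, level = lvl,
              n = as.integer(tab[lvl]), stringsAsFactors = FALSE))
          keep <- keep[!(meta[[tm]][keep] %in% small)]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    primary <- droplevels(factor(meta[[terms[1]]][keep]))
    if (nlevels(primary) < 2L) {
      skipped <- rbind(skipped, data.frame(
        stratum = s, reason = "fewer than 2 levels of the primary term",
        stringsAsFactors = FALSE))
      next
    }
    sub_meta <- droplevels(meta[keep, , drop = FALSE])
    use_terms <- terms[vapply(terms, function(tm)
      nlevels(droplevels(factor(sub_meta[[tm]]))) >= 2L, logical(1))]
    model_df <- sum(vapply(use_terms, function(tm)
      nlevels(droplevels(factor(sub_meta[[tm]]))) - 1L, integer(1)))
    if (length(keep) < model_df + 2L) {
      skipped <- rbind(skipped, data.frame(
        stratum = s, reason = "too few samples for the model",
        stringsAsFactors = FALSE))
      next
    }
    d <- brayCurtis(tpm[keep, , drop = FALSE])
    fml <- stats::as.formula(paste("d ~", paste(use_terms, collapse = " + ")))
    environment(fml) <- environment()
    results[[s]] <- permanova(fml, sub_meta, permutations = permutations,
                              mode = mode, seed = stratum_seeds[i])
  }
  list(results = results,
       skipped = if (is.null(skipped)) data.frame(
         stratum = character(), reason = character()) else skipped,
       dropped = if (is.null(dropped)) data.frame(
         stratum = character(), term = character(), level = character(),
         n = integer()) else dropped)
}
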