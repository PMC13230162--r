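#' Log transform of relative abundances for enrichment modelling
#'
#' Per-taxon response vectors ln(relative abundance + pseudocount), with
#' the pseudocount set to half the smallest nonzero relative abundance of
#' that taxon (recorded for audit). The transform follows the
#' TSS-normalise + LOG convention of multivariable microbiome association
#' models.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale, already passed
#'   through [enrichmentInputFilter()]
#' @return list with `response` (sample-by-taxon matrix) and
#'   `pseudocount` (named per-taxon vector)
#' @export
transformAbundance <- function(tpm) {
  rel <- tpm / 1e6
  pc <- apply(rel, 2, function(v) {
    nz <- v[v > 0]
    if (!length(nz)) stop("all-zero taxon reached the transform; filter first")
    min(nz) / 2
  })
  response <- log(sweep(rel, 2, pc, "+"))
  list(response = response, pseudocount = pc)
}

#' Fit one pairwise covariate-adjusted model per taxon
#'
#' Restricted to samples of the two levels of the primary factor, each
#' taxon's log-abundance response is regressed (OLS) on the
#' contrast-level indicator plus dummy-coded covariates. Covariate levels
#' absent within the pair are dropped; covariate columns confounded with
#' the rest of the design are removed by the rank-revealing decomposition
#' and the affected taxa flagged if the primary indicator itself is lost.
#' Zero-variance responses get coefficient 0 and p = 1 (flagged).
#'
#' @param response sample-by-taxon response matrix from
#'   [transformAbundance()]
#' @param meta sample metadata aligned with `response` rows
#' @param primary name of the primary factor column
#' @param ref,contrast the two levels compared; the coefficient is the
#'   log-scale shift of `contrast` relative to `ref`
#' @param covariates character vector of covariate columns
#' @return data.frame (taxon, coefficient, p, flagged) with attributes
#'   `reference`, `contrast`, `n`, `dropped_covariates`
#' @export
fitPairwise <- function(response, meta, primary, ref, contrast,
                        covariates = character()) {
  if (identical(ref, contrast)) stop("reference and contrast must differ")
  if (primary %in% covariates)
    stop("primary factor cannot also be a covariate")
  sel <- meta[[primary]] %in% c(ref, contrast)
  Y <- response[sel, , drop = FALSE]
  g <- factor(as.character(meta[[primary]][sel]), levels = c(ref, contrast))
  if (min(table(g)) < 3L)
    stop(sprintf("level with fewer than 3 samples in pair %s vs %s",
                 ref, contrast))
  X <- cbind(`(Intercept)` = 1, primary = as.numeric(g == contrast))
  dropped <- character()
  for (cv in covariates) {
    f <- droplevels(factor(meta[[cv]][sel]))
    if (nlevels(f) < 2L) { dropped <- c(dropped, cv); next }
    X <- cbind(X, stats::model.matrix(~f)[, -1, drop = FALSE])
  }
  qx <- qr(X)
  r <- qx$rank
  used <- qx$pivot[seq_len(r)]
  primary_ok <- 2L %in% used
  Xr <- X[, used, drop = FALSE]
  fit <- stats::lm.fit(Xr, Y)
  n <- nrow(Xr)
  df <- n - r
  if (df < 1L) stop("saturated design: no residual degrees of freedom")
  res <- as.matrix(fit$residuals)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qr(Xr)))
  j <- match(2L, used)
  coefs <- as.matrix(fit$coefficients)
  beta <- if (primary_ok) coefs[j, ] else rep(NA_real_, ncol(Y))
  se <- if (primary_ok) sqrt(pmax(sigma2, 0) * XtXinv[j, j]) else
    rep(NA_real_, ncol(Y))
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  flagged <- rep(!primary_ok, ncol(Y))
  degen <- sigma2 < .Machine$double.eps * 100
  if (any(degen) && primary_ok) {
    p[degen] <- ifelse(abs(beta[degen]) < 1e-12, 1, 0)
    beta[degen & abs(beta) < 1e-12] <- 0
    flagged[degen] <- TRUE
  }
  out <- data.frame(taxon = colnames(Y), coefficient = beta, p = p,
                    flagged = flagged, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "reference") <- ref
  attr(out, "contrast") <- contrast
  attr(out, "n") <- n
  attr(out, "dropped_covariates") <- dropped
  out
}

#' Cross-comparison consistency classifier
#'
#' Labels a taxon enriched in level L only when, in both pairwise models
#' involving L, the effect direction favours L and the BH q-value is
#' strictly below `q_threshold`. Discordant signs or one q at or above
#' the threshold yield no label; sign logic makes labels mutually
#' exclusive. Taxa missing one of the two required models are labelled
#' none and flagged incomplete.
#'
#' @param models data.frame with columns taxon, reference, contrast,
#'   coefficient, q (one row per taxon per pairwise model)
#' @param levels the three levels of the primary factor
#' @param q_threshold strict q cutoff (default 0.05)
#' @return data.frame (taxon, label, incomplete); label is
#'   "enriched-in-<L>" or "none"
#' @export
classifyConsistent <- function(models, levels, q_threshold = 0.05) {
  taxa <- unique(models$taxon)
  label <- rep("none", length(taxa))
  incomplete <- rep(FALSE, length(taxa))
  for (L in levels) {
    rel <- models[models$reference == L | models$contrast == L, ]
    # effect favours L: positive when L is the contrast, negative when ref
    rel$favors <- ifelse(rel$contrast == L, rel$coefficient,
                         -rel$coefficient)
    spl <- split(rel, rel$taxon)
    for (tx in names(spl)) {
      rws <- spl[[tx]]
      i <- match(tx, taxa)
      if (nrow(rws) < 2L) { incomplete[i] <- TRUE; next }
      if (anyNA(rws$favors) || anyNA(rws$q)) next
      if (all(rws$favors > 0) && all(rws$q < q_threshold))
        label[i] <- paste0("enriched-in-", L)
    }
  }
  data.frame(taxon = taxa, label = label, incomplete = incomplete,
             row.names = NULL, stringsAsFactors = FALSE)
}

.defaultCovariates <- function(primary) {
  switch(primary,
         breed = c("company", "farm", "batch"),
         age_stage = c("farm", "breed", "batch"),
         stop("unsupported primary factor: ", primary))
}

#' Breed / age-stage enrichment analysis
#'
#' The full per-taxon association chain: abundance filtering (detection in
#' >= `min_prev` of samples and mean relative abundance >= `min_mean`),
#' log transform with per-taxon pseudocount, the three pairwise
#' covariate-adjusted models over the levels of the primary factor, BH
#' adjustment across taxa within each pairwise model, and the consistency
#' classifier. Default covariates are company + farm + batch for breed and
#' farm + breed + batch for age stage.
#'
#' @param tpm sample-by-taxon matrix on the TPM scale
#' @param meta sample metadata aligned with `tpm` rows
#' @param primary "breed" or "age_stage" (must have exactly 3 levels)
#' @param covariates covariate columns; NULL picks the primary-specific
#'   default
#' @param q_threshold strict BH q cutoff for the classifier
#' @param min_prev,min_mean filters of [enrichmentInputFilter()]
#' @return an `enrichmentResult`: list with `models` (long data.frame:
#'   taxon, reference, contrast, coefficient, p, q, flagged), `labels`
#'   (from [classifyConsistent()]), `pseudocount`, `settings`
#' @export
runEnrichment <- function(tpm, meta, primary = "breed", covariates = NULL,
                          q_threshold = 0.05, min_prev = 0.05,
                          min_mean = 1e-5) {
  lv <- levels(droplevels(factor(meta[[primary]])))
  if (length(lv) != 3L)
    stop("primary factor must have exactly 3 levels, found ", length(lv))
  if (is.null(covariates)) covariates <- .defaultCovariates(primary)
  filtered <- enrichmentInputFilter(tpm, min_prev = min_prev,
                                    min_mean_relabund = min_mean)
  tr <- transformAbundance(filtered)
  pairs <- utils::combn(lv, 2)
  models <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    ft <- fitPairwise(tr$response, meta, primary,
                      ref = pairs[1, i], contrast = pairs[2, i],
                      covariates = covariates)
    data.frame(taxon = ft$taxon, reference = pairs[1, i],
               contrast = pairs[2, i], coefficient = ft$coefficient,
               p = ft$p, q = bhAdjust(ft$p), flagged = ft$flagged,
               stringsAsFactors = FALSE)
  }))
  labels <- classifyConsistent(models, lv, q_threshold)
  structure(list(models = models, labels = labels,
                 pseudocount = tr$pseudocount,
                 settings = list(primary = primary, covariates = covariates,
                                 q_threshold = q_threshold,
                                 min_prev = min_prev, min_mean = min_mean,
                                 levels = lv)),
            class = "enrichmentResult")
}

#' @export
print.enrichmentResult <- function(x, ...) {
  st <- x$settings
  cat(sprintf("enrichment: primary %s (%s), covariates %s\n", st$primary,
              paste(st$levels, collapse = "/"),
              paste(st$covariates, collapse = "+")))
  cat(sprintf("%d taxa x 3 pairwise models; q < %g in both models required\n",
              length(unique(x$models$taxon)), st$q_threshold))
  tab <- table(x$labels$label)
  for (nm in names(tab)) cat(sprintf("  %-22s %d\n", nm, tab[nm]))
  invisible(x)
}

#' Evaluate enrichment calls against a planted truth table
#'
#' For simulated cohorts: compares consistency labels with the generator's
#' planted breed/stage effects. A planted record (taxon, level, sign +1)
#' counts as recovered when the taxon is labelled enriched in that level.
#'
#' @param result an `enrichmentResult`
#' @param truth planted-truth data.frame (taxon, factor, level, sign)
#' @return list with per-level recovery counts, the number of labelled
#'   null taxa, the null label rate, and the false-discovery proportion
#'   among labelled taxa
#' @export
evaluateEnrichment <- function(result, truth) {
  primary <- result$settings$primary
  truth <- truth[truth$factor == primary & truth$sign > 0, , drop = FALSE]
  labels <- result$labels
  planted_label <- paste0("enriched-in-", truth$level)
  got <- labels$label[match(truth$taxon, labels$taxon)]
  recovered <- !is.na(got) & got == planted_label
  per_level <- table(factor(truth$level,
                            levels = result$settings$levels))
  rec_level <- table(factor(truth$level[recovered],
                            levels = result$settings$levels))
  null_taxa <- setdiff(labels$taxon, truth$taxon)
  null_labeled <- sum(labels$label[labels$taxon %in% null_taxa] != "none")
  n_labeled <- sum(labels$label != "none")
  list(n_planted = nrow(truth),
       n_recovered = sum(recovered),
       planted_per_level = stats::setNames(as.integer(per_level),
                                           names(per_level)),
       recovered_per_level = stats::setNames(as.integer(rec_level),
                                             names(rec_level)),
       n_null = length(null_taxa),
       null_labeled = null_labeled,
       null_label_rate = if (length(null_taxa)) null_labeled /
         length(null_taxa) else NA_real_,
       false_discovery_proportion = if (n_labeled) null_labeled /
         n_labeled else 0)
}
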