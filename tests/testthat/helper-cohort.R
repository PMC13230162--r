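# shared builders for small simulated cohorts

# one-farm design with equal breed groups
flatDesign <- function(n_per = 20, breeds = c("Duroc", "Landrace", "LargeWhite"),
                       farms = "F1", n_batches = 2, seed = 1) {
  gr <- expand.grid(breed = breeds, farm = farms, stringsAsFactors = FALSE)
  gr$company <- "A"
  gr$n <- n_per
  cohortDesign(gr[, c("company", "farm", "breed", "n")],
               n_batches = n_batches, seed = seed)
}

# nine-group design mirroring the surveyed stations but at reduced size
miniStationDesign <- function(n_per = 15, seed = 1, n_batches = 2) {
  gr <- boarStationGroups()
  gr$n <- n_per
  cohortDesign(gr, n_batches = n_batches, seed = seed)
}

nullModel <- function(n_taxa = 40, dispersion = 1, ...)
  effectModel(n_taxa = n_taxa, dispersion = dispersion, ...)

plantBreed <- function(taxa, level, shift)
  data.frame(taxon = taxa, level = level, shift = shift)

# brute-force BH step-up, independent of stats::p.adjust
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force exclusive intersections via set algebra over all subsets
bruteIntersections <- function(sets) {
  k <- length(sets)
  nms <- names(sets)
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    inn <- nms[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    outg <- setdiff(nms, inn)
    cur <- Reduce(intersect, sets[inn])
    for (g in outg) cur <- setdiff(cur, sets[[g]])
    out[[paste(inn, collapse = "&")]] <- length(cur)
  }
  out
}
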