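test_that("pseudocount is half the minimum nonzero relative abundance", {
  tp <- cbind(t1 = c(20, 0, 40, 0), t2 = c(10, 10, 10, 10))
  tp <- cbind(tp, filler = 1e6 - rowSums(tp))
  tr <- transformAbundance(tp)
  expect_equal(unname(tr$pseudocount["t1"]), 1e-5)   # min nonzero 2e-5
  expect_equal(tr$response[, "t1"],
               log(tp[, "t1"] / 1e6 + 1e-5), ignore_attr = TRUE)
})

test_that("doubling a taxon shifts its response uniformly, not its coefficient", {
  set.seed(3)
  n <- 60
  meta <- data.frame(breed = rep(c("A", "B"), each = n / 2),
                     batch = sample(c("b1", "b2"), n, TRUE))
  base <- matrix(rexp(n * 4) * 100 + 10, n, 4,
                 dimnames = list(NULL, paste0("t", 1:4)))
  resp1 <- transformAbundance(base)$response
  doubled <- base; doubled[, "t2"] <- doubled[, "t2"] * 2
  resp2 <- transformAbundance(doubled)$response
  shift <- resp2[, "t2"] - resp1[, "t2"]
  expect_lt(diff(range(shift)), 1e-12)
  expect_equal(mean(shift), log(2), tolerance = 1e-12)
  f1 <- fitPairwise(resp1, meta, "breed", "A", "B", "batch")
  f2 <- fitPairwise(resp2, meta, "breed", "A", "B", "batch")
  expect_equal(f1$coefficient, f2$coefficient, tolerance = 1e-10)
})

test_that("pairwise OLS recovers planted shifts and adjusts for batch", {
  # planted +1.5 log-shift: estimates concentrate around it
  est <- vapply(1:20, function(s) {
    des <- flatDesign(n_per = 50, breeds = c("A", "B", "C"), seed = s)
    mod <- effectModel(n_taxa = 40, base_logmean = rep(0, 40),
                       dispersion = 0.5,
                       breed_effects = plantBreed(1, "A", 1.5))
    sc <- simulateCohort(des, mod)
    tr <- transformAbundance(tpm(sc))
    ft <- fitPairwise(tr$response, sampleData(sc), "breed", "B", "A")
    ft$coefficient[1]
  }, numeric(1))
  expect_gte(mean(est >= 1.2 & est <= 1.8), 0.95)

  # batch effect as covariate: null primary coefficient stays centred
  est0 <- vapply(1:20, function(s) {
    des <- flatDesign(n_per = 40, breeds = c("A", "B", "C"), seed = 100 + s,
                      n_batches = 2)
    mod <- effectModel(n_taxa = 40, dispersion = 0.5,
                       batch_effects = data.frame(taxon = 1, level = "F1_b1",
                                                  shift = 2))
    sc <- simulateCohort(des, mod)
    tr <- transformAbundance(tpm(sc))
    ft <- fitPairwise(tr$response, sampleData(sc), "breed", "A", "B",
                      covariates = "batch")
    ft$coefficient[1]
  }, numeric(1))
  expect_lt(abs(mean(est0)), 0.1)
})

test_that("degenerate responses are flagged with p = 1", {
  n <- 12
  meta <- data.frame(breed = rep(c("A", "B"), each = n / 2))
  resp <- cbind(flat = rep(3.5, n), ok = rnorm(n))
  ft <- fitPairwise(resp, meta, "breed", "A", "B")
  expect_equal(ft$coefficient[ft$taxon == "flat"], 0)
  expect_equal(ft$p[ft$taxon == "flat"], 1)
  expect_true(ft$flagged[ft$taxon == "flat"])
  expect_false(ft$flagged[ft$taxon == "ok"])
})

test_that("consistency classifier follows the two-model concordance rule", {
  mk <- function(q1, q2, c1 = 1, c2 = -1) data.frame(
    taxon = "t", reference = c("DU", "LR"), contrast = c("LR", "LW"),
    coefficient = c(c1, c2), q = c(q1, q2))
  lv <- c("DU", "LR", "LW")
  # both models favour LR (contrast +, reference -) with q < 0.05
  expect_equal(classifyConsistent(mk(0.01, 0.02), lv)$label,
               "enriched-in-LR")
  # second model misses the strict threshold
  expect_equal(classifyConsistent(mk(0.01, 0.06), lv)$label, "none")
  expect_equal(classifyConsistent(mk(0.05, 0.01), lv)$label, "none")
  # discordant directions, however significant
  expect_equal(classifyConsistent(mk(1e-5, 1e-5, c1 = 1, c2 = 1), lv)$label,
               "none")
  # missing one model: incomplete, none
  one <- mk(0.01, 0.01)[1, ]
  out <- classifyConsistent(one, lv)
  expect_equal(out$label, "none")
  expect_true(out$incomplete)
})

test_that("labels are invariant to reference/contrast orientation", {
  des <- flatDesign(n_per = 30, seed = 8)
  mod <- effectModel(n_taxa = 50, dispersion = 0.6,
                     breed_effects = plantBreed(1:4, "Duroc", 2.5))
  sc <- simulateCohort(des, mod)
  ab <- tpm(sc); meta <- sampleData(sc)
  filtered <- enrichmentInputFilter(ab)
  tr <- transformAbundance(filtered)
  a <- fitPairwise(tr$response, meta, "breed", "Duroc", "Landrace")
  b <- fitPairwise(tr$response, meta, "breed", "Landrace", "Duroc")
  expect_equal(a$coefficient, -b$coefficient, tolerance = 1e-10)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("full enrichment run is order-invariant and deterministic", {
  des <- flatDesign(n_per = 20, seed = 5)
  mod <- effectModel(n_taxa = 40, dispersion = 0.8,
                     breed_effects = plantBreed(1:3, "Landrace", 3))
  sc <- simulateCohort(des, mod)
  ab <- tpm(sc); meta <- sampleData(sc)
  r1 <- runEnrichment(ab, meta, primary = "breed")
  set.seed(99)
  prm <- sample(nrow(ab))
  r2 <- runEnrichment(ab[prm, ], meta[prm, ], primary = "breed")
  expect_equal(r1$models, r2$models, tolerance = 1e-10)
  expect_equal(r1$labels, r2$labels)
  expect_true(all(r1$models$q >= r1$models$p - 1e-15))
  expect_error(runEnrichment(ab[meta$breed != "Duroc", ],
                             meta[meta$breed != "Duroc", ]),
               "exactly 3 levels")
})

test_that("planted breed taxa are recovered and null cohorts stay quiet", {
  des <- flatDesign(n_per = 40, seed = 61)
  eff <- rbind(plantBreed(1:4, "Duroc", 3), plantBreed(5:8, "Landrace", 3),
               plantBreed(9:12, "LargeWhite", 3))
  # flat baseline keeps planted mass symmetric across breeds, so closure
  # does not spill the planted signal into null taxa
  sc <- simulateCohort(des, effectModel(n_taxa = 80,
                                        base_logmean = rep(0, 80),
                                        dispersion = 1,
                                        breed_effects = eff))
  r <- runEnrichment(tpm(sc), sampleData(sc), primary = "breed")
  ev <- evaluateEnrichment(r, plantedTruth(sc))
  expect_gte(ev$n_recovered, 10)
  expect_lte(ev$false_discovery_proportion, 0.10)

  # no-effect cohorts: labelled fraction small in the majority of seeds
  frac <- vapply(1:10, function(s) {
    sc0 <- simulateCohort(flatDesign(n_per = 25, seed = 200 + s),
                          nullModel(n_taxa = 50))
    r0 <- runEnrichment(tpm(sc0), sampleData(sc0), primary = "breed")
    mean(r0$labels$label != "none")
  }, numeric(1))
  expect_gte(mean(frac <= 0.05), 0.5)
})

test_that("age-stage enrichment uses the same machinery on three stages", {
  des <- flatDesign(n_per = 35, seed = 44)
  mod <- effectModel(n_taxa = 40, dispersion = 0.8,
                     stage_effects = data.frame(taxon = 1:2, level = "aged",
                                                shift = 3))
  sc <- simulateCohort(des, mod)
  r <- runEnrichment(tpm(sc), sampleData(sc), primary = "age_stage")
  got <- r$labels$label[r$labels$taxon %in% c("t0001", "t0002")]
  expect_true(any(got == "enriched-in-aged"))
})
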