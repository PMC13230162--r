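test_that("Gower centring: hand cases and centring identities", {
  # two points at distance 1: total SS = sum d^2 / n = 0.5
  G2 <- gowerCenter(matrix(c(0, 1, 1, 0), 2))
  expect_equal(sum(diag(G2)), 0.5, tolerance = 1e-12)
  expect_equal(gowerCenter(matrix(0, 4, 4)), matrix(0, 4, 4))
  set.seed(2)
  d <- as.matrix(dist(matrix(rnorm(18), 6)))
  G <- gowerCenter(d)
  expect_lt(max(abs(rowSums(G))), 1e-10)
  expect_true(isSymmetric(G))
  expect_error(gowerCenter(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("sequential SS on Euclidean 1-D data equals classical ANOVA", {
  set.seed(14)
  for (i in 1:5) {
    n <- 36
    meta <- data.frame(f1 = factor(sample(letters[1:3], n, TRUE)),
                       f2 = factor(sample(LETTERS[1:4], n, TRUE)))
    y <- rnorm(n) + as.integer(meta$f1)
    d <- dist(y)
    fml <- d ~ f1 + f2; environment(fml) <- environment()
    res <- permanova(fml, meta, permutations = 0)
    av <- anova(lm(y ~ f1 + f2, meta))
    expect_equal(res$SumOfSqs[1:3], av[["Sum Sq"]], tolerance = 1e-8)
    expect_equal(res$Df[1:3], av$Df)
    # exact decomposition
    expect_equal(sum(res$SumOfSqs[1:3]), res$SumOfSqs[4], tolerance = 1e-8)
  }
})

test_that("sequential and marginal tables reproduce the reference implementation", {
  set.seed(23)
  n <- 30
  meta <- data.frame(a = factor(sample(c("x", "y", "z"), n, TRUE)),
                     b = factor(sample(c("p", "q"), n, TRUE)))
  x <- matrix(rexp(n * 20), n)
  d <- vegan::vegdist(x)
  fml <- d ~ a + b; environment(fml) <- environment()
  seq_mine <- permanova(fml, meta, permutations = 99, seed = 1)
  seq_ref <- vegan::adonis2(d ~ a + b, data = meta, permutations = 99,
                            by = "terms")
  expect_equal(seq_mine$SumOfSqs, seq_ref$SumOfSqs, tolerance = 1e-10)
  expect_equal(seq_mine$R2, seq_ref$R2, tolerance = 1e-10)
  expect_equal(seq_mine$F[1:2], seq_ref$F[1:2], tolerance = 1e-10)
  marg_mine <- permanova(fml, meta, permutations = 99, mode = "marginal",
                         seed = 1)
  marg_ref <- vegan::adonis2(d ~ a + b, data = meta, permutations = 99,
                             by = "margin")
  expect_equal(marg_mine$SumOfSqs[1:2], marg_ref$SumOfSqs[1:2],
               tolerance = 1e-10)
})

test_that("permutation p matches exhaustive enumeration on a 6-sample design", {
  set.seed(6)
  y <- c(0.3, 1.1, 0.8, 2.4, 2.9, 2.1)
  g <- factor(rep(c("A", "B"), each = 3))
  d <- dist(y)
  # enumeration oracle: pseudo-F for every 3-of-6 label assignment
  G <- gowerCenter(as.matrix(d))
  fStat <- function(lab) {
    H <- {
      X <- cbind(1, as.numeric(lab == "B"))
      Q <- qr.Q(qr(X))
      tcrossprod(Q)
    }
    ssb <- sum(H * G) # includes intercept part = 0 on centred G
    ssr <- sum(diag(G)) - ssb
    (ssb / 1) / (ssr / 4)
  }
  f_obs <- fStat(g)
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; fStat(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  meta <- data.frame(g = g)
  fml <- d ~ g; environment(fml) <- environment()
  res <- permanova(fml, meta, permutations = 999, seed = 42)
  expect_lt(abs(res["g", "p"] - p_exact), 0.05)
})

test_that("equal off-diagonal distances give an exchangeable, effect-free fit", {
  n <- 12
  d <- matrix(0.7, n, n); diag(d) <- 0
  meta <- data.frame(g = factor(rep(c("a", "b", "c"), each = 4)))
  fml <- d ~ g; environment(fml) <- environment()
  res <- permanova(fml, meta, permutations = 199, seed = 3)
  # under exchangeability the term R2 equals its df share of n - 1
  expect_lt(abs(res["g", "R2"] - res["g", "Df"] / (n - 1)), 1e-8)
  expect_equal(res["g", "F"], 1, tolerance = 1e-8)
})

test_that("marginal equals sequential on balanced orthogonal designs", {
  meta <- expand.grid(a = factor(c("x", "y")), b = factor(c("p", "q", "r")),
                      rep = 1:3)[, 1:2]
  set.seed(9)
  y <- rnorm(nrow(meta)) + 2 * as.integer(meta$a) + 0.5 * as.integer(meta$b)
  d <- dist(cbind(y, rnorm(nrow(meta))))
  fml <- d ~ a + b; environment(fml) <- environment()
  s <- permanova(fml, meta, permutations = 0)
  m <- permanova(fml, meta, permutations = 0, mode = "marginal")
  expect_equal(s$SumOfSqs[1:2], m$SumOfSqs[1:2], tolerance = 1e-8)
})

test_that("permutation p is seeded-reproducible and stable across seeds", {
  set.seed(33)
  n <- 40
  meta <- data.frame(g = factor(sample(c("a", "b"), n, TRUE)))
  x <- matrix(rexp(n * 10), n)
  x[meta$g == "a", 1:3] <- x[meta$g == "a", 1:3] * 2.2
  d <- vegan::vegdist(x)
  fml <- d ~ g; environment(fml) <- environment()
  p1 <- permanova(fml, meta, permutations = 999, seed = 5)["g", "p"]
  p2 <- permanova(fml, meta, permutations = 999, seed = 5)["g", "p"]
  expect_identical(p1, p2)
  ps <- vapply(1:5, function(s)
    permanova(fml, meta, permutations = 999, seed = s)["g", "p"], numeric(1))
  se <- 2 * sqrt(max(mean(ps), 1 / 1000) * (1 - mean(ps)) / 999)
  expect_lt(max(ps) - min(ps), 2 * se + 2e-3)
})

test_that("confounded terms get zero df and a flag", {
  meta <- data.frame(g = factor(rep(c("a", "b"), each = 5)))
  meta$dup <- meta$g  # perfectly confounded copy
  set.seed(3)
  d <- dist(rnorm(10))
  fml <- d ~ g + dup; environment(fml) <- environment()
  expect_warning(res <- permanova(fml, meta, permutations = 99), "confounded")
  expect_equal(res["dup", "Df"], 0)
  expect_true(attr(res, "confounded")["dup"])
})

test_that("stratified fits drop undersized levels and record skips", {
  # farm-like strata; one breed of n = 8 must be excluded at min size 10
  gr <- data.frame(company = "A",
                   farm = c("A2", "A2", "A2", "Z", "Z"),
                   breed = c("Duroc", "Landrace", "LargeWhite", "Duroc",
                             "Landrace"),
                   n = c(8, 20, 20, 4, 5))
  sc <- simulateCohort(cohortDesign(gr, seed = 19, n_batches = 1),
                       nullModel(n_taxa = 25))
  ab <- tpm(sc); meta <- sampleData(sc)
  out <- permanovaByStratum(ab, meta, "farm", c("breed", "age_stage"),
                            min_group_size = 10, permutations = 99, seed = 2)
  expect_true("A2" %in% names(out$results))
  dropped_a2 <- out$dropped[out$dropped$stratum == "A2" &
                              out$dropped$term == "breed", ]
  expect_true("Duroc" %in% dropped_a2$level)
  expect_equal(dropped_a2$n[dropped_a2$level == "Duroc"], 8L)
  # stratum Z is entirely degenerate after exclusion
  expect_true("Z" %in% out$skipped$stratum)
})

test_that("a planted breed effect dominates batch in stratified R2", {
  wins <- vapply(1:25, function(s) {
    gr <- data.frame(company = "B", farm = "B1",
                     breed = c("Duroc", "Landrace", "LargeWhite"),
                     n = c(40, 15, 12))
    mod <- effectModel(n_taxa = 40, dispersion = 1,
                       breed_effects = plantBreed(1:6, "Duroc", 2.5))
    sc <- simulateCohort(cohortDesign(gr, seed = s, n_batches = 2), mod)
    ab <- tpm(sc); meta <- sampleData(sc)
    out <- permanovaByStratum(ab, meta, "farm", c("breed", "batch"),
                              min_group_size = 10, permutations = 0)
    r <- out$results$B1
    r["breed", "R2"] > r["batch", "R2"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
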