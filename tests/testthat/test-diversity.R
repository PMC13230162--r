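test_that("alpha indices match closed forms", {
  tp <- rbind(uniform4 = rep(2.5e5, 4),
              single = c(1e6, 0, 0, 0),
              skew = c(5e5, 2.5e5, 2.5e5, 0))
  a <- alphaDiversity(tp)
  expect_equal(a$richness, c(4, 1, 3))
  expect_equal(a$shannon, c(log(4), 0, 1.5 * log(2)), tolerance = 1e-12)
  expect_equal(a$simpson, c(0.75, 0, 0.625), tolerance = 1e-12)
  expect_error(alphaDiversity(rbind(c(0, 0))), "empty")
})

test_that("Shannon is maximal at uniformity and Simpson bounded by 1 - 1/S", {
  set.seed(4)
  for (S in c(3, 7, 20)) {
    u <- matrix(1e6 / S, 1, S)
    pert <- normalizeTPM(u + matrix(runif(S, 0, 1e5), 1))
    a_u <- alphaDiversity(u); a_p <- alphaDiversity(pert)
    expect_gt(a_u$shannon, a_p$shannon)
    expect_lte(a_p$simpson, 1 - 1 / S)
    expect_lte(a_p$shannon, log(S) + 1e-12)
  }
})

test_that("Bray-Curtis handles identical, disjoint and hand-computed rows", {
  tp <- normalizeTPM(rbind(a = c(0.7, 0.3, 0), b = c(0.2, 0.3, 0.5),
                           a2 = c(0.7, 0.3, 0), c = c(0, 0, 1)))
  d <- as.matrix(brayCurtis(tp))
  expect_equal(d["a", "a2"], 0)
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(d["a", "c"], 1)          # disjoint supports
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(brayCurtis(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("PCoA recovers Euclidean configurations and symmetric cases", {
  # three equidistant points sit at equilateral-triangle vertices
  d3 <- matrix(1, 3, 3) - diag(3)
  pc3 <- pcoa(d3)
  cd <- as.matrix(dist(pc3$coordinates))
  off <- cd[upper.tri(cd)]
  expect_lt(max(abs(off - off[1])), 1e-9)

  # distances from random planar points are reproduced exactly
  set.seed(8)
  pts <- matrix(rnorm(2 * 12), 12, 2)
  d <- dist(pts)
  pc <- pcoa(d, n_axes = 2)
  expect_lt(max(abs(as.matrix(dist(pc$coordinates)) - as.matrix(d))), 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-9))
  expect_lte(sum(pc$proportion_explained), 1 + 1e-12)

  # duplicated samples land on identical coordinates
  tp <- normalizeTPM(matrix(runif(5 * 8), 5, 8))
  tp <- rbind(tp, tp[1, , drop = FALSE])
  pcd <- pcoa(as.matrix(brayCurtis(tp)))
  expect_equal(pcd$coordinates[1, ], pcd$coordinates[6, ], tolerance = 1e-9,
               ignore_attr = TRUE)

  # asking for more axes than positive eigenvalues truncates with warning
  expect_warning(pc_few <- pcoa(d3, n_axes = 3), "positive")
  expect_equal(ncol(pc_few$coordinates), 2L)
  expect_true(pc_few$axes_truncated)
})

test_that("PCoA agrees with the reference classical-scaling implementation", {
  skip_if_not_installed("ape")
  set.seed(21)
  tp <- normalizeTPM(matrix(rexp(10 * 15), 10, 15))
  rownames(tp) <- paste0("s", 1:10)
  d <- brayCurtis(tp)
  mine <- pcoa(d, n_axes = 2)
  ref <- ape::pcoa(d)
  expect_equal(abs(mine$coordinates[, 1]), abs(ref$vectors[, 1]),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mine$eigenvalues[1:4], ref$values$Eigenvalues[1:4],
               tolerance = 1e-8)
})

test_that("BH adjustment matches hand results and the brute-force oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bhAdjust(p)
    expect_equal(q, bruteBH(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  }
})

test_that("group comparisons: ties, null behaviour and power", {
  # degenerate ties: one shared value in two groups of two
  a <- data.frame(sample_id = 1:4, richness = c(5, 5, 5, 5),
                  shannon = rep(1, 4), simpson = rep(0.5, 4))
  cmp <- compareGroupsAlpha(a, c("g1", "g1", "g2", "g2"))
  expect_true(all(abs(cmp$p - 1) < 1e-9))

  # identically-distributed breeds: each index family stays calibrated
  hits <- vapply(1:100, function(i) {
    sc <- simulateCohort(flatDesign(n_per = 15, breeds = c("A", "B"),
                                    seed = 4000 + i),
                         nullModel(n_taxa = 30))
    al <- alphaDiversity(tpm(gateByCoverage(sc)))
    cmp <- compareGroupsAlpha(al, sampleData(sc)$breed)
    vapply(split(cmp$q, cmp$index), min, numeric(1)) < 0.05
  }, logical(3))
  expect_true(all(rowMeans(hits) <= 0.10))

  # a large planted richness shift is detected decisively
  al <- data.frame(sample_id = 1:60,
                   richness = c(rpois(30, 40), rpois(30, 90)),
                   shannon = rnorm(60, 3, 0.2), simpson = runif(60, 0.8, 0.95))
  cmp <- compareGroupsAlpha(al, rep(c("A", "B"), each = 30))
  expect_lt(cmp$p[cmp$index == "richness"], 1e-3)

  expect_error(compareGroupsAlpha(a, c("g1", "g1", "g1", "g2")), "fewer than 2")
})
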