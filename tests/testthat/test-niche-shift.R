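test_that("Bray-Curtis matches its definition and an external reference", {
  expect_identical(brayCurtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(brayCurtis(c(1, 1, 0), c(0, 0, 2)), 1)
  expect_equal(brayCurtis(c(1, 1, 0), c(0, 1, 1)), 0.5)
  expect_error(brayCurtis(c(0, 0), c(0, 0)), "undefined")
  set.seed(8)
  for (i in 1:1000) {
    p <- rgamma(6, 0.6); q <- rgamma(6, 0.6)
    expect_lt(abs(brayCurtis(p, q) - bcLoop(p, q)), 1e-12)
  }
  X <- matrix(rpois(5 * 7, 4), 5, 7)
  expect_equal(brayCurtisMatrix(X)[lower.tri(diag(5))],
               as.vector(vegan::vegdist(X, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dissimilarity matrices are symmetric with zero diagonal", {
  set.seed(21)
  X <- matrix(rgamma(8 * 10, 0.8), 8, 10)
  D <- brayCurtisMatrix(X)
  expect_identical(diag(D), numeric(8))
  expect_lt(max(abs(D - t(D))), 1e-15)
  expect_true(all(D >= 0 & D <= 1))
})

test_that("PERMANOVA reproduces the reference pseudo-F and R^2", {
  set.seed(31)
  X <- matrix(rpois(14 * 9, 5) * rep(c(1, 2), each = 7), 14, 9)
  g <- rep(c("a", "b"), each = 7)
  D <- brayCurtisMatrix(X)
  mine <- permanova(D, g, nPerm = 199, seed = 4)
  ref <- vegan::adonis2(stats::as.dist(D) ~ g, permutations = 199)
  expect_lt(abs(mine$f - ref$F[1]), 1e-10)
  expect_lt(abs(mine$r2 - ref$R2[1]), 1e-10)
  expect_gte(mine$p, 1 / 200)

  expect_identical(permanova(D, g, nPerm = 99, seed = 7)$p,
                   permanova(D, g, nPerm = 99, seed = 7)$p)
  expect_error(permanova(D, c("a", rep("b", 13)), 99), "degenerate")
})

test_that("complete group separation attains the minimal p-value", {
  # groups large enough that a random relabelling essentially never
  # reconstitutes the observed split, so no permuted F ties the observed one
  set.seed(30)
  X <- rbind(
    cbind(matrix(5 + rpois(100, 3), 10, 10), matrix(0, 10, 10)),
    cbind(matrix(0, 10, 10), matrix(5 + rpois(100, 3), 10, 10)))
  D <- brayCurtisMatrix(X)
  res <- permanova(D, rep(c("a", "b"), each = 10), nPerm = 999, seed = 1)
  expect_identical(res$p, 1 / 1000)
})

test_that("duplicating every sample preserves R^2", {
  set.seed(41)
  X <- matrix(rgamma(12 * 6, 1), 12, 6)
  g <- rep(c("a", "b"), each = 6)
  D1 <- brayCurtisMatrix(X)
  D2 <- brayCurtisMatrix(X[rep(1:12, 2), ])
  r1 <- permanova(D1, g, nPerm = 49, seed = 1)
  r2 <- permanova(D2, rep(g, 2), nPerm = 49, seed = 1)
  expect_lt(abs(r1$r2 - r2$r2), 1e-10)
  expect_true(is.finite(r2$f))
})

test_that("PERMANOVA p-values are roughly uniform under exchangeability", {
  set.seed(51)
  ps <- vapply(1:300, function(i) {
    X <- matrix(rgamma(10 * 6, 0.9), 10, 6)
    permanova(brayCurtisMatrix(X), rep(c("a", "b"), each = 5),
              nPerm = 99, seed = i)$p
  }, numeric(1))
  expect_lt(suppressWarnings(
    stats::ks.test(ps, "punif")$statistic), 0.09)
})

test_that("NMDS recovers exactly embeddable configurations", {
  set.seed(61)
  P <- matrix(rnorm(8), 4, 2)
  D <- as.matrix(dist(P))
  res <- nmds(D, k = 2, nRestarts = 5, seed = 1)
  expect_lt(res$stress, 1e-3)
  expect_true(res$converged)
  expect_lt(max(abs(colMeans(res$points))), 1e-8)
})

test_that("NMDS stress is invariant to monotone transforms of D", {
  set.seed(62)
  P <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(P))
  s1 <- nmds(D, seed = 3)$stress
  s2 <- nmds(sqrt(D), seed = 4)$stress
  s3 <- nmds(D^2, seed = 5)$stress
  expect_lt(abs(s1 - s2), 1e-3)
  expect_lt(abs(s1 - s3), 1e-3)
})

test_that("NMDS separates well-separated clusters", {
  set.seed(63)
  X <- rbind(cbind(matrix(rgamma(5 * 6, 2) + 1, 5, 6), matrix(0, 5, 6)),
             cbind(matrix(0, 5, 6), matrix(rgamma(5 * 6, 2) + 1, 5, 6)))
  res <- nmds(brayCurtisMatrix(X), seed = 9)
  d <- as.matrix(dist(res$points))
  within <- c(d[1:5, 1:5][lower.tri(diag(5))],
              d[6:10, 6:10][lower.tri(diag(5))])
  between <- d[1:5, 6:10]
  expect_gt(mean(between), max(within))
})

test_that("diet profiles are row proportions over combined survey blocks", {
  records <- rbind(
    rec("i1", "B1", "P1", 5, round = 1), rec("i1", "B1", "P2", 5, round = 1),
    rec("i2", "B1", "P1", 5, round = 2),
    rec("i3", "B1", "P2", 5, round = 3), rec("i4", "B1", "P2", 5, round = 4),
    rec("i5", "B1", "P3", 1, round = 3))  # below threshold: not a link
  profs <- dietProfiles(records, "B1", blockSize = 2)
  M <- profs$B1$profiles
  expect_equal(rowSums(M), c(1, 1), ignore_attr = TRUE)
  # block 1 = rounds 1-2: links P1 x2, P2 x1
  expect_equal(M["p1:1", ], c(P1 = 2 / 3, P2 = 1 / 3))
  expect_equal(M["p1:2", ], c(P1 = 0, P2 = 1))
  single <- dietProfiles(records, "B1", combineAdjacent = FALSE)
  expect_identical(nrow(single$B1$profiles), 4L)
})

test_that("niche-shift testing handles one-sided and two-sided species", {
  sim <- simulateCommunity(simulationConfig(seed = 17))
  ab <- suppressWarnings(abundanceChange(sim$sweeps))
  common <- head(ab$bee_species[!ab$rare], 3)
  profs <- suppressMessages(dietProfiles(sim$pollen, common))
  res <- nicheShiftTest(profs, nPerm = 99, seed = 5)
  expect_identical(sort(res$tests$bee_species), sort(names(profs)))
  ok <- !is.na(res$tests$p)
  expect_true(all(res$tests$p[ok] >= 1 / 100 & res$tests$p[ok] <= 1))
})

test_that("flower surveys reshape and test cleanly", {
  sim <- simulateCommunity(simulationConfig(seed = 23, nPlants = 20))
  comp <- flowerComposition(sim$flowers)
  expect_identical(dim(comp$abundance), c(30L, 20L))  # 6 plots x 5 surveys
  res <- flowerSimilarity(sim$flowers, nPerm = 99, seed = 2)
  # flowering composition is shared across plots by construction
  expect_gt(res$permanova_type$p, 0.05)
  expect_s3_class(res$nmds, "nmdsResult")
})
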