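adjustedFixture <- function(counts, specimens) {
  methods::new("AdjustedMatrix", values = counts / specimens,
               divisors = specimens, plotId = "p1", plotType = "nearby")
}

test_that("abundance adjustment divides each row by its specimen count", {
  net <- buildNetwork(rbind(
    rec("b1", "B1", "P1", 5), rec("b2", "B1", "P1", 5),
    rec("b1", "B1", "P2", 5),
    rec("c1", "B2", "P2", 5)))
  adj <- adjustMatrix(net)
  expect_equal(adjustedValues(adj)["B1", ], c(P1 = 1, P2 = 0.5))
  expect_equal(adjustedValues(adj)["B2", ], c(P1 = 0, P2 = 1))
  # scaling counts and specimens together leaves the adjusted row unchanged
  m <- matrix(c(4, 2), 1, 2, dimnames = list("B1", c("P1", "P2")))
  expect_equal(m / 2, (3 * m) / 6)
})

test_that("the honeybee profile averages specimens and reduces the row", {
  nets <- lapply(1:3, function(i) {
    # build via records so validity and ordering apply
    rows <- list()
    for (b in 1:(10 * i)) rows[[length(rows) + 1]] <-
      rec(sprintf("hb%d_%d", i, b), "Apis_mellifera", "P1", 5,
          plot = paste0("n", i))
    for (b in 1:2) rows[[length(rows) + 1]] <-
      rec(sprintf("n%d_%d", i, b), "N1", "P2", 5, plot = paste0("n", i))
    buildNetwork(do.call(rbind, rows))
  })
  prof <- honeybeeProfile(nets, mode = "mean")
  expect_equal(prof@aHb, 20)  # specimens 10, 20, 30
  expect_equal(unname(prof@row[["P1"]]), 20)
  pooled <- honeybeeProfile(nets)
  expect_equal(unname(pooled@row[["P1"]]), 60)
  expect_equal(pooled@aHb, 20)

  adj <- adjustMatrix(nets[[1]], honeybee = prof)
  expect_equal(adjustedValues(adj)["Apis_mellifera", "P1"], 1)  # 20 / 20
})

test_that("Muller row sums over all partners are exactly one", {
  for (seed in 1:100) {
    set.seed(seed)
    A <- matrix(rpois(8 * 12, 2), 8, 12)
    A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
    dimnames(A) <- list(paste0("b", seq_len(nrow(A))),
                        paste0("p", seq_len(ncol(A))))
    d <- mullerMatrix(A)
    expect_lt(max(abs(rowSums(d) - 1)), 1e-12)
  }
})

test_that("a hand-summed index value is reproduced", {
  A <- matrix(c(2, 1, 0, 1, 1, 2), 2, 3, byrow = TRUE,
              dimnames = list(c("i", "j"), c("k1", "k2", "k3")))
  # per-term: (2/3)(1/3) + (1/3)(1/2) + 0 = 7/18
  expect_equal(mullerIndex(A, "i", "j"), 7 / 18)
  expect_equal(mullerMatrix(A), mullerLoop(A), ignore_attr = TRUE)
})

test_that("vectorized index equals the naive loop oracle on random networks", {
  for (seed in 1:100) {
    set.seed(seed)
    A <- matrix(rgamma(10 * 20, 0.5), 10, 20)
    A[A < 0.2] <- 0
    A <- A[rowSums(A) > 0, colSums(A) > 0, drop = FALSE]
    expect_lt(max(abs(mullerMatrix(A) - mullerLoop(A))), 1e-10)
  }
})

test_that("pairwise PAC hits its exact anchors", {
  v <- c(P1 = 0.2, P2 = 0.5, P3 = 0.3)
  expect_identical(pairwisePac(v, v), 0.5)
  expect_identical(pairwisePac(c(P1 = 1, P2 = 1, P3 = 0),
                               c(P1 = 0, P2 = 0, P3 = 2)), 0)
  expect_equal(pairwisePac(c(1, 1, 0), c(0, 1, 1)), 0.25)
  expect_message(z <- pairwisePac(c(P1 = 1), c(P1 = 0)), "PAC = 0")
  expect_identical(z, 0)
  expect_error(pairwisePac(c(P1 = 0), c(P1 = 1)), "undefined")
})

test_that("pairwise PAC is scale invariant and matches the loop oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- rgamma(15, 0.7); h <- rgamma(15, 0.7)
    n[sample.int(15, 4)] <- 0; h[sample.int(15, 4)] <- 0
    if (sum(n) == 0 || sum(h) == 0) next
    base <- pairwisePac(n, h)
    expect_lt(abs(base - pacLoop(n, h)), 1e-12)
    expect_lt(abs(pairwisePac(3.7 * n, h) - base), 1e-12)
    expect_lt(abs(pairwisePac(n, 0.21 * h) - base), 1e-12)
    expect_lt(abs(pairwisePac(n, h, "honeybee_to_native") - pacLoop(h, n)),
              1e-12)
  }
})

test_that("the PAC table aggregates per-plot pairwise values by plot mean", {
  sim <- simulateCommunity(simulationConfig(seed = 42))
  nets <- buildPlotNetworks(sim$pollen)
  types <- vapply(nets, plotType, character(1))
  nearby <- nets[types == "nearby"]; distant <- nets[types == "distant"]
  prof <- honeybeeProfile(nearby)
  tab <- pacTable(nearby, distant, prof)

  # loop oracle over plots and species
  adjAll <- lapply(c(nearby, distant), adjustMatrix, honeybee = prof)
  for (sp in tab$bee_species) {
    for (side in c("nearby", "distant")) {
      vals <- c()
      for (m in adjAll) {
        if (plotType(m) != side) next
        V <- adjustedValues(m)
        if (!sp %in% rownames(V) || sum(V[sp, ]) == 0) next
        vals <- c(vals, pacLoop(V[sp, ], V["Apis_mellifera", ]))
      }
      got <- tab[tab$bee_species == sp,
                 if (side == "nearby") "pac_c" else "pac_d"]
      if (length(vals)) expect_equal(got, mean(vals)) else expect_true(is.na(got))
    }
  }
  expect_true(all(tab$pac_d >= 0 & tab$pac_d <= 1, na.rm = TRUE))
  expect_true(all(tab$n_plots_d >= 1))
})

test_that("species present only in distant plots get PAC_D but no PAC_C", {
  mkRec <- function(plot, type, sp, ind, plant)
    rec(paste(plot, ind), sp, plant, 5, plot = plot, type = type)
  nearby <- lapply(1:2, function(i) buildNetwork(rbind(
    mkRec(paste0("n", i), "nearby", "Apis_mellifera", "h1", "P1"),
    mkRec(paste0("n", i), "nearby", "Apis_mellifera", "h2", "P2"),
    mkRec(paste0("n", i), "nearby", "CommonBee", "c1", "P1"))))
  distant <- list(buildNetwork(rbind(
    mkRec("d1", "distant", "LostBee", "l1", "P1"),
    mkRec("d1", "distant", "LostBee", "l2", "P2"),
    mkRec("d1", "distant", "CommonBee", "c2", "P2"))))
  tab <- pacTable(nearby, distant)
  lost <- tab[tab$bee_species == "LostBee", ]
  expect_true(is.na(lost$pac_c))
  expect_identical(lost$n_plots_c, 0L)
  expect_identical(lost$n_plots_d, 1L)
  # single contributing plot: the mean is that plot's pairwise value
  prof <- honeybeeProfile(nearby)
  V <- adjustedValues(adjustMatrix(distant[[1]], honeybee = prof))
  expect_equal(lost$pac_d, pacLoop(V["LostBee", ], V["Apis_mellifera", ]))
})
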