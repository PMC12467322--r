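test_that("relative change follows its defining arithmetic", {
  expect_identical(relativeChange(5, 5), 0)
  expect_identical(relativeChange(10, 0), 1)
  expect_equal(relativeChange(8, 2), 0.75)
  expect_error(relativeChange(0, 3), "undefined")
  for (seed in 1:20) {
    set.seed(seed)
    d <- runif(1, 0.1, 50); n <- runif(1, 0, 50); c <- runif(1, 0.01, 100)
    expect_equal(relativeChange(c * d, c * n), relativeChange(d, n))
  }
})

test_that("NB plot-type coefficient equals the log group-mean ratio", {
  # equal group means: coefficient collapses to zero
  swEq <- sweepFixture(muDistant = 6, muNearby = 6, seed = 5)
  # constant within each survey round, so both plot types share one mean
  swEq$count <- rep(c(4L, 8L), each = 6, length.out = nrow(swEq))
  fit <- suppressWarnings(fitSpeciesAbundanceGlm(swEq, "X"))
  expect_lt(abs(fit$estimate), 1e-8)

  for (seed in 1:5) {
    sw <- sweepFixture(muDistant = 7, muNearby = 2.5, seed = seed)
    gm <- tapply(sw$count, sw$plot_type, mean)
    if (any(gm == 0)) next
    fit <- suppressWarnings(fitSpeciesAbundanceGlm(sw, "X"))
    expect_lt(abs(fit$estimate - log(gm[["nearby"]] / gm[["distant"]])), 1e-6)
    expect_identical(fit$df_residual, nrow(sw) - 2L)
  }
})

test_that("NB fit flags boundary and non-identifiable cases", {
  sw <- sweepFixture(muDistant = 5, muNearby = 0, seed = 2)
  sw$count[sw$plot_type == "nearby"] <- 0L
  expect_warning(fit <- fitSpeciesAbundanceGlm(sw, "X"), "boundary")
  expect_true(fit$boundary)
  swZero <- sw; swZero$count <- 0L
  expect_error(fitSpeciesAbundanceGlm(swZero, "X"), "not identifiable")
})

test_that("NB estimator recovers a known log-ratio in simulation", {
  # true log ratio -1; per-survey NB counts, 15 observations per type
  est <- vapply(1:500, function(seed) {
    sw <- sweepFixture(muDistant = 8, muNearby = 8 * exp(-1), seed = seed,
                       size = 5)
    if (any(tapply(sw$count, sw$plot_type, mean) == 0)) return(NA_real_)
    suppressWarnings(fitSpeciesAbundanceGlm(sw, "X"))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) + 1), 0.05)
})

test_that("Gaussian change models reproduce closed-form least squares", {
  set.seed(11)
  tab <- data.frame(
    bee_species = sprintf("s%02d", 1:15),
    relative_change = runif(15), pac_d = runif(15, 0, 0.5),
    pac_c = runif(15, 0, 0.5), abundance_distant = rlnorm(15, 2, 0.7))
  fit <- fitChangeModel(tab, "interaction")
  X <- model.matrix(~ abundance_distant * pac_d, tab)
  beta <- solve(crossprod(X), crossprod(X, tab$relative_change))
  expect_lt(max(abs(fit$coefficients$estimate - beta)), 1e-8)
  expect_identical(fit$df_residual, 11L)

  # noiseless linear signal is recovered exactly
  tab$relative_change <- 2 * tab$pac_d
  f2 <- suppressWarnings(fitChangeModel(tab, "pac_d"))
  expect_equal(f2$coefficients$estimate[2], 2)
  expect_equal(f2$adj_r_squared, 1)
})

test_that("species without PAC_C drop out of the PAC_C model only", {
  set.seed(3)
  tab <- data.frame(
    bee_species = sprintf("s%02d", 1:15),
    relative_change = runif(15), pac_d = runif(15),
    pac_c = c(rep(NA, 5), runif(10)), abundance_distant = rlnorm(15))
  expect_identical(fitChangeModel(tab, "pac_c")$n, 10L)
  expect_identical(fitChangeModel(tab, "pac_d")$n, 15L)
  tab$pac_d <- 0.3
  expect_error(fitChangeModel(tab, "pac_d"), "constant predictor")
})

test_that("the change-model test is calibrated under the null", {
  set.seed(99)
  hits <- vapply(1:1000, function(i) {
    tab <- data.frame(relative_change = rnorm(15), pac_d = runif(15))
    fitChangeModel(tab, "pac_d")$coefficients$p[2] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.025)
  expect_lt(mean(hits), 0.08)
})

test_that("abundance summaries classify rarity and loss as defined", {
  sw <- rbind(
    sweepFixture(10, 6, species = "Common", seed = 1),
    sweepFixture(0.4, 0, species = "Rare", seed = 2))
  # pin the rare species at 3 distant individuals in total, none nearby
  sw$count[sw$bee_species == "Rare"] <- 0L
  sw$count[sw$bee_species == "Rare" & sw$plot_type == "distant"][1:3] <- 1L
  ab <- abundanceChange(sw)
  expect_identical(ab$bee_species, c("Common", "Rare"))
  expect_true(ab$rare[ab$bee_species == "Rare"])
  expect_false(ab$rare[ab$bee_species == "Common"])
  expect_true(ab$lost[ab$bee_species == "Rare"])
  expect_identical(ab$relative_change[ab$bee_species == "Rare"], 1)
  # mean per-plot-per-survey abundance matches a direct computation
  direct <- mean(tapply(
    sw$count[sw$bee_species == "Common" & sw$plot_type == "distant"],
    sw$plot_id[sw$bee_species == "Common" & sw$plot_type == "distant"], mean))
  expect_equal(ab$abundance_distant[ab$bee_species == "Common"], direct)
})
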