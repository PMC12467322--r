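#' Configuration for the synthetic plant-bee community generator
#'
#' Bundles every tunable of [simulateCommunity()] with defaults emulating
#' the field design the pipeline was written for: ~50 flowering plants, 15
#' native bee species plus one introduced honeybee, three plots near
#' apiaries and three distant ones, ten pollen-capture surveys and five
#' sweep-net surveys per plot, a log-normal spread of baseline abundances
#' wide enough to contain both common and rare (<5% relative abundance)
#' species, and a decline in the nearby plots that grows with diet overlap
#' with the honeybee and with rarity.
#'
#' @param nPlants,nNativeBees,nPlotsPerType,nPollenSurveys,nSweepSurveys
#'   community and design sizes.
#' @param preferenceConcentration Dirichlet concentration of each native
#'   bee's diet preferences, centered on the floral abundance shares;
#'   small values give specialized, idiosyncratic diets, large values
#'   broad flower-tracking ones. A scalar is recycled; the default is a
#'   log-spaced gradient from strong specialists to near-generalists, so
#'   true overlap with the honeybee varies widely across species.
#' @param honeybeeGeneralism concentration multiplier for the honeybee's
#'   Dirichlet preference, centered on the floral abundance shares; large
#'   values make the honeybee a broad, flower-tracking generalist.
#' @param declineSlope `beta >= 0`: effect of true diet overlap with the
#'   honeybee on the log decline of nearby abundance.
#' @param rarityPenalty `gamma >= 0`: extra log decline `gamma /
#'   abundance`, so low-abundance species suffer disproportionately.
#' @param baselineMeanlog,baselineSdlog log-normal parameters of the
#'   per-plot per-survey expected sweep count of each native species in
#'   the distant plots.
#' @param nbDispersion negative-binomial size parameter of sweep counts.
#' @param grainMu,grainSize zero-truncated negative-binomial parameters of
#'   the pollen grain count deposited per visited plant; the mean is kept
#'   well above the detection threshold so the >=3-grain rule passes with
#'   high but known probability.
#' @param detectionThreshold grain-count threshold emulating the >=3-grain
#'   interaction rule.
#' @param honeybeeSweepMean expected honeybee sweep count per nearby survey.
#' @param pollenEffort expected pollen-survey captures per plot per unit of
#'   per-survey abundance (ten transect surveys accumulate many captures).
#' @param maxCapturesPerSpecies cap on pollen-load individuals retained per
#'   species per plot (field target: >15 per species where attainable).
#' @param visitRate each captured individual carries pollen of
#'   `1 + Poisson(visitRate)` plant draws from its preference.
#' @param declineForm `"multiplicative"` (log-link consistent, default) or
#'   `"additive"` decline of nearby expected abundance.
#' @param seed integer master seed; fixed seed gives bit-identical output.
#' @return classed list of settings for [simulateCommunity()].
#' @export
simulationConfig <- function(nPlants = 53,
                             nNativeBees = 15,
                             nPlotsPerType = 3,
                             nPollenSurveys = 10,
                             nSweepSurveys = 5,
                             preferenceConcentration = NULL,
                             honeybeeGeneralism = 3,
                             declineSlope = 2,
                             rarityPenalty = 6,
                             baselineMeanlog = log(8),
                             baselineSdlog = 0.9,
                             nbDispersion = 10,
                             grainMu = 8,
                             grainSize = 2,
                             detectionThreshold = 3,
                             honeybeeSweepMean = 50,
                             pollenEffort = 30,
                             maxCapturesPerSpecies = 30,
                             visitRate = 3,
                             declineForm = c("multiplicative", "additive"),
                             seed = 1L) {
  if (is.null(preferenceConcentration))
    preferenceConcentration <- exp(seq(log(0.01), log(8),
                                       length.out = nNativeBees))
  preferenceConcentration <- rep_len(preferenceConcentration, nNativeBees)
  if (any(preferenceConcentration <= 0))
    stop("preferenceConcentration must be positive", call. = FALSE)
  cfg <- list(
    nPlants = nPlants, nNativeBees = nNativeBees,
    nPlotsPerType = nPlotsPerType, nPollenSurveys = nPollenSurveys,
    nSweepSurveys = nSweepSurveys,
    preferenceConcentration = preferenceConcentration,
    honeybeeGeneralism = honeybeeGeneralism,
    declineSlope = declineSlope, rarityPenalty = rarityPenalty,
    baselineMeanlog = baselineMeanlog, baselineSdlog = baselineSdlog,
    nbDispersion = nbDispersion, grainMu = grainMu, grainSize = grainSize,
    detectionThreshold = detectionThreshold,
    honeybeeSweepMean = honeybeeSweepMean, pollenEffort = pollenEffort,
    maxCapturesPerSpecies = maxCapturesPerSpecies, visitRate = visitRate,
    declineForm = match.arg(declineForm), seed = as.integer(seed)
  )
  counts <- c("nPlants", "nNativeBees", "nPlotsPerType", "nPollenSurveys",
              "nSweepSurveys")
  if (any(unlist(cfg[counts]) < 1))
    stop("all design counts must be positive", call. = FALSE)
  if (cfg$declineSlope < 0 || cfg$rarityPenalty < 0)
    stop("declineSlope and rarityPenalty must be >= 0", call. = FALSE)
  if (cfg$grainMu <= 0 || cfg$grainSize <= 0 || cfg$detectionThreshold < 1)
    stop("invalid grain-count settings", call. = FALSE)
  class(cfg) <- "simulationConfig"
  cfg
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# zero-truncated negative binomial via inverse CDF
rztnbinom <- function(n, mu, size) {
  p0 <- stats::dnbinom(0, mu = mu, size = size)
  u <- stats::runif(n, p0, 1)
  stats::qnbinom(u, mu = mu, size = size)
}

#' True niche overlap between two preference vectors
#'
#' Muller's index evaluated directly on the two-species matrix of exact
#' (noise-free) preference probabilities, the ground-truth counterpart of
#' [pairwisePac()] on estimated diet rows and the recovery target for the
#' estimated PAC values.
#'
#' @param preferences,honeybeePreferences non-negative vectors on the same
#'   plant set (need not be normalized).
#' @return overlap in `[0, 1]`; 0.5 for identical preferences, 0 for
#'   disjoint ones.
#' @export
truthOverlap <- function(preferences, honeybeePreferences) {
  p <- preferences
  q <- honeybeePreferences
  if (length(p) != length(q))
    stop("preference vectors must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0) || sum(p) == 0 || sum(q) == 0)
    stop("preferences must be non-negative with positive sum", call. = FALSE)
  p <- p / sum(p)  # equal-abundance footing, as the adjusted matrices have
  q <- q / sum(q)
  keep <- p > 0 | q > 0
  p <- p[keep]
  q <- q[keep]
  sum((p / sum(p)) * (q / (p + q)))
}

#' Simulate a plant-bee community with known ground truth
#'
#' Draws a full synthetic data set with the sampling structure the
#' pipeline expects: a flowering community shared across plots up to small
#' noise, Dirichlet diet preferences (broad and flower-tracking for the
#' honeybee, narrow for natives), log-normal baseline abundances in the
#' distant plots, a nearby decline `exp(-beta * overlap - gamma /
#' abundance)` acting on the expected abundance, negative-binomial
#' sweep-net counts (the honeybee never occurs in distant plots),
#' multinomial pollen loads per captured individual with zero-truncated
#' negative-binomial grain counts (so the >=3-grain detection rule passes
#' with known probability), and quadrat flower counts. The returned truth
#' table records each species' true overlap with the honeybee, expected
#' abundances, and whether the realized sampling lost it from the nearby
#' plots entirely.
#'
#' @param config a [simulationConfig()]; its `seed` fixes all randomness.
#' @return list with `pollen` (pollen-load records), `sweeps` (sweep
#'   counts), `flowers` (flower surveys), `truth` (per-species ground
#'   truth; diet preference matrix in `attr(truth, "preferences")`,
#'   grain-detection probability in `attr(truth, "detection_prob")`), and
#'   the `config`.
#' @export
simulateCommunity <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  cfg <- config
  set.seed(cfg$seed)

  plants <- sprintf("Plant_%02d", seq_len(cfg$nPlants))
  natives <- sprintf("Native_%02d", seq_len(cfg$nNativeBees))
  hb <- "Apis_mellifera"
  plotsN <- sprintf("nearby_%d", seq_len(cfg$nPlotsPerType))
  plotsD <- sprintf("distant_%d", seq_len(cfg$nPlotsPerType))

  # flowering community, shared across plots up to small log-normal noise
  flowerBase <- stats::rlnorm(cfg$nPlants, meanlog = 3, sdlog = 1)
  flowerShare <- flowerBase / sum(flowerBase)

  prefHb <- rdirichlet1(cfg$honeybeeGeneralism * cfg$nPlants * flowerShare)
  prefs <- t(vapply(seq_along(natives), function(i)
    rdirichlet1(cfg$preferenceConcentration[i] * cfg$nPlants * flowerShare),
    numeric(cfg$nPlants)))
  prefMat <- rbind(prefs, matrix(prefHb, 1))
  dimnames(prefMat) <- list(c(natives, hb), plants)

  overlap <- apply(prefs, 1, truthOverlap, honeybeePreferences = prefHb)

  muDistant <- stats::rlnorm(cfg$nNativeBees, cfg$baselineMeanlog,
                             cfg$baselineSdlog)
  decline <- cfg$declineSlope * overlap + cfg$rarityPenalty / muDistant
  muNearby <- if (cfg$declineForm == "multiplicative")
    muDistant * exp(-decline) else pmax(muDistant - decline, 0)

  if (all(cfg$pollenEffort * c(muDistant, muNearby) < 1e-8) &&
      cfg$honeybeeSweepMean <= 0)
    stop("degenerate config: zero expected captures for every species",
         call. = FALSE)

  muOf <- function(sp, type) {
    if (sp == hb) {
      if (type == "nearby") cfg$honeybeeSweepMean else 0
    } else {
      i <- match(sp, natives)
      if (type == "nearby") muNearby[i] else muDistant[i]
    }
  }

  # --- sweep-net counts --------------------------------------------------
  allPlots <- data.frame(
    plot_id = c(plotsN, plotsD),
    plot_type = rep(c("nearby", "distant"), each = cfg$nPlotsPerType),
    stringsAsFactors = FALSE)
  sweeps <- expand.grid(
    bee_species = c(natives, hb), plot_id = allPlots$plot_id,
    survey_round = seq_len(cfg$nSweepSurveys),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sweeps$plot_type <- allPlots$plot_type[match(sweeps$plot_id,
                                               allPlots$plot_id)]
  sweeps <- sweeps[order(sweeps$bee_species, sweeps$plot_id,
                         sweeps$survey_round, method = "radix"), ]
  mu <- mapply(muOf, sweeps$bee_species, sweeps$plot_type)
  sweeps$count <- ifelse(mu > 0,
    stats::rnbinom(nrow(sweeps), mu = mu, size = cfg$nbDispersion), 0L)
  sweeps$count <- as.integer(sweeps$count)
  sweeps <- sweeps[, c("plot_id", "plot_type", "survey_round",
                       "bee_species", "count")]
  rownames(sweeps) <- NULL

  # --- pollen-load records ----------------------------------------------
  recs <- list()
  for (pi in seq_len(nrow(allPlots))) {
    plot <- allPlots$plot_id[pi]
    type <- allPlots$plot_type[pi]
    for (sp in c(natives, hb)) {
      m <- muOf(sp, type)
      if (m <= 0) next
      nAvail <- stats::rpois(1, cfg$pollenEffort * m)
      nCap <- min(nAvail, cfg$maxCapturesPerSpecies)
      if (nCap == 0) next
      pref <- prefMat[sp, ]
      for (ind in seq_len(nCap)) {
        nVisit <- 1L + stats::rpois(1, cfg$visitRate)
        visited <- unique(sample.int(cfg$nPlants, nVisit, replace = TRUE,
                                     prob = pref))
        grains <- rztnbinom(length(visited), cfg$grainMu, cfg$grainSize)
        recs[[length(recs) + 1L]] <- data.frame(
          individual_id = sprintf("%s|%s|%03d", plot, sp, ind),
          bee_species = sp, plot_id = plot, plot_type = type,
          survey_round = sample.int(cfg$nPollenSurveys, 1),
          plant_species = plants[visited],
          grain_count = as.integer(grains),
          stringsAsFactors = FALSE)
      }
    }
  }
  pollen <- do.call(rbind, recs)
  rownames(pollen) <- NULL

  # --- flower surveys ----------------------------------------------------
  plotMod <- matrix(stats::rlnorm(nrow(allPlots) * cfg$nPlants, 0, 0.05),
                    nrow(allPlots), cfg$nPlants)
  fl <- expand.grid(
    plant_species = plants, plot_id = allPlots$plot_id,
    survey_round = seq_len(cfg$nSweepSurveys),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fl$plot_type <- allPlots$plot_type[match(fl$plot_id, allPlots$plot_id)]
  fl <- fl[order(fl$plot_id, fl$survey_round, fl$plant_species,
                 method = "radix"), ]
  muF <- flowerBase[match(fl$plant_species, plants)] *
    plotMod[cbind(match(fl$plot_id, allPlots$plot_id),
                  match(fl$plant_species, plants))]
  fl$flower_count <- as.integer(stats::rnbinom(nrow(fl), mu = muF, size = 20))
  flowers <- fl[, c("plot_id", "plot_type", "survey_round", "plant_species",
                    "flower_count")]
  rownames(flowers) <- NULL

  # --- ground truth ------------------------------------------------------
  nearbySweepTot <- tapply(
    sweeps$count[sweeps$plot_type == "nearby"],
    sweeps$bee_species[sweeps$plot_type == "nearby"], sum)
  nearbyPollen <- table(pollen$bee_species[pollen$plot_type == "nearby"])
  lost <- vapply(natives, function(s) {
    sw <- nearbySweepTot[[s]]
    pl <- if (s %in% names(nearbyPollen)) nearbyPollen[[s]] else 0L
    (is.na(sw) || sw == 0) && pl == 0
  }, TRUE)

  pDetect <- (1 - stats::pnbinom(cfg$detectionThreshold - 1,
                                 mu = cfg$grainMu, size = cfg$grainSize)) /
    (1 - stats::dnbinom(0, mu = cfg$grainMu, size = cfg$grainSize))

  truth <- data.frame(
    bee_species = natives,
    true_overlap = unname(overlap),
    expected_distant = muDistant,
    expected_nearby = muNearby,
    lost = unname(lost),
    row.names = NULL
  )
  attr(truth, "preferences") <- prefMat
  attr(truth, "detection_prob") <- pDetect

  list(pollen = pollen, sweeps = sweeps, flowers = flowers,
       truth = truth, config = cfg)
}
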