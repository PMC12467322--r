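# Independent brute-force oracles, kept deliberately naive (loops, no reuse
# of package internals) so they can arbitrate the vectorized implementations.

# per-individual tally of the grain-threshold rule
bruteTallyNetwork <- function(records, minGrains = 3) {
  hits <- records[records$grain_count >= minGrains, , drop = FALSE]
  bees <- sort(unique(hits$bee_species), method = "radix")
  plants <- sort(unique(hits$plant_species), method = "radix")
  m <- matrix(0L, length(bees), length(plants), dimnames = list(bees, plants))
  for (r in seq_len(nrow(hits))) {
    b <- hits$bee_species[r]; p <- hits$plant_species[r]
    m[b, p] <- m[b, p] + 1L
  }
  m
}

# triple-loop Muller index matrix
mullerLoop <- function(A) {
  n <- nrow(A)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(ncol(A))) {
        if (A[i, k] > 0) {
          acc <- acc + (A[i, k] / sum(A[i, ])) * (A[j, k] / sum(A[, k]))
        }
      }
      d[i, j] <- acc
    }
  }
  d
}

# direct two-row evaluation of the pairwise index, summing term by term;
# rows enter as diet proportions (the equal-abundance two-species matrix)
pacLoop <- function(native, honeybee) {
  p <- native / sum(native)
  q <- honeybee / sum(honeybee)
  tot <- 0
  for (k in seq_along(p)) {
    if (p[k] == 0 && q[k] == 0) next
    tot <- tot + p[k] * (q[k] / (p[k] + q[k]))
  }
  unname(tot)
}

bcLoop <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + min(p[i], q[i])
  1 - 2 * s / (sum(p) + sum(q))
}

# random pollen-load record set spanning one plot
randomRecords <- function(seed, nInd = 200, nBees = 10, nPlants = 20,
                          plot = "p1", type = "nearby") {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nInd)) {
    sp <- sprintf("Bee_%02d", sample.int(nBees, 1))
    plants <- sample.int(nPlants, 1 + rpois(1, 1.5), replace = TRUE)
    for (pl in unique(plants)) {
      rows[[length(rows) + 1L]] <- data.frame(
        individual_id = sprintf("i%04d", i), bee_species = sp,
        plot_id = plot, plot_type = type, survey_round = sample.int(10, 1),
        plant_species = sprintf("Plant_%02d", pl),
        grain_count = rpois(1, 4))
    }
  }
  do.call(rbind, rows)
}

# tiny deterministic record builder
rec <- function(ind, bee, plant, grains, plot = "p1", type = "nearby",
                round = 1L) {
  data.frame(individual_id = ind, bee_species = bee, plot_id = plot,
             plot_type = type, survey_round = round, plant_species = plant,
             grain_count = grains, stringsAsFactors = FALSE)
}

# balanced two-type sweep table from per-type means
sweepFixture <- function(muDistant, muNearby, species = "X", seed = 1,
                         size = 10, nPlots = 3, nSurveys = 5) {
  set.seed(seed)
  g <- expand.grid(
    plot_id = c(sprintf("n%d", 1:nPlots), sprintf("d%d", 1:nPlots)),
    survey_round = seq_len(nSurveys), bee_species = species,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$plot_type <- ifelse(grepl("^n", g$plot_id), "nearby", "distant")
  mu <- ifelse(g$plot_type == "nearby", muNearby, muDistant)
  g$count <- as.integer(rnbinom(nrow(g), mu = mu, size = size))
  g[, c("plot_id", "plot_type", "survey_round", "bee_species", "count")]
}
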