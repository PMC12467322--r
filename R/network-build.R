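#' Build a quantitative pollen-transport network for one plot
#'
#' Turns individual pollen-load records into a bee-by-plant interaction
#' matrix. A bee individual counts as interacting with a plant when it
#' carried at least `minGrains` grains of that plant's pollen morphotype
#' (default 3, a deliberately permissive detection rule for plants that
#' deposit few grains per visitor). Entry \eqn{(x, y)} is the number of
#' distinct individuals of bee species \eqn{x} with a qualifying load of
#' plant \eqn{y}. Bee and plant species left without any interaction
#' partner are removed. The per-species specimen count records *all*
#' distinct captured individuals of each retained species, including those
#' whose loads all fell below the threshold, because every captured
#' individual was involved in constructing the network and the specimen
#' count is later used as the abundance divisor.
#'
#' @param records data.frame of pollen-load records for a single plot with
#'   columns `individual_id`, `bee_species`, `plot_id`, `plot_type`,
#'   `survey_round`, `plant_species`, `grain_count` (one row per captured
#'   individual and pollen morphotype).
#' @param minGrains minimum grain count for a load to count as an
#'   interaction; must be >= 1.
#' @return an [InteractionMatrix-class].
#' @examples
#' rec <- data.frame(
#'   individual_id = c("b1", "b1", "b2", "b3"),
#'   bee_species = c("B1", "B1", "B1", "B2"),
#'   plot_id = "p1", plot_type = "nearby", survey_round = 1L,
#'   plant_species = c("P1", "P2", "P1", "P1"),
#'   grain_count = c(5L, 3L, 2L, 4L)
#' )
#' net <- buildNetwork(rec)
#' interactionCounts(net)
#' specimens(net)
#' @export
buildNetwork <- function(records, minGrains = 3L) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("cannot build a network from an empty record set", call. = FALSE)
  stopIfMissingCols(records, c(
    "individual_id", "bee_species", "plot_id", "plot_type",
    "survey_round", "plant_species", "grain_count"
  ), "pollen-load records")
  if (length(minGrains) != 1L || is.na(minGrains) || minGrains < 1)
    stop("minGrains must be a single integer >= 1", call. = FALSE)

  plots <- unique(as.character(records$plot_id))
  if (length(plots) != 1L)
    stop("records must belong to a single plot; got: ",
         paste(plots, collapse = ", "), call. = FALSE)
  types <- unique(as.character(records$plot_type))
  if (length(types) != 1L)
    stop("plot_type must be consistent within a plot", call. = FALSE)

  if (any(is.na(records$grain_count)) || any(records$grain_count < 0))
    stop("grain_count must be a non-negative integer", call. = FALSE)

  # morphotypes that could not be matched to the pollen library have no
  # column in the network; drop them but keep the individual as a specimen
  unknown <- is.na(records$plant_species) | records$plant_species == ""
  specimenSource <- records
  if (any(unknown)) {
    warning(sprintf("dropped %d record(s) with unknown pollen morphotype",
                    sum(unknown)), call. = FALSE)
    records <- records[!unknown, , drop = FALSE]
  }

  key <- paste(specimenSource$individual_id, specimenSource$plant_species,
               sep = "\r")
  if (anyDuplicated(key[!unknown]))
    stop("duplicate (individual_id, plant_species) records", call. = FALSE)

  # specimens: all distinct captured individuals per species, threshold or not
  ind <- !duplicated(specimenSource$individual_id)
  specCount <- table(as.character(specimenSource$bee_species[ind]))

  hits <- records[records$grain_count >= minGrains, , drop = FALSE]
  if (nrow(hits) == 0L)
    stop(sprintf(
      "empty network: no pollen load reaches the %d-grain detection threshold",
      as.integer(minGrains)), call. = FALSE)

  bees <- sortLabels(hits$bee_species)
  plants <- sortLabels(hits$plant_species)
  counts <- matrix(0L, length(bees), length(plants),
                   dimnames = list(bees, plants))
  tab <- table(factor(hits$bee_species, bees),
               factor(hits$plant_species, plants))
  counts[] <- as.integer(tab)

  spec <- stats::setNames(as.numeric(specCount[bees]), bees)

  methods::new("InteractionMatrix",
    counts = counts, specimens = spec,
    plotId = plots, plotType = types
  )
}

#' Keep per-plot networks or pool them by plot type
#'
#' The per-plot mode is the analysis default (one network per plot,
#' pollen surveys already combined within the plot). Pooling sums the
#' interaction counts and specimen counts across all plots of a type and
#' re-applies the zero-row/column removal, which is occasionally useful as
#' a sensitivity check on the per-plot PAC aggregation.
#'
#' @param nets list of [InteractionMatrix-class] objects.
#' @param mode `"per_plot"` (identity) or `"pooled_by_type"`.
#' @return list of `InteractionMatrix` (one per plot, or one per plot type).
#' @export
poolNetworks <- function(nets, mode = c("per_plot", "pooled_by_type")) {
  mode <- match.arg(mode)
  if (!length(nets) || !all(vapply(nets, methods::is, TRUE, "InteractionMatrix")))
    stop("nets must be a non-empty list of InteractionMatrix objects",
         call. = FALSE)
  if (mode == "per_plot") return(nets)

  types <- vapply(nets, plotType, character(1))
  if (anyNA(types)) stop("cannot pool networks of unknown plot type", call. = FALSE)
  out <- lapply(sortLabels(types), function(tp) {
    grp <- nets[types == tp]
    bees <- sortLabels(unlist(lapply(grp, beeSpecies)))
    plants <- sortLabels(unlist(lapply(grp, plantSpecies)))
    counts <- matrix(0, length(bees), length(plants),
                     dimnames = list(bees, plants))
    spec <- stats::setNames(numeric(length(bees)), bees)
    for (g in grp) {
      counts[beeSpecies(g), plantSpecies(g)] <-
        counts[beeSpecies(g), plantSpecies(g)] + interactionCounts(g)
      spec[beeSpecies(g)] <- spec[beeSpecies(g)] + specimens(g)
    }
    keepR <- rowSums(counts) > 0
    keepC <- colSums(counts) > 0
    methods::new("InteractionMatrix",
      counts = counts[keepR, keepC, drop = FALSE],
      specimens = spec[keepR],
      plotId = paste0("pooled:", tp), plotType = tp
    )
  })
  out
}
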