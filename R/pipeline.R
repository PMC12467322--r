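#' Configuration of the end-to-end analysis pipeline
#'
#' Collects every choice of the pipeline with defaults reproducing the
#' intended analysis: a 3-grain detection threshold, per-plot networks,
#' a pooled honeybee row, PAC averaged over plots, relative change with
#' decline positive, per-survey replication for the negative-binomial
#' abundance models, survey blocks of two for the diet profiles, and 999
#' PERMANOVA permutations. Either file paths or in-memory data frames can
#' be supplied; [simulateCommunity()] output plugs in directly.
#'
#' @param pollen,sweeps,flowers data.frames, or paths to the corresponding
#'   CSVs.
#' @param outDir output directory; `NULL` suppresses file output.
#' @param minGrains detection threshold for interactions.
#' @param honeybeeSpecies honeybee row label.
#' @param honeybeeMode `"pooled"` or `"mean"` honeybee row reduction.
#' @param abundanceStat `"mean"` or `"sum"` per-plot abundance summary.
#' @param replicationUnit `"survey"` or `"plot"` for the NB models.
#' @param dietBlockSize consecutive pollen surveys per diet sample block.
#' @param nPerm PERMANOVA permutations.
#' @param seed master seed; stage seeds are derived from it.
#' @return classed configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(pollen, sweeps, flowers = NULL, outDir = NULL,
                           minGrains = 3L,
                           honeybeeSpecies = "Apis_mellifera",
                           honeybeeMode = c("pooled", "mean"),
                           abundanceStat = c("mean", "sum"),
                           replicationUnit = c("survey", "plot"),
                           dietBlockSize = 2L,
                           nPerm = 999L,
                           seed = 1L) {
  structure(list(
    pollen = pollen, sweeps = sweeps, flowers = flowers, outDir = outDir,
    minGrains = as.integer(minGrains),
    honeybeeSpecies = honeybeeSpecies,
    honeybeeMode = match.arg(honeybeeMode),
    abundanceStat = match.arg(abundanceStat),
    replicationUnit = match.arg(replicationUnit),
    dietBlockSize = as.integer(dietBlockSize),
    nPerm = as.integer(nPerm),
    seed = as.integer(seed)
  ), class = "pipelineConfig")
}

resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full analysis pipeline
#'
#' Executes the whole analysis on one set of inputs: per-plot
#' pollen-transport networks, the honeybee profile and PAC table,
#' per-species abundance summaries and negative-binomial models, the four
#' Gaussian relative-change regressions, diet-niche-shift tests for the
#' common species, and (when flower surveys are supplied) the
#' flowering-community similarity check. When `outDir` is set, every table
#' is written as CSV together with a JSON run manifest (configuration,
#' seed, package version, file checksums); reruns with the same inputs and
#' seed are bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @return list bundle with elements `networks`, `honeybee`, `pac`,
#'   `abundance`, `species_glms`, `change_models`, `diet`, `flowers`,
#'   `manifest`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  pollen <- resolveInput(config$pollen, readPollenRecords)
  sweeps <- resolveInput(config$sweeps, readSweepCounts)
  flowers <- if (!is.null(config$flowers))
    resolveInput(config$flowers, readFlowerSurveys) else NULL

  nets <- stage("network_build",
                buildPlotNetworks(pollen, config$minGrains))
  types <- vapply(nets, plotType, character(1))
  nearby <- nets[types == "nearby"]
  distant <- nets[types == "distant"]

  hbProfile <- stage("honeybee_profile",
    honeybeeProfile(nearby, config$honeybeeSpecies, config$honeybeeMode))
  pac <- stage("niche_overlap",
    pacTable(nearby, distant, hbProfile, config$honeybeeSpecies))

  abund <- stage("abundance_change", suppressWarnings(
    abundanceChange(sweeps, stat = config$abundanceStat,
                    exclude = config$honeybeeSpecies)))

  glms <- stage("species_glms", {
    fits <- lapply(abund$bee_species, function(sp)
      tryCatch(
        suppressWarnings(
          fitSpeciesAbundanceGlm(sweeps, sp, unit = config$replicationUnit)),
        error = function(e) NULL))
    names(fits) <- abund$bee_species
    fits[!vapply(fits, is.null, TRUE)]
  })

  joined <- merge(abund, pac, by = "bee_species", all.x = TRUE)
  changeModels <- stage("change_models", {
    out <- list()
    for (m in c("pac_d", "pac_c", "abundance", "interaction")) {
      out[[m]] <- tryCatch(fitChangeModel(joined, m),
                           error = function(e) NULL)
    }
    out[!vapply(out, is.null, TRUE)]
  })

  common <- abund$bee_species[!abund$rare]
  diet <- stage("niche_shift", {
    if (length(common)) {
      profs <- suppressMessages(
        dietProfiles(pollen, common, blockSize = config$dietBlockSize,
                     minGrains = config$minGrains))
      nicheShiftTest(profs, nPerm = config$nPerm, seed = config$seed + 1L)
    } else NULL
  })

  flowerRes <- if (!is.null(flowers))
    stage("flower_similarity",
          flowerSimilarity(flowers, nPerm = config$nPerm,
                           seed = config$seed + 2L)) else NULL

  glmTable <- do.call(rbind, lapply(glms, function(f) data.frame(
    bee_species = f$species, estimate = f$estimate, se = f$se, p = f$p,
    theta = f$theta, df_residual = f$df_residual, boundary = f$boundary)))
  changeTable <- do.call(rbind, lapply(names(changeModels), function(m) {
    co <- changeModels[[m]]$coefficients
    data.frame(model = m, co,
               df_residual = changeModels[[m]]$df_residual,
               adj_r_squared = changeModels[[m]]$adj_r_squared,
               n = changeModels[[m]]$n)
  }))

  manifest <- list(
    package = "pacnet",
    version = as.character(utils::packageVersion("pacnet")),
    seed = config$seed,
    settings = config[c("minGrains", "honeybeeSpecies", "honeybeeMode",
                        "abundanceStat", "replicationUnit", "dietBlockSize",
                        "nPerm")],
    n_pollen_records = nrow(pollen),
    n_sweep_records = nrow(sweeps),
    networks = lapply(nets, function(n) list(
      plot = plotId(n), type = plotType(n),
      bees = nrow(interactionCounts(n)),
      plants = ncol(interactionCounts(n)),
      links = sum(interactionCounts(n) > 0)))
  )

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outDir
    for (n in nets)
      writeNetwork(n, file.path(od, paste0("network_", plotId(n), ".csv")))
    utils::write.csv(pac, file.path(od, "pac_table.csv"), row.names = FALSE)
    utils::write.csv(abund, file.path(od, "abundance_change.csv"),
                     row.names = FALSE)
    if (!is.null(glmTable))
      utils::write.csv(glmTable, file.path(od, "species_glms.csv"),
                       row.names = FALSE)
    if (!is.null(changeTable))
      utils::write.csv(changeTable, file.path(od, "change_models.csv"),
                       row.names = FALSE)
    if (!is.null(diet))
      utils::write.csv(diet$tests, file.path(od, "niche_shift.csv"),
                       row.names = FALSE)
    files <- list.files(od, pattern = "\\.csv$", full.names = TRUE)
    manifest$checksums <- as.list(tools::md5sum(files))
    names(manifest$checksums) <- basename(files)
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  list(networks = nets, honeybee = hbProfile, pac = pac,
       abundance = abund, species_glms = glms, species_glm_table = glmTable,
       change_models = changeModels, change_model_table = changeTable,
       diet = diet, flowers = flowerRes, manifest = manifest)
}
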