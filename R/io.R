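pollenCols <- c("individual_id", "bee_species", "plot_id", "plot_type",
                "survey_round", "plant_species", "grain_count")
sweepCols <- c("plot_id", "plot_type", "survey_round", "bee_species", "count")
flowerCols <- c("plot_id", "plot_type", "survey_round", "plant_species",
                "flower_count")

readTable <- function(path, cols, what, intCols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  stopIfMissingCols(df, cols, what)
  df <- df[, cols, drop = FALSE]
  for (cc in intCols) {
    v <- df[[cc]]
    if (any(is.na(v)) || any(v != round(v)) || any(v < 0))
      stop(what, ": column '", cc, "' must hold non-negative integers",
           call. = FALSE)
    df[[cc]] <- as.integer(v)
  }
  df
}

#' Read and validate the pipeline's input tables
#'
#' Strict CSV readers for the three input streams: individual pollen-load
#' records, sweep-net counts, and quadrat flower surveys. Each checks the
#' header (errors name the missing column), coerces and validates count
#' columns, and rejects structurally inconsistent rows (duplicate
#' individual-plant pairs, plots with conflicting types).
#'
#' @param path CSV file path (UTF-8, header row required).
#' @return validated data.frame with exactly the schema columns.
#' @export
readPollenRecords <- function(path) {
  df <- readTable(path, pollenCols, "pollen-load records",
                  c("survey_round", "grain_count"))
  key <- paste(df$individual_id, df$plant_species, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop("duplicate (individual_id, plant_species) record at row ", dup,
         call. = FALSE)
  }
  byPlot <- unique(df[, c("plot_id", "plot_type")])
  if (anyDuplicated(byPlot$plot_id))
    stop("plot_type is inconsistent within a plot", call. = FALSE)
  df
}

#' @rdname readPollenRecords
#' @export
readSweepCounts <- function(path) {
  df <- readTable(path, sweepCols, "sweep counts", c("survey_round", "count"))
  byPlot <- unique(df[, c("plot_id", "plot_type")])
  if (anyDuplicated(byPlot$plot_id))
    stop("plot_type is inconsistent within a plot", call. = FALSE)
  df
}

#' @rdname readPollenRecords
#' @export
readFlowerSurveys <- function(path) {
  readTable(path, flowerCols, "flower surveys",
            c("survey_round", "flower_count"))
}

#' Write a network to CSV (matrix plus specimen sidecar)
#'
#' Serializes an [InteractionMatrix-class] as a labelled matrix CSV (first
#' column the bee species, header the plant species) and a sidecar CSV of
#' specimens per bee species next to it (`<stem>_specimens.csv`).
#'
#' @param net an [InteractionMatrix-class].
#' @param path output CSV path for the matrix.
#' @return invisibly, the two file paths written.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(methods::is(net, "InteractionMatrix"))
  m <- interactionCounts(net)
  df <- data.frame(bee_species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.csv$", "_specimens.csv", path)
  utils::write.csv(
    data.frame(bee_species = names(specimens(net)),
               specimens = unname(specimens(net))),
    sidecar, row.names = FALSE)
  invisible(c(path, sidecar))
}

#' Split records by plot and build one network per plot
#'
#' @param records pollen-load records spanning several plots.
#' @param minGrains detection threshold (see [buildNetwork()]).
#' @return named list of [InteractionMatrix-class], one per plot.
#' @export
buildPlotNetworks <- function(records, minGrains = 3L) {
  plots <- sortLabels(records$plot_id)
  out <- lapply(plots, function(p)
    buildNetwork(records[records$plot_id == p, , drop = FALSE], minGrains))
  names(out) <- plots
  out
}
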