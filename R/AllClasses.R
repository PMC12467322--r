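#' @import methods
NULL

#' Quantitative pollen-transport network for one plot
#'
#' An `InteractionMatrix` holds a bee-by-plant matrix whose entry \eqn{(x, y)}
#' counts the individual bees of species \eqn{x} found carrying pollen of
#' plant \eqn{y} at or above the grain-count detection threshold, together
#' with the number of specimens of each bee species that went into building
#' the network (including individuals that contributed no interaction).
#' Rows and columns with no interaction are removed at construction; labels
#' are sorted lexicographically for deterministic serialization.
#'
#' @slot counts non-negative integer matrix, bee species in rows, plant
#'   species (pollen morphotypes) in columns.
#' @slot specimens named numeric vector, one entry per retained bee species:
#'   the number of distinct captured individuals used to construct the
#'   network. Always `specimens[x] >= max(counts[x, ])`.
#' @slot plotId single plot label ("pooled:<type>" for pooled networks).
#' @slot plotType `"nearby"` or `"distant"`.
#'
#' @seealso [buildNetwork()], [poolNetworks()], [adjustMatrix()]
#' @export
setClass("InteractionMatrix",
  representation(
    counts = "matrix",
    specimens = "numeric",
    plotId = "character",
    plotType = "character"
  )
)

setValidity("InteractionMatrix", function(object) {
  m <- object@counts
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "counts must have bee species row names and plant column names")
  if (any(m < 0) || any(m != round(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (nrow(m) > 0 && any(rowSums(m) == 0))
    msg <- c(msg, "all-zero bee rows must be removed")
  if (ncol(m) > 0 && any(colSums(m) == 0))
    msg <- c(msg, "all-zero plant columns must be removed")
  if (!identical(names(object@specimens), rownames(m)))
    msg <- c(msg, "specimens must be named exactly by the bee species rows")
  if (any(object@specimens < 1))
    msg <- c(msg, "every retained bee species needs at least one specimen")
  if (nrow(m) > 0 && any(m > object@specimens[rownames(m)]))
    msg <- c(msg, "counts cannot exceed the number of specimens of the species")
  if (length(object@plotId) != 1L)
    msg <- c(msg, "plotId must be a single label")
  if (length(object@plotType) != 1L ||
      !object@plotType %in% c("nearby", "distant"))
    msg <- c(msg, "plotType must be 'nearby' or 'distant'")
  if (length(msg)) msg else TRUE
})

#' Abundance-adjusted interaction matrix
#'
#' Same shape and labels as the [InteractionMatrix-class] it was derived
#' from, but with every interaction count divided by the number of
#' specimens of the bee species, \eqn{N_{xy} = P_{xy} / A_x}, so that
#' Muller's index is no longer driven by the relative abundance of the
#' competing species. When a honeybee profile is injected, its row uses
#' the profile's cross-plot average specimen count as divisor and is
#' identical in every network.
#'
#' @slot values non-negative numeric matrix of adjusted interaction
#'   strengths.
#' @slot divisors named numeric vector: the per-row specimen counts that
#'   were divided out.
#' @slot plotId,plotType as in [InteractionMatrix-class].
#' @export
setClass("AdjustedMatrix",
  representation(
    values = "matrix",
    divisors = "numeric",
    plotId = "character",
    plotType = "character"
  )
)

setValidity("AdjustedMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry bee and plant labels")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "adjusted values must be finite and non-negative")
  if (!identical(names(object@divisors), rownames(v)))
    msg <- c(msg, "divisors must be named exactly by the bee species rows")
  if (any(object@divisors <= 0))
    msg <- c(msg, "divisors must be positive")
  if (length(msg)) msg else TRUE
})

#' Honeybee interaction profile shared across networks
#'
#' The introduced honeybee forages from fixed apiaries, so its
#' plant-interaction row is taken from the plots near the apiaries and
#' treated as the same in every network: `row` holds the interaction counts
#' \eqn{P_{hb,y}} (pooled, or averaged, over the nearby-plot networks) and
#' `aHb` the average number of honeybee specimens used to construct those
#' networks. The profile is injected into distant-plot networks, where the
#' honeybee itself was never captured.
#'
#' @slot species honeybee taxon label.
#' @slot row named numeric vector of interaction counts per plant.
#' @slot aHb positive scalar, mean specimen count across nearby networks.
#' @slot mode `"pooled"` or `"mean"`: how `row` was reduced across plots.
#' @export
setClass("HoneybeeProfile",
  representation(
    species = "character",
    row = "numeric",
    aHb = "numeric",
    mode = "character"
  )
)

setValidity("HoneybeeProfile", function(object) {
  msg <- character()
  if (length(object@species) != 1L)
    msg <- c(msg, "species must be a single label")
  if (is.null(names(object@row)) || !any(object@row > 0))
    msg <- c(msg, "row must be plant-named with at least one positive entry")
  if (length(object@aHb) != 1L || !is.finite(object@aHb) || object@aHb <= 0)
    msg <- c(msg, "aHb must be a positive scalar")
  if (!object@mode %in% c("pooled", "mean"))
    msg <- c(msg, "mode must be 'pooled' or 'mean'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf(
    "InteractionMatrix: plot %s (%s), %d bee species x %d plants, %d interaction links\n",
    object@plotId, object@plotType, nrow(object@counts), ncol(object@counts),
    sum(object@counts > 0)
  ))
  cat(sprintf("  specimens: %s\n", paste0(
    names(object@specimens), "=", object@specimens, collapse = ", "
  )))
})

setMethod("show", "AdjustedMatrix", function(object) {
  cat(sprintf(
    "AdjustedMatrix: plot %s (%s), %d bee species x %d plants\n",
    object@plotId, object@plotType, nrow(object@values), ncol(object@values)
  ))
})

setMethod("show", "HoneybeeProfile", function(object) {
  cat(sprintf(
    "HoneybeeProfile: %s, %d plants (%d used), aHb = %.3g, %s row\n",
    object@species, length(object@row), sum(object@row > 0), object@aHb,
    object@mode
  ))
})
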