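#' Accessors for network objects
#'
#' @param x an [InteractionMatrix-class] or [AdjustedMatrix-class].
#' @return `interactionCounts()` / `adjustedValues()` return the labelled
#'   matrix; `specimens()` the named per-bee specimen counts (for an
#'   `AdjustedMatrix`, the divisors that were applied); `plotId()` and
#'   `plotType()` the plot metadata; `beeSpecies()` and `plantSpecies()`
#'   the row and column labels.
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
setGeneric("interactionCounts", function(x) standardGeneric("interactionCounts"))
#' @rdname network-accessors
#' @export
setGeneric("adjustedValues", function(x) standardGeneric("adjustedValues"))
#' @rdname network-accessors
#' @export
setGeneric("specimens", function(x) standardGeneric("specimens"))
#' @rdname network-accessors
#' @export
setGeneric("plotId", function(x) standardGeneric("plotId"))
#' @rdname network-accessors
#' @export
setGeneric("plotType", function(x) standardGeneric("plotType"))
#' @rdname network-accessors
#' @export
setGeneric("beeSpecies", function(x) standardGeneric("beeSpecies"))
#' @rdname network-accessors
#' @export
setGeneric("plantSpecies", function(x) standardGeneric("plantSpecies"))

#' @rdname network-accessors
#' @export
setMethod("interactionCounts", "InteractionMatrix", function(x) x@counts)
#' @rdname network-accessors
#' @export
setMethod("adjustedValues", "AdjustedMatrix", function(x) x@values)
#' @rdname network-accessors
#' @export
setMethod("specimens", "InteractionMatrix", function(x) x@specimens)
#' @rdname network-accessors
#' @export
setMethod("specimens", "AdjustedMatrix", function(x) x@divisors)

#' @rdname network-accessors
#' @export
setMethod("plotId", "InteractionMatrix", function(x) x@plotId)
#' @rdname network-accessors
#' @export
setMethod("plotId", "AdjustedMatrix", function(x) x@plotId)
#' @rdname network-accessors
#' @export
setMethod("plotType", "InteractionMatrix", function(x) x@plotType)
#' @rdname network-accessors
#' @export
setMethod("plotType", "AdjustedMatrix", function(x) x@plotType)

#' @rdname network-accessors
#' @export
setMethod("beeSpecies", "InteractionMatrix", function(x) rownames(x@counts))
#' @rdname network-accessors
#' @export
setMethod("beeSpecies", "AdjustedMatrix", function(x) rownames(x@values))
#' @rdname network-accessors
#' @export
setMethod("plantSpecies", "InteractionMatrix", function(x) colnames(x@counts))
#' @rdname network-accessors
#' @export
setMethod("plantSpecies", "AdjustedMatrix", function(x) colnames(x@values))
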