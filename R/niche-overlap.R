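#' Derive the honeybee's shared interaction profile from nearby networks
#'
#' The introduced honeybee is only captured in the plots near the apiaries,
#' yet its perceived apparent competition with each native bee must be
#' evaluated in every plot. Its interaction row \eqn{P_{hb,y}} is therefore
#' reduced across the nearby networks (pooled sum by default, arithmetic
#' mean as an alternative) and its abundance divisor \eqn{a_{hb}} is the
#' average number of honeybee specimens used to construct those networks.
#' The resulting profile is identical in all networks it is injected into.
#'
#' @param nearbyNets list of nearby-plot [InteractionMatrix-class] objects.
#' @param species honeybee row label.
#' @param mode `"pooled"` (sum of the per-plot rows, default) or `"mean"`.
#' @return a [HoneybeeProfile-class].
#' @export
honeybeeProfile <- function(nearbyNets, species = "Apis_mellifera",
                            mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  has <- vapply(nearbyNets, function(n) species %in% beeSpecies(n), TRUE)
  if (!any(has))
    stop(sprintf("'%s' is absent from every nearby network", species),
         call. = FALSE)
  nets <- nearbyNets[has]
  plants <- sortLabels(unlist(lapply(nets, plantSpecies)))
  rows <- vapply(nets, function(n)
    alignTo(interactionCounts(n)[species, ], plants), numeric(length(plants)))
  rows <- matrix(rows, nrow = length(plants),
                 dimnames = list(plants, NULL))
  row <- if (mode == "pooled") rowSums(rows) else rowMeans(rows)
  aHb <- mean(vapply(nets, function(n) specimens(n)[[species]], numeric(1)))
  methods::new("HoneybeeProfile",
    species = species, row = row, aHb = aHb, mode = mode)
}

#' Abundance-adjust an interaction matrix
#'
#' Divides every interaction count by the number of specimens of the bee
#' species that built the network, \eqn{N_{xy} = P_{xy} / A_x}, removing
#' the dependence of Muller's index on the relative abundance of the
#' competing species. When a [HoneybeeProfile-class] is supplied, any
#' honeybee row already present is replaced by (and otherwise the profile
#' is injected as) the shared row `profile@row / profile@aHb`; plants used
#' only by the honeybee are added as extra columns.
#'
#' @param net an [InteractionMatrix-class].
#' @param honeybee optional [HoneybeeProfile-class] to inject.
#' @return an [AdjustedMatrix-class].
#' @export
adjustMatrix <- function(net, honeybee = NULL) {
  stopifnot(methods::is(net, "InteractionMatrix"))
  P <- interactionCounts(net)
  A <- specimens(net)
  if (any(A <= 0))
    stop("zero specimen count for: ",
         paste(names(A)[A <= 0], collapse = ", "), call. = FALSE)
  if (!is.null(honeybee)) {
    stopifnot(methods::is(honeybee, "HoneybeeProfile"))
    keep <- setdiff(rownames(P), honeybee@species)
    P <- P[keep, , drop = FALSE]
    A <- A[keep]
  }
  N <- P / A
  if (!is.null(honeybee)) {
    plants <- sortLabels(c(colnames(N), names(honeybee@row)))
    M <- matrix(0, nrow(N) + 1L, length(plants),
                dimnames = list(c(rownames(N), honeybee@species), plants))
    M[rownames(N), colnames(N)] <- N
    M[honeybee@species, ] <- alignTo(honeybee@row, plants) / honeybee@aHb
    ord <- sortLabels(rownames(M))
    N <- M[ord, , drop = FALSE]
    A <- c(A, stats::setNames(honeybee@aHb, honeybee@species))[ord]
  }
  methods::new("AdjustedMatrix",
    values = N, divisors = A,
    plotId = plotId(net), plotType = plotType(net))
}

#' Muller's index of perceived apparent competition
#'
#' For a quantitative consumer-by-resource matrix with entries
#' \eqn{\alpha_{ik}}, Muller's index for focal consumer \eqn{i} against
#' competitor \eqn{j} is
#' \deqn{d_{ij} = \sum_k \frac{\alpha_{ik}}{\sum_l \alpha_{il}} \cdot
#'               \frac{\alpha_{jk}}{\sum_m \alpha_{mk}},}
#' the share of \eqn{i}'s resource use that flows through resources, times
#' the share of each resource's use taken by \eqn{j}. Rows of the full
#' index matrix sum to one over all consumers (the focal row included).
#'
#' `mullerMatrix()` returns the complete index matrix; `mullerIndex()` a
#' single \eqn{d_{ij}}.
#'
#' @param M an [AdjustedMatrix-class], [InteractionMatrix-class] or plain
#'   non-negative matrix with consumer rows.
#' @param i,j consumer row labels or indices (focal `i`, competitor `j`).
#' @return `mullerMatrix()`: square matrix `d` with `d[i, j]` as above;
#'   `mullerIndex()`: a single number in `[0, 1]`.
#' @export
mullerMatrix <- function(M) {
  A <- asAlphaMatrix(M)
  rs <- rowSums(A)
  if (any(rs == 0))
    stop("Muller's index is undefined for all-zero consumer rows: ",
         paste(rownames(A)[rs == 0], collapse = ", "), call. = FALSE)
  cs <- colSums(A)
  colShare <- A / rep(cs, each = nrow(A))
  colShare[, cs == 0] <- 0  # columns nobody uses contribute nothing
  d <- (A / rs) %*% t(colShare)
  dimnames(d) <- list(rownames(A), rownames(A))
  d
}

#' @rdname mullerMatrix
#' @export
mullerIndex <- function(M, i, j) {
  mullerMatrix(M)[i, j]
}

asAlphaMatrix <- function(M) {
  if (methods::is(M, "AdjustedMatrix")) return(adjustedValues(M))
  if (methods::is(M, "InteractionMatrix")) return(interactionCounts(M))
  if (is.matrix(M) && is.numeric(M)) {
    if (any(M < 0)) stop("interaction strengths must be non-negative",
                         call. = FALSE)
    return(M)
  }
  stop("M must be a matrix, InteractionMatrix or AdjustedMatrix", call. = FALSE)
}

#' Pairwise PAC between one native bee and the honeybee
#'
#' Builds the two-species network containing only the (already
#' abundance-adjusted) native row and honeybee row, restricted to plants
#' used by at least one of the two, and evaluates Muller's index on it.
#' The headline value is \eqn{d_{\mathrm{native} \to \mathrm{honeybee}}}:
#' the share of the native bee's resource use recaptured through plants the
#' honeybee also exploits. Each row of the two-species matrix is first
#' reduced to diet proportions (the abundance adjustment taken to its
#' equal-abundance limit), so the value depends only on how the two bees
#' spread their visits and is invariant to rescaling either row by a
#' positive constant. Identical profiles give exactly 0.5 (every plant is
#' split half-and-half); disjoint profiles give 0.
#'
#' @param nativeRow,honeybeeRow plant-named, abundance-adjusted interaction
#'   vectors on a common plant set (names are matched when present).
#' @param direction `"native_to_honeybee"` (default) or the reverse.
#' @return PAC value in `[0, 1]`; 0 (with a message) when the honeybee row
#'   is all zero, i.e. no shared resources exist.
#' @export
pairwisePac <- function(nativeRow, honeybeeRow,
                        direction = c("native_to_honeybee",
                                      "honeybee_to_native")) {
  direction <- match.arg(direction)
  if (!is.null(names(nativeRow)) && !is.null(names(honeybeeRow))) {
    plants <- sortLabels(c(names(nativeRow), names(honeybeeRow)))
    nativeRow <- alignTo(nativeRow, plants)
    honeybeeRow <- alignTo(honeybeeRow, plants)
  } else if (length(nativeRow) != length(honeybeeRow)) {
    stop("unnamed rows must have equal length", call. = FALSE)
  }
  if (any(nativeRow < 0) || any(honeybeeRow < 0))
    stop("interaction strengths must be non-negative", call. = FALSE)
  if (sum(nativeRow) == 0)
    stop("PAC is undefined for a native bee with no interactions",
         call. = FALSE)
  if (sum(honeybeeRow) == 0) {
    message("honeybee row is all zero: no shared resources, PAC = 0")
    return(0)
  }
  keep <- nativeRow > 0 | honeybeeRow > 0  # both-zero plants would give 0/0
  # equal-abundance footing: each row of the two-species matrix is reduced
  # to its diet proportions before the index is evaluated, so the result
  # depends only on how each bee spreads its visits, not on how many were
  # caught
  n <- nativeRow[keep] / sum(nativeRow)
  h <- honeybeeRow[keep] / sum(honeybeeRow)
  if (direction == "native_to_honeybee") {
    sum(n * (h / (n + h)))
  } else {
    sum(h * (n / (n + h)))
  }
}

#' PAC table for every native bee species
#'
#' Computes perceived apparent competition between the honeybee and each
#' native bee species in the plots near the apiaries (PAC_C) and in the
#' distant plots (PAC_D), pairing each native species' per-plot
#' abundance-adjusted diet row with the honeybee's fixed (nearby-derived)
#' profile and averaging the per-plot pairwise values over the plots where
#' the species occurs. Species absent from all plots of a type get `NA`
#' there, not zero. The reverse-direction index (honeybee as focal) is
#' reported alongside.
#'
#' @param nearbyNets,distantNets lists of [InteractionMatrix-class] objects
#'   for the two plot types.
#' @param honeybee a [HoneybeeProfile-class]; defaults to the pooled
#'   profile derived from `nearbyNets`.
#' @param species honeybee label, used to exclude it from the native list.
#' @return data.frame with one row per native species: `bee_species`,
#'   `pac_c`, `pac_d`, `pac_c_reverse`, `pac_d_reverse`, `n_plots_c`,
#'   `n_plots_d`.
#' @export
pacTable <- function(nearbyNets, distantNets, honeybee = NULL,
                     species = "Apis_mellifera") {
  if (is.null(honeybee)) honeybee <- honeybeeProfile(nearbyNets, species)
  adjN <- lapply(nearbyNets, adjustMatrix, honeybee = honeybee)
  adjD <- lapply(distantNets, adjustMatrix, honeybee = honeybee)
  natives <- setdiff(
    sortLabels(unlist(lapply(c(adjN, adjD), beeSpecies))),
    honeybee@species)

  perType <- function(adj, sp) {
    vals <- matrix(NA_real_, 0, 2)
    for (m in adj) {
      V <- adjustedValues(m)
      if (!sp %in% rownames(V)) next
      nat <- V[sp, ]
      if (sum(nat) == 0) next
      hb <- V[honeybee@species, ]
      vals <- rbind(vals, c(
        pairwisePac(nat, hb),
        pairwisePac(nat, hb, direction = "honeybee_to_native")))
    }
    if (nrow(vals) == 0) c(NA_real_, NA_real_, 0L)
    else c(colMeans(vals), nrow(vals))
  }

  resN <- t(vapply(natives, perType, numeric(3), adj = adjN))
  resD <- t(vapply(natives, perType, numeric(3), adj = adjD))
  data.frame(
    bee_species = natives,
    pac_c = resN[, 1], pac_d = resD[, 1],
    pac_c_reverse = resN[, 2], pac_d_reverse = resD[, 2],
    n_plots_c = as.integer(resN[, 3]), n_plots_d = as.integer(resD[, 3]),
    row.names = NULL
  )
}
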