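#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(pmin(p, q)) / (sum(p) + sum(q))`: 0 for identical
#' composition, 1 for disjoint supports. `brayCurtisMatrix()` applies it
#' to every pair of rows of a sample-by-feature matrix.
#'
#' @param p,q non-negative vectors of equal length, not both all zero.
#' @param X non-negative matrix, samples in rows.
#' @return a single dissimilarity, or a symmetric matrix with zero
#'   diagonal and row/column names taken from `X`.
#' @export
brayCurtis <- function(p, q) {
  if (length(p) != length(q)) stop("vectors must have equal length", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("entries must be non-negative", call. = FALSE)
  tot <- sum(p) + sum(q)
  if (tot == 0) stop("Bray-Curtis is undefined for two all-zero vectors",
                     call. = FALSE)
  1 - 2 * sum(pmin(p, q)) / tot
}

#' @rdname brayCurtis
#' @export
brayCurtisMatrix <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- brayCurtis(X[i, ], X[j, ])
    }
  }
  D
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Anderson's PERMANOVA on a dissimilarity matrix: the total and
#' within-group sums of squares are computed from the squared
#' dissimilarities (equivalently, from the trace of the Gower-centered
#' inner-product matrix), the pseudo-F compares the among-group to the
#' within-group mean square, and the p-value comes from free permutation
#' of the group labels:
#' `p = (1 + #permuted F >= observed F) / (1 + nPerm)`.
#' Permutation F statistics are evaluated for all permutations at once via
#' indicator-matrix products, so large calibration runs stay fast.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param groups group label per sample; at least 2 groups with at least
#'   2 samples each.
#' @param nPerm number of permutations (default 999).
#' @param seed optional integer for reproducible permutations.
#' @return object of class `"permanovaResult"`: list with `f`, `r2`, `p`,
#'   `df` (among, within), `nPerm`, `n`.
#' @export
permanova <- function(D, groups, nPerm = 999, seed = NULL) {
  D <- as.matrix(D)
  n <- nrow(D)
  groups <- as.factor(groups)
  if (length(groups) != n) stop("one group label per sample", call. = FALSE)
  if (nlevels(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("degenerate design: every group needs at least two samples",
         call. = FALSE)
  D2 <- D^2
  a <- nlevels(groups)
  sst <- sum(D2) / (2 * n)

  # within-group SS for an assignment given as an n x a indicator matrix U:
  # ssw = sum_g (1' U_g D2 U_g 1) / (2 n_g)
  sswFor <- function(U, sizes) {
    quad <- colSums(U * (D2 %*% U))  # one entry per group
    sum(quad / (2 * sizes))
  }
  U0 <- stats::model.matrix(~ groups - 1)
  sizes <- as.numeric(table(groups))
  ssw <- sswFor(U0, sizes)
  ssa <- sst - ssw
  fObs <- (ssa / (a - 1)) / (ssw / (n - a))

  perm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(k) {
      idx <- sample.int(n)
      Up <- U0[idx, , drop = FALSE]
      sswP <- sswFor(Up, sizes)
      ((sst - sswP) / (a - 1)) / (sswP / (n - a))
    }, numeric(1))
  })
  p <- (1 + sum(perm >= fObs)) / (1 + nPerm)

  structure(list(
    f = fObs, r2 = ssa / sst, p = p,
    df = c(among = a - 1, within = n - a),
    nPerm = nPerm, n = n
  ), class = "permanovaResult")
}

#' @export
print.permanovaResult <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F(%d, %d) = %.3f, R^2 = %.3f, p = %.4g (%d permutations)\n",
    x$df[["among"]], x$df[["within"]], x$f, x$r2, x$p, x$nPerm))
  invisible(x)
}

#' Non-metric multidimensional scaling by Kruskal stress minimization
#'
#' Finds a k-dimensional configuration whose inter-point distances are, in
#' rank order, as close as possible to the observed dissimilarities.
#' Each iteration fits monotone disparities to the configuration distances
#' by isotonic regression (primary, i.e. weak, treatment of ties: tied
#' dissimilarities are ordered by their current distances, so they may take
#' different disparities) and then moves the configuration by a Guttman
#' majorization step. Stress is Kruskal's stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`. The best of `nRestarts` starts
#' (a classical-scaling start plus random starts) is returned, with
#' coordinates centered at the origin.
#'
#' @param D symmetric dissimilarity matrix (or `dist`).
#' @param k embedding dimension (default 2).
#' @param nRestarts number of starts (default 20).
#' @param seed optional integer seed for the random starts.
#' @param maxit,tol iteration cap and stress-change convergence tolerance.
#' @return object of class `"nmdsResult"`: list with `points` (n x k),
#'   `stress`, `converged`, `nRestarts`.
#' @export
nmds <- function(D, k = 2, nRestarts = 20, seed = NULL,
                 maxit = 2000, tol = 1e-7) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  low <- lower.tri(D)
  diss <- D[low]
  ord <- order(diss)

  run <- function(X) {
    sPrev <- Inf
    converged <- FALSE
    for (it in seq_len(maxit)) {
      dx <- as.matrix(stats::dist(X))
      dv <- dx[low]
      # primary tie treatment: within tied dissimilarities, follow the
      # current distances so ties are free to differ
      o <- order(diss, dv)
      fitIso <- stats::isoreg(dv[o])
      dhat <- numeric(length(dv))
      dhat[o] <- fitIso$yf
      s <- sqrt(sum((dv - dhat)^2) / sum(dv^2))
      if (is.nan(s)) break
      # a near-interpolating configuration counts as converged even while
      # the residual stress still creeps multiplicatively towards zero
      if (s < 1e-4 || abs(sPrev - s) < tol) { converged <- TRUE; break }
      sPrev <- s
      # Guttman transform with weights 1
      B <- matrix(0, n, n)
      Bl <- ifelse(dv > 0, -dhat / dv, 0)
      B[low] <- Bl
      B <- B + t(B)
      diag(B) <- -rowSums(B)
      X <- (B %*% X) / n
    }
    dx <- as.matrix(stats::dist(X))
    dv <- dx[low]
    o <- order(diss, dv)
    fitIso <- stats::isoreg(dv[o])
    dhat <- numeric(length(dv))
    dhat[o] <- fitIso$yf
    s <- sqrt(sum((dv - dhat)^2) / sum(dv^2))
    list(X = X, stress = s, converged = converged)
  }

  best <- withSeed(seed, {
    # classical metric scaling as the first start
    starts <- vector("list", nRestarts)
    cm <- tryCatch(stats::cmdscale(D, k = k), error = function(e) NULL)
    if (!is.null(cm) && ncol(cm) == k) starts[[1]] <- cm
    for (r in seq_len(nRestarts)) {
      if (is.null(starts[[r]]))
        starts[[r]] <- matrix(stats::rnorm(n * k), n, k)
    }
    fits <- lapply(starts, run)
    fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  })

  pts <- scale(best$X, center = TRUE, scale = FALSE)
  dimnames(pts) <- list(rownames(D), paste0("NMDS", seq_len(k)))
  if (!best$converged)
    warning("NMDS did not converge in any restart within maxit iterations",
            call. = FALSE)
  structure(list(
    points = pts, stress = best$stress,
    converged = best$converged, nRestarts = nRestarts
  ), class = "nmdsResult")
}

#' @export
print.nmdsResult <- function(x, ...) {
  cat(sprintf("NMDS (%d points, %d axes): stress-1 = %.4f%s\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Diet profiles of selected bee species per plot and survey block
#'
#' Computes, for each requested species and each sample unit, the
#' proportion of the species' interaction links going to each plant
#' (links to a plant divided by the species' total links in the sample).
#' Pollen surveys within a plot are combined into blocks of
#' `blockSize` consecutive rounds (default pairs) before proportioning, so
#' every sample rests on enough captures; samples in which the species has
#' no qualifying link are omitted with a message. Set
#' `combineAdjacent = FALSE` to keep single survey rounds as samples.
#'
#' @param records pollen-load records for any number of plots (see
#'   [buildNetwork()]).
#' @param species character vector of bee species to profile (typically the
#'   common species).
#' @param blockSize number of consecutive survey rounds per sample block.
#' @param combineAdjacent combine adjacent survey rounds into blocks?
#' @param minGrains detection threshold passed to the link rule.
#' @return named list, one element per species: list with `profiles`
#'   (samples x plants proportion matrix, rows summing to 1), `plot_id`,
#'   `plot_type`, `sample_id` per row.
#' @export
dietProfiles <- function(records, species, blockSize = 2,
                         combineAdjacent = TRUE, minGrains = 3L) {
  stopIfMissingCols(records, c(
    "individual_id", "bee_species", "plot_id", "plot_type",
    "survey_round", "plant_species", "grain_count"
  ), "pollen-load records")
  hits <- records[records$grain_count >= minGrains &
                    !is.na(records$plant_species) &
                    records$plant_species != "", , drop = FALSE]
  hits$block <- if (combineAdjacent)
    ceiling(hits$survey_round / blockSize) else hits$survey_round

  out <- list()
  for (sp in species) {
    h <- hits[hits$bee_species == sp, , drop = FALSE]
    if (nrow(h) == 0L) {
      message("species '", sp, "' has no qualifying links anywhere; skipped")
      next
    }
    plants <- sortLabels(h$plant_species)
    sampleKey <- paste(h$plot_id, h$block, sep = ":")
    tab <- table(sampleKey, factor(h$plant_species, plants))
    M <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    M <- M / rowSums(M)
    plotOf <- sub(":.*$", "", rownames(M))
    typeOf <- h$plot_type[match(plotOf, h$plot_id)]
    out[[sp]] <- list(
      profiles = M,
      sample_id = rownames(M),
      plot_id = plotOf,
      plot_type = as.character(typeOf)
    )
  }
  out
}

#' Test diet-niche shifts between plot types for each species
#'
#' Runs a one-way PERMANOVA (Bray-Curtis, free permutations) of each
#' species' per-sample diet profiles against plot type, plus an NMDS
#' ordination of the same matrix. Species whose samples do not span both
#' plot types (or have fewer than two samples in a type) are reported with
#' `NA` statistics.
#'
#' @param profiles output of [dietProfiles()].
#' @param nPerm permutations for the PERMANOVA (default 999).
#' @param seed integer seed; each species uses a deterministic offset.
#' @param runNmds also compute the NMDS ordinations (default TRUE).
#' @return list with `tests` (data.frame: `bee_species`, `f`, `r2`, `p`,
#'   `n_samples`) and `ordinations` (named list of [nmds()] results).
#' @export
nicheShiftTest <- function(profiles, nPerm = 999, seed = NULL, runNmds = TRUE) {
  rows <- list()
  ords <- list()
  for (i in seq_along(profiles)) {
    sp <- names(profiles)[i]
    pr <- profiles[[i]]
    groups <- pr$plot_type
    ok <- length(unique(groups)) == 2 && all(table(groups) >= 2)
    if (!ok) {
      rows[[sp]] <- data.frame(bee_species = sp, f = NA_real_, r2 = NA_real_,
                               p = NA_real_, n_samples = nrow(pr$profiles))
      next
    }
    D <- brayCurtisMatrix(pr$profiles)
    res <- permanova(D, groups, nPerm = nPerm,
                     seed = if (is.null(seed)) NULL else seed + i)
    rows[[sp]] <- data.frame(bee_species = sp, f = res$f, r2 = res$r2,
                             p = res$p, n_samples = res$n)
    if (runNmds && nrow(D) >= 4) {
      ords[[sp]] <- nmds(D, k = 2, nRestarts = 10,
                         seed = if (is.null(seed)) NULL else seed + 1000 + i)
    }
  }
  list(tests = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       ordinations = ords)
}

#' Flowering-community composition and similarity across plots
#'
#' `flowerComposition()` reshapes quadrat flower surveys into a
#' (plot x survey)-by-plant abundance matrix. `flowerSimilarity()` then
#' asks whether the flowering-plant composition differs among the plots
#' (PERMANOVA on Bray-Curtis with plots as groups and surveys as
#' replicates, plus an NMDS ordination) - the design-control check that
#' nearby and distant plots offer comparable floral resources.
#'
#' @param flowers data.frame with `plot_id`, `plot_type`, `survey_round`,
#'   `plant_species`, `flower_count`.
#' @param nPerm,seed passed to [permanova()].
#' @return `flowerComposition()`: list with `abundance` matrix, `plot_id`,
#'   `plot_type` per row. `flowerSimilarity()`: list with `permanova_plot`
#'   (among the six plots), `permanova_type` (nearby vs distant) and
#'   `nmds`.
#' @export
flowerComposition <- function(flowers) {
  stopIfMissingCols(flowers, c(
    "plot_id", "plot_type", "survey_round", "plant_species", "flower_count"
  ), "flower surveys")
  if (any(flowers$flower_count < 0))
    stop("flower counts must be non-negative", call. = FALSE)
  plants <- sortLabels(flowers$plant_species)
  key <- paste(flowers$plot_id, flowers$survey_round, sep = ":")
  tot <- stats::aggregate(
    flowers$flower_count,
    by = list(key = key, plant = factor(flowers$plant_species, plants)),
    FUN = sum)
  samples <- sortLabels(key)
  M <- matrix(0, length(samples), length(plants),
              dimnames = list(samples, plants))
  M[cbind(match(tot$key, samples), match(tot$plant, plants))] <- tot$x
  plotOf <- sub(":[^:]*$", "", samples)
  typeOf <- flowers$plot_type[match(plotOf, flowers$plot_id)]
  list(abundance = M, plot_id = plotOf, plot_type = as.character(typeOf))
}

#' @rdname flowerComposition
#' @export
flowerSimilarity <- function(flowers, nPerm = 999, seed = NULL) {
  comp <- flowerComposition(flowers)
  D <- brayCurtisMatrix(comp$abundance)
  list(
    permanova_plot = permanova(D, comp$plot_id, nPerm = nPerm, seed = seed),
    permanova_type = permanova(D, comp$plot_type, nPerm = nPerm,
                               seed = if (is.null(seed)) NULL else seed + 1),
    nmds = nmds(D, k = 2, nRestarts = 10,
                seed = if (is.null(seed)) NULL else seed + 2)
  )
}
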