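#' Relative change in abundance between distant and nearby plots
#'
#' `(distant - nearby) / distant`: positive values mean the species is less
#' abundant near the apiaries (decline), 1 means it was not detected there
#' at all, negative values mean it is more abundant near the apiaries. The
#' value is invariant to rescaling both abundances by the same positive
#' factor, so it does not matter whether per-survey means or per-plot sums
#' are fed in, as long as both sides use the same unit.
#'
#' @param distant,nearby non-negative abundances (vectorized); every
#'   `distant` must be positive.
#' @return numeric vector of relative changes.
#' @export
relativeChange <- function(distant, nearby) {
  if (any(!is.finite(distant)) || any(distant <= 0))
    stop("relative change is undefined when distant abundance is 0",
         call. = FALSE)
  if (any(!is.finite(nearby)) || any(nearby < 0))
    stop("nearby abundance must be non-negative", call. = FALSE)
  (distant - nearby) / distant
}

# expand sparse sweep records to the full species x plot x survey grid;
# absent combinations are true zero counts
completeSweepGrid <- function(sweeps, species = NULL) {
  stopIfMissingCols(sweeps, c(
    "plot_id", "plot_type", "survey_round", "bee_species", "count"
  ), "sweep counts")
  if (any(sweeps$count < 0) || any(sweeps$count != round(sweeps$count)))
    stop("sweep counts must be non-negative integers", call. = FALSE)
  if (is.null(species)) species <- sortLabels(sweeps$bee_species)
  plotInfo <- unique(sweeps[, c("plot_id", "plot_type")])
  if (anyDuplicated(plotInfo$plot_id))
    stop("plot_type must be consistent within a plot", call. = FALSE)
  rounds <- sortLabels(sweeps$survey_round)
  grid <- expand.grid(
    bee_species = species, plot_id = plotInfo$plot_id,
    survey_round = rounds,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$plot_type <- plotInfo$plot_type[match(grid$plot_id, plotInfo$plot_id)]
  key <- function(d) paste(d$bee_species, d$plot_id, d$survey_round, sep = "\r")
  grid$count <- sweeps$count[match(key(grid), key(sweeps))]
  grid$count[is.na(grid$count)] <- 0L
  grid
}

#' Per-species abundance summary and relative change
#'
#' Summarizes sweep-net counts into mean (or summed) per-plot abundance by
#' plot type for each bee species and derives the relative change. Species
#' never observed in the distant plots are dropped with a warning (the
#' change is undefined without a distant baseline). Species are flagged
#' rare when their relative abundance among the listed species in the
#' distant plots falls below `rareThreshold` (default 5%).
#'
#' @param sweeps sweep-count data.frame (`plot_id`, `plot_type`,
#'   `survey_round`, `bee_species`, `count`); unlisted combinations are
#'   treated as zero counts.
#' @param stat `"mean"` (per-plot per-survey average, default) or `"sum"`
#'   (per-plot totals over surveys) before averaging over plots.
#' @param exclude species labels to drop (e.g. the introduced honeybee).
#' @param rareThreshold relative-abundance cutoff for the `rare` flag.
#' @return data.frame with `bee_species`, `abundance_distant`,
#'   `abundance_nearby`, `relative_change`, `relative_abundance_distant`,
#'   `rare`, `lost` (not detected nearby at all).
#' @export
abundanceChange <- function(sweeps, stat = c("mean", "sum"),
                            exclude = "Apis_mellifera",
                            rareThreshold = 0.05) {
  stat <- match.arg(stat)
  grid <- completeSweepGrid(sweeps)
  grid <- grid[!grid$bee_species %in% exclude, , drop = FALSE]
  agg <- stats::aggregate(count ~ bee_species + plot_id + plot_type,
                          data = grid,
                          FUN = if (stat == "mean") mean else sum)
  byType <- stats::aggregate(count ~ bee_species + plot_type, data = agg,
                             FUN = mean)
  sp <- sortLabels(byType$bee_species)
  pick <- function(tp) {
    v <- byType$count[byType$plot_type == tp]
    names(v) <- byType$bee_species[byType$plot_type == tp]
    alignTo(v, sp)
  }
  distant <- pick("distant")
  nearby <- pick("nearby")
  zero <- distant == 0
  if (any(zero)) {
    warning("dropping species never observed in distant plots: ",
            paste(sp[zero], collapse = ", "), call. = FALSE)
    sp <- sp[!zero]; distant <- distant[!zero]; nearby <- nearby[!zero]
  }
  rel <- distant / sum(distant)
  data.frame(
    bee_species = sp,
    abundance_distant = unname(distant),
    abundance_nearby = unname(nearby),
    relative_change = relativeChange(distant, nearby),
    relative_abundance_distant = unname(rel),
    rare = unname(rel < rareThreshold),
    lost = unname(nearby == 0),
    row.names = NULL
  )
}

#' Negative-binomial GLM for one species' abundance by plot type
#'
#' Fits `count ~ plot_type` with a negative-binomial error and log link on
#' the per-plot per-survey sweep counts of one species (the replication
#' unit; set `unit = "plot"` to fit on per-plot totals instead). The
#' distant plots are the reference level, so the plot-type coefficient is
#' the log ratio of the nearby to the distant mean count, with a Wald test
#' against zero. With a single binary factor the fitted group means equal
#' the sample means, so the coefficient equals `log(mean_nearby /
#' mean_distant)` whenever both group means are positive; when one group is
#' all zero the estimate diverges and the fit is flagged as on the
#' boundary.
#'
#' @param sweeps sweep-count data.frame (see [abundanceChange()]).
#' @param species single species label.
#' @param unit `"survey"` (default) or `"plot"`.
#' @return object of class `"nbAbundanceFit"`: list with `species`,
#'   `estimate` (plot-type log ratio), `se`, `p`, `theta` (NB dispersion;
#'   `Inf` when the fit collapses to the Poisson limit),
#'   `df_residual`, `boundary` flag, and the coefficient table.
#' @export
fitSpeciesAbundanceGlm <- function(sweeps, species, unit = c("survey", "plot")) {
  unit <- match.arg(unit)
  grid <- completeSweepGrid(sweeps)
  d <- grid[grid$bee_species == species, , drop = FALSE]
  if (nrow(d) == 0L) stop("no sweep records for species ", species, call. = FALSE)
  if (unit == "plot")
    d <- stats::aggregate(count ~ plot_id + plot_type, data = d, FUN = sum)
  if (length(unique(d$plot_id[d$plot_type == "distant"])) < 2 ||
      length(unique(d$plot_id[d$plot_type == "nearby"])) < 2)
    stop("need at least two plots per plot type", call. = FALSE)
  d$plot_type <- factor(d$plot_type, levels = c("distant", "nearby"))
  groupMeans <- tapply(d$count, d$plot_type, mean)
  if (all(groupMeans == 0))
    stop("abundance model is not identifiable: species '", species,
         "' has zero counts in both plot types", call. = FALSE)
  boundary <- any(groupMeans == 0)
  if (boundary)
    warning("species '", species, "' has all-zero counts in one plot type; ",
            "the plot-type effect lies on the boundary", call. = FALSE)
  # theta estimation diverges when the counts carry no overdispersion; the
  # NB then collapses to its Poisson limit, which keeps the same mean
  # structure (fitted group means = sample means either way)
  fit <- tryCatch(
    suppressWarnings(
      MASS::glm.nb(count ~ plot_type, data = d,
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100))),
    error = function(e) NULL)
  theta <- if (is.null(fit)) Inf else fit$theta
  if (is.null(fit))
    fit <- stats::glm(count ~ plot_type, data = d, family = stats::poisson(),
                      control = stats::glm.control(epsilon = 1e-10,
                                                   maxit = 100))
  co <- summary(fit)$coefficients
  structure(list(
    species = species,
    estimate = unname(co["plot_typenearby", "Estimate"]),
    se = unname(co["plot_typenearby", "Std. Error"]),
    p = unname(co["plot_typenearby", "Pr(>|z|)"]),
    theta = theta,
    df_residual = fit$df.residual,
    boundary = boundary,
    coefficients = co,
    group_means = groupMeans
  ), class = "nbAbundanceFit")
}

#' @export
print.nbAbundanceFit <- function(x, ...) {
  cat(sprintf(
    "NB abundance model for %s: nearby/distant log-ratio = %.3f (SE %.3f, p = %.3g)%s\n",
    x$species, x$estimate, x$se, x$p,
    if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Gaussian models for the relative change in abundance
#'
#' Ordinary Gaussian linear models of the relative change in abundance on
#' perceived apparent competition and/or baseline abundance, matching the
#' four model forms of the analysis: PAC_D alone, PAC_C alone, distant
#' abundance alone, and the two-main-effects-plus-interaction model.
#' Species with a missing PAC_C (lost near the apiaries, so no nearby diet)
#' are dropped from the PAC_C model only; all species enter the other
#' models. With 15 species the interaction model has 11 residual degrees
#' of freedom.
#'
#' @param table data.frame joining [abundanceChange()] and [pacTable()]
#'   rows by species; must contain `relative_change` plus the predictors
#'   used (`pac_d`, `pac_c`, `abundance_distant`).
#' @param predictors one of `"pac_d"`, `"pac_c"`, `"abundance"`,
#'   `"interaction"` (abundance * PAC_D).
#' @return object of class `"changeModelFit"`: list with the coefficient
#'   table (`estimate`, `se`, `t`, `p`), `df_residual`, `adj_r_squared`,
#'   `sigma`, `n`, and the underlying `lm` fit.
#' @export
fitChangeModel <- function(table,
                           predictors = c("pac_d", "pac_c", "abundance",
                                          "interaction")) {
  predictors <- match.arg(predictors)
  form <- switch(predictors,
    pac_d = relative_change ~ pac_d,
    pac_c = relative_change ~ pac_c,
    abundance = relative_change ~ abundance_distant,
    interaction = relative_change ~ abundance_distant * pac_d
  )
  vars <- all.vars(form)
  stopIfMissingCols(table, vars, "change-model table")
  d <- table[stats::complete.cases(table[, vars, drop = FALSE]), , drop = FALSE]
  p <- length(attr(stats::terms(form), "term.labels"))
  if (nrow(d) < p + 2)
    stop("too few complete cases (", nrow(d), ") for ", p, " predictor(s)",
         call. = FALSE)
  const <- vapply(vars[-1], function(v) stats::var(d[[v]]) == 0, TRUE)
  if (any(const))
    stop("constant predictor(s): ", paste(vars[-1][const], collapse = ", "),
         call. = FALSE)
  fit <- stats::lm(form, data = d)
  s <- summary(fit)
  co <- s$coefficients
  structure(list(
    formula = deparse(form),
    coefficients = data.frame(
      term = rownames(co),
      estimate = co[, "Estimate"],
      se = co[, "Std. Error"],
      t = co[, "t value"],
      p = co[, "Pr(>|t|)"],
      row.names = NULL
    ),
    df_residual = fit$df.residual,
    adj_r_squared = s$adj.r.squared,
    sigma = s$sigma,
    n = nrow(d),
    fit = fit
  ), class = "changeModelFit")
}

#' @export
print.changeModelFit <- function(x, ...) {
  cat("Gaussian change model:", x$formula, "\n")
  cat(sprintf("  n = %d, residual df = %d, adjusted R^2 = %.3f, sigma = %.4f\n",
              x$n, x$df_residual, x$adj_r_squared, x$sigma))
  print(x$coefficients, digits = 4)
  invisible(x)
}
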