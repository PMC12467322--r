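# pacnet

Pollen-transport networks and perceived apparent competition (PAC) between
an introduced generalist pollinator — the western honeybee, *Apis
mellifera* — and native bees.

Apiaries concentrate enormous numbers of honeybee foragers in flower-rich
grasslands. `pacnet` is for ecologists asking what that does to the native
bee fauna under a spatial-contrast design: plots near long-established
apiaries versus matched plots far enough away that honeybees are absent,
each sampled with sweep-net abundance surveys, individual pollen-load
screening, and flower quadrats. The package carries the analysis from raw
individual-level pollen records to the final models:

1. **Networks** — `buildNetwork()` turns pollen-load records into a
   quantitative bee × plant matrix: entry *P₍ₓᵧ₎* counts individuals of bee
   *x* carrying ≥ 3 grains of plant *y*'s pollen, with the specimen counts
   *Aₓ* kept alongside.
2. **Niche overlap** — PAC via Müller's index,

   *d₍ᵢⱼ₎* = Σₖ (α₍ᵢₖ₎ / Σₗ α₍ᵢₗ₎) · (α₍ⱼₖ₎ / Σₘ α₍ₘₖ₎),

   computed on abundance-adjusted interactions *N₍ₓᵧ₎ = P₍ₓᵧ₎ / Aₓ* in a
   two-species matrix per native bee and plot (`pairwisePac()`,
   `pacTable()`). PAC_C uses the nearby-plot diets, PAC_D pairs each
   native's *distant*-plot diet with the honeybee's fixed invaded-site
   profile.
3. **Abundance** — per-species negative-binomial GLMs of sweep counts on
   plot type, and Gaussian regressions of the relative change in abundance,
   (distant − nearby)/distant, on PAC_D, PAC_C, baseline abundance, and
   abundance × PAC_D (`fitSpeciesAbundanceGlm()`, `fitChangeModel()`).
4. **Diet shifts** — Bray–Curtis dissimilarity of per-sample diet
   proportions, one-way PERMANOVA (999 seeded permutations) and NMDS
   (isotonic-regression stress minimization), also used for the
   flowering-community similarity control (`nicheShiftTest()`,
   `flowerSimilarity()`).
5. **Synthetic communities** — `simulateCommunity()` generates the whole
   data structure with known ground truth (true overlap per species,
   decline slope β, rarity penalty γ), so every estimator is testable
   end to end without field data.

The vignette (`vignettes/honeybee-pac-methods.Rmd`) documents the models,
the generator, and the numerical choices.

## Worked example

```r
library(pacnet)

sim <- simulateCommunity(simulationConfig(seed = 1))
res <- runPipeline(pipelineConfig(sim$pollen, sim$sweeps, sim$flowers,
                                  nPerm = 999, seed = 1))
res$networks[[1]]
#> InteractionMatrix: plot distant_1 (distant), 15 bee species x 52 plants, 315 interaction links

head(res$pac[, c("bee_species", "pac_c", "pac_d", "n_plots_c", "n_plots_d")], 5)
#>   bee_species  pac_c  pac_d n_plots_c n_plots_d
#> 1   Native_01 0.0976 0.0961         3         3
#> 2   Native_02 0.0733 0.0855         3         3
#> 3   Native_03 0.0782 0.0663         3         3
#> 4   Native_04 0.1152 0.1269         3         3
#> 5   Native_05 0.1530 0.1683         3         3

res$change_models$pac_d
#> Gaussian change model: relative_change ~ pac_d
#>   n = 15, residual df = 13, adjusted R^2 = 0.383, sigma = 0.1707
#>          term estimate     se     t        p
#> 1 (Intercept)   0.3574 0.1038 3.442 0.004377
#> 2       pac_d   1.1610 0.3727 3.115 0.008212

res$change_models$interaction
#> Gaussian change model: relative_change ~ abundance_distant * pac_d
#>   n = 15, residual df = 11, adjusted R^2 = 0.557, sigma = 0.1448
#>                      term estimate       se      t       p
#> 1             (Intercept)  0.25236 0.148418  1.700 0.11713
#> 2       abundance_distant  0.01085 0.008383  1.294 0.22207
#> 3                   pac_d  1.79414 0.587970  3.051 0.01102
#> 4 abundance_distant:pac_d -0.05975 0.040047 -1.492 0.16383

res$flowers$permanova_type
#> PERMANOVA: pseudo-F(1, 28) = 1.408, R^2 = 0.048, p = 0.051 (999 permutations)
```

Reading the output: bees that spread their visits like the honeybee does
(high `pac_d`) declined more near the apiaries — the PAC_D slope of 1.16
means a species overlapping the honeybee's diet at the theoretical maximum
of 0.5 loses roughly an extra 58% of its distant-plot abundance. The
interaction model has 11 residual degrees of freedom (15 species − 4
parameters). The flowering-community PERMANOVA is the design control: the
plot classes offer similar floral resources, so abundance differences are
not explained by the flowers. With `outDir` set, `runPipeline()` also
writes every table as CSV plus a JSON manifest with seeds and checksums;
reruns are bit-identical.

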