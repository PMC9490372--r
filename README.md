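# metgei

Genotype-by-environment interaction (GEI) and stability analysis for
balanced multi-environment trials (METs), for plant breeders and
quantitative geneticists deciding which genotypes combine high mean
performance with consistent performance across environments.

A MET evaluates $g$ genotypes at $e$ location × year combinations with
$r$ replicated plots. From the two-way table of cell means $x_{ij}$,
`metgei` implements the standard stability stack:

- **Pooled factorial ANOVA** over genotype, location, year and their
  interactions, plus the collapsed G / E / G×E partition with df
  $(g-1)$, $(e-1)$, $(g-1)(e-1)$.
- **Univariate stability**: Eberhart–Russell
  joint regression $x_{ij} = \mu_i + \beta_i I_j + \delta_{ij}$ on the
  environment index $I_j = X_{.j} - X_{..}$, giving slope $b_i$ and
  deviation $S^2_{di}$; Perkins–Jinks slope $B_i = b_i - 1$ and
  deviation $DJ_i$; Wricke's ecovalence
  $W_i = \sum_j (x_{ij} - X_{i.} - X_{.j} + X_{..})^2$ with
  $\sum_i W_i = SS_{G\times E}$; Francis–Kannenberg SD and CV.
- **AMMI**: SVD of the double-centered interaction matrix,
  $x_{ij} = \mu + \alpha_i + \beta_j + \sum_n \lambda_n \gamma_{in}
  \delta_{jn} + \rho_{ij}$, with the IPCA ANOVA (Gollob df
  $g + e - 1 - 2n$) and AMMI1/AMMI2 biplot coordinates.
- **GGE biplots**: environment-centered SVD keeping G + GE, with
  singular-value partitioning; which-won-where convex-hull sectors and
  mega-environments; mean-vs-stability projections on the average
  environment coordinate (AEC); ideal-genotype ranking; environment
  discriminativeness vs representativeness.
- **Trait correlation** (Pearson, on cell means by default) and a
  one-shot `run_report()` bundling everything as delimited text.
- **A MET simulator** (`simulate_met()`) that implants known additive
  effects, low-rank multiplicative interaction (or genotype-specific
  regression slopes), and replicate error, so every estimator can be
  checked against ground truth.

## Worked example

```r
library(metgei)

sim <- simulate_met(seed = 42)           # 13 genotypes x 8 env x 3 reps
tw  <- cell_means(sim$data, "yield")     # two-way table of cell means

ammi_anova(fit_ammi(tw, basis = "plot"), n_axes = 2)
#> ANOVA (plot basis)
#>       source  df       ss      ms      f         p pct_explained stars
#>  Environment   7 118.3227 16.9032 805.29 6.81e-147         50.45   ***
#>     Genotype  12  16.9584  1.4132  67.33  8.73e-65          7.23   ***
#>        G x E  84  99.2336  1.1814  56.28 3.81e-108         42.31   ***
#>        IPCA1  18  74.4917  4.1384 197.16 6.00e-120         75.07   ***
#>        IPCA2  16  23.9598  1.4975  71.34  3.71e-75         24.14   ***
#>     Residual  50   0.7822  0.0156   0.75  8.91e-01          0.79    ns
#>        Error 208   4.3660  0.0210     NA        NA            NA
```

The interaction (84 df) dominates the genotype main effect — 42% vs 7%
of G+E+G×E — and its first two principal components capture 75% and
24% of the interaction SS, so a 2-D biplot summarises this trial almost
completely. Per-genotype stability:

```r
head(as.data.frame(stability_table(tw))[c("genotype", "mean", "cv", "bi", "s2di", "wi")], 4)
#>   genotype     mean       cv        bi      s2di       wi
#> 1      G01 2.954967 40.18159 1.1882068 0.9238789 5.692721
#> 2      G02 2.522834 31.62822 1.0377038 0.1913047 1.194122
#> 3      G03 2.751799 29.28832 0.8650844 0.3724129 2.331682
#> 4      G04 2.769903 39.74757 0.8630204 1.0305469 6.282189
```

G02 is the stable one here: slope near 1 (average responsiveness),
small regression deviation, and the smallest ecovalence (its share of
the interaction SS). GGE ranking against the ideal point:

```r
head(rank_genotypes(fit_gge(tw, svp = "genotype")), 4)
#>   rank genotype  distance     ideal_x   ideal_y
#> 1    1      G09 0.8535608 -0.04728337 -1.563887
#> 2    2      G12 1.4075520 -0.04728337 -1.563887
#> 3    3      G06 1.5309964 -0.04728337 -1.563887
#> 4    4      G10 1.8101978 -0.04728337 -1.563887
```

G09's marker sits closest to the ideal point (best mean projection on
the AEC at perfect stability), so it is the top pick by the biplot
criterion.

## Analysis workflow

The numbered drivers under `analysis/` run the full study pipeline on
a simulated trial of the reference dimensions and write their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R       # data + implanted truth
Rscript analysis/02_pooled_anova.R
Rscript analysis/03_stability.R
Rscript analysis/04_ammi.R
Rscript analysis/05_gge.R
Rscript analysis/06_correlation.R
Rscript analysis/07_report.R         # everything, as one bundle
```

Real data enter through `read_met()`: delimited text (comma or tab,
auto-detected) with columns `genotype, location, year, rep, trait,
value`, or wide with one column per trait. See
`vignettes/met-gei-methods.Rmd` for the models, conventions (basis,
SVP, error correction), and the simulator's assumptions.

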