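---
title: "Models and methods for multi-environment trial stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-environment trial stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgei)
```

## The problem

A multi-environment trial (MET) evaluates a set of crop genotypes at
several location × year combinations, with replicated plots inside each
environment. Breeders want two things from the data: which genotypes
perform best on average, and which perform *consistently* — the two
questions are coupled through genotype-by-environment interaction (GEI),
the non-additive part of the response. `metgei` implements the standard
analysis stack for balanced METs: a pooled factorial ANOVA, four
univariate stability families, the AMMI bilinear decomposition, GGE
biplot geometry, and trait correlation, together with a simulator that
implants known structure so every stage can be validated against ground
truth.

All analyses start from the two-way table of cell means
$x_{ij}$ (genotype $i = 1..g$, environment $j = 1..e$), with the
replicate-level error summarised by the pooled within-cell error mean
square. Environments are coded `ENV1..ENVk` by enumerating locations
within year, so a 4-location × 2-year trial yields ENV1–ENV4 for the
first year and ENV5–ENV8 for the second. Balance is enforced, not
imputed: an unbalanced design is an error that names the offending
cells, because every formula below relies on the orthogonality that
balance provides.

## Pooled ANOVA

`pooled_anova()` partitions plot-level data into genotype, location,
year, all their interactions, and pooled error — the classical
fixed-effects sums of squares, which on a balanced design are unique
(sequential = marginal). Every term is tested against the pooled error
mean square by default; `g_over_ge = TRUE` tests genotype over the
pooled genotype-involving interactions instead, a choice some analysts
prefer when environments are viewed as a sample. The package computes
fixed-effects arithmetic throughout even where a random-environments
interpretation is intended: only SS/MS/F arithmetic is reported, and
that arithmetic is identical. Replicate blocks are pooled into error;
there is no separate block term.

`env_collapsed_anova()` re-expresses the same variation as genotype (G),
environment (E = location × year), and G × E with df $(g-1)$, $(e-1)$,
$(g-1)(e-1)$. On the *plot* basis the means-based SS are multiplied by
the replicate count $r$ so they sit on the same scale as the pooled
ANOVA (the E row then equals L + Y + L×Y exactly, and G×E pools the
three genotype-involving interactions); on the *means* basis they stay
on the cell-mean scale. The distinction matters when comparing with
published tables: interaction SS on the plot basis is $r$ times the sum
of the ecovalences, which live on the means basis.

## Univariate stability

With the environment index $I_j = X_{.j} - X_{..}$ (which sums to zero),
the joint-regression model of Eberhart and Russell fits per genotype

$$ x_{ij} = \mu_i + \beta_i I_j + \delta_{ij}, \qquad
   b_i = \frac{\sum_j x_{ij} I_j}{\sum_j I_j^2}. $$

A slope of 1 marks average responsiveness; $b_i > 1$ marks genotypes
that exploit favorable environments, $b_i < 1$ genotypes buffered
against poor ones. The deviation mean square
$S^2_{di} = \sum_j \hat\delta_{ij}^2/(e-2) - \mathrm{MSE}/r$ subtracts
the sampling noise of a cell mean so that a genotype tracking the
environment means exactly has expectation zero; `error_correction =
FALSE` gives the raw deviation mean square instead. Both conventions
are exposed because published tables mix them: the Perkins–Jinks
deviation `dji` is deliberately the *raw* mean square, so across
genotypes `dji - s2di` is the constant $\mathrm{MSE}/r$ — a useful
fingerprint when reverse-engineering which convention a table used.
The Perkins–Jinks slope is the regression of the interaction deviation
on $I_j$ and satisfies $B_i = b_i - 1$ identically.

Wricke's ecovalence $W_i = \sum_j z_{ij}^2$ (with
$z_{ij} = x_{ij} - X_{i.} - X_{.j} + X_{..}$) is each genotype's share
of the interaction SS: $\sum_i W_i = SS_{G\times E}$ on the means basis,
an identity the tests assert on random tables. Francis–Kannenberg takes
the sample standard deviation of each genotype's environment means and
its CV ($100\,sd/\bar x_i$) as model-free stability measures.

`classify_adaptation()` turns the slope into a verbal class with a band
of ±0.05 around 1 ("average" responsiveness). No threshold is standard
in the literature — published studies classify verbally — so the band is
a package choice, kept configurable; 0.05 is roughly the slope precision
implied by 4-decimal published tables, and in practice classifications
are insensitive to the exact band because estimated slopes rarely fall
within a few hundredths of 1.

## AMMI

`fit_ammi()` decomposes the double-centered interaction matrix by SVD:

$$ x_{ij} = \mu + \alpha_i + \beta_j +
   \sum_n \lambda_n \gamma_{in} \delta_{jn} + \rho_{ij}, $$

with orthonormal score columns and $\sum_n \lambda_n^2 = SS_{G\times E}$
(Eckart–Young). Each interaction principal component (IPCA) receives
Gollob degrees of freedom $g + e - 1 - 2n$, which sum to $(g-1)(e-1)$
over the full rank; `ammi_anova()` appends the retained IPCA rows and a
pooled residual row to the G/E/G×E table, with F against the pooled
error mean square (the Gollob approach — the liberal end of the AMMI
testing spectrum; published AMMI tables typically print significance
stars without naming the denominator, and a permutation-based
alternative was judged out of scope). Component signs are fixed by making the
largest-magnitude environment score of each component positive, so
coordinates are reproducible across platforms; all reported stability
quantities (origin distances) are invariant to this convention, which
the tests verify by flipping signs.

Biplot coordinates use symmetric scaling, $\lambda^{0.5}$ to each side,
configurable through the `scaling` exponent. AMMI1 plots the main
effects ($\mu + \alpha_i$, $\mu + \beta_j$) against IPCA1; AMMI2 plots
IPCA1 against IPCA2 and ranks genotypes by ascending distance from the
origin — the genotype contributing least to the interaction is the most
stable in this sense.

The ANOVA defaults to the plot basis (SS comparable to the pooled
ANOVA); coordinates are conventionally computed on the means basis.
Both are available because published AMMI tables are frequently on the
plot basis while the ecovalence and regression tables are on the means
basis — the package treats the basis as an explicit flag rather than a
hidden convention.

## GGE

`fit_gge()` centers the mean table by environment means only, keeping
G + GE — the quantities relevant to genotype evaluation — and
decomposes by SVD, optionally after dividing each environment column by
its standard deviation (`scaling = "sd"`). Rank-2 markers are formed
under a singular-value partitioning (SVP): genotype-focused
($\lambda$ into genotype markers; preserves Euclidean geometry among
genotypes), environment-focused (among environments), or symmetric.
Defaults per view follow standard GGE practice — symmetric for
which-won-where, genotype-focused for mean-vs-stability and ranking,
environment-focused for discriminativeness — and every view accepts an
override. The geometry is rank-2 by construction (the views are
2-D figures); the PC1+PC2 share of $\sum \lambda^2$ is always reported
(`gof`) so users can judge whether 2-D geometry summarises their data
adequately.

**Which-won-where.** The convex hull of the genotype markers is split
into angular sectors by the rays from the origin perpendicular to the
hull edges; each environment falls in exactly one sector and the hull
vertex inside that sector is its winner (the genotype maximizing the
rank-2 reconstruction of the centered table in that environment — the
property test checks this equivalence on random tables). Boundary ties
are resolved by half-open intervals, assigned counterclockwise, so the
partition is deterministic. Environments sharing a winner form a
mega-environment.

**Mean vs stability.** The average environment coordinate (AEC) axis
runs through the mean of the environment markers. A genotype's signed
projection on the AEC reads as mean performance; its perpendicular
component as instability. The ideal point sits on the positive AEC at
the longest projection; `rank_genotypes()` sorts by distance to it.
**Discriminativeness vs representativeness**: an environment's marker
length (proportional to its genotype standard deviation in rank 2)
against the cosine of its angle with the AEC; the product of the two is
the documented combined score used to flag the "ideal test
environment". If the mean environment marker is (numerically) at the
origin the AEC is undefined and the functions say so — that happens
exactly when the data are interaction-dominated with no consistent
environment direction.

## Correlation

`pearson_matrix()` correlates traits on the g·e cell means by default
(each genotype × environment mean is one observation, pooling across
environments), with plot-level and genotype-mean bases as options.
p-values come from the t transform with $n-2$ df and are unadjusted by
default, matching common practice in MET papers; a Bonferroni flag is
available. Note the quantity is a *phenotypic* correlation even where
breeding papers label it genetic — no variance-component decomposition
is attempted.

## The simulator and what passing tests mean

`simulate_met()` generates
$Y_{ijr} = \mu + g_i + e_j + \sum_k \lambda_k \gamma_{ik}\delta_{jk} +
\varepsilon_{ijr}$ with centered main-effect draws, interaction score
vectors produced by QR-orthogonalization of normal draws against the
intercept (exactly the identifiability constraints AMMI assumes), and
i.i.d. normal error; `slope_mode` replaces the free bilinear term with
$(b_i - 1)e_j$, the structure joint regression assumes, with slopes
centered to mean 1. A single integer seed drives all draws in a fixed
documented order, so a seed fully determines both data and truth.

Defaults emulate a wheat yield trial: 13 genotypes, 4 locations × 2
years, 3 replicates, grand mean 2.8 kg/plot, genotype/environment
effect SDs 0.24/0.48, a rank-2 interaction with singular values 4.8 and
2.9 on the means basis, and plot error SD 0.15. These magnitudes were
chosen once to reproduce the relative variance shares such trials
show — interaction SS comparable to the environment SS and an order of
magnitude above the genotype SS on the plot basis — and are not tuned
thereafter. Test problem sizes (tables of 4–10 genotypes × 3–8
environments, 50–200 simulation replicates) were likewise fixed as the
smallest sizes at which the asserted properties are non-trivial.

The generator is deliberately idealized: errors are homoscedastic and
spatially unstructured, there is no genotype × year × location three-way
truth term (three-way structure arises only through how environments
are coded), and no missing plots. Passing tests therefore demonstrate
algorithmic correctness — the estimators recover implanted structure
under the model's own assumptions — not robustness to field realities
like spatial trend, heteroscedasticity, or unbalanced data. Unbalanced
data are explicitly rejected rather than approximated; a REML-based
mixed-model route would be the right tool there and is out of scope.

## Numerical choices and degenerate inputs

- All arithmetic is double precision; rounding (4 decimals for
  stability tables, 2 for ANOVA displays) happens only at the
  presentation layer.
- Singular values below `1e-12` of the largest are snapped to zero so
  additive tables report exactly zero interaction components.
- A single-replicate design is accepted with pooled error 0 and a
  warning; everything needing an error term (F tests, the
  error-corrected deviation) then degrades explicitly rather than
  silently.
- Zero environment variance (all $I_j = 0$) is an undefined-slope
  error; a zero-variance environment under sd-scaling is an error
  naming the environment; collinear genotype markers make
  which-won-where refuse with a pointer to the rank check.
- Sector boundaries, ranking ties and SVD signs all have deterministic
  tie-breaks, so identical inputs give byte-identical report bundles.

## Limitations

Fixed-effects arithmetic only (no variance components or
heritability); no Shukla stability variance, Lin–Binns superiority or
nonparametric stability measures; no AMMI stability-value indices or
cross-validated axis retention; no genotype-by-trait biplots. The
which-won-where partition is rank-2 geometry — with a low `gof` its
sector structure can differ from the full-rank winners.
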