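---
title: "Methods: MET quality control, BLUEs, consistency, breeding progress and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MET quality control, BLUEs, consistency, breeding progress and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgxe)
```

# Scope and data model

`metgxe` analyses plot-level multi-environment trials (MET) of cultivar
panels. The environmental unit throughout is the *growing condition*: one
year x location x management combination, keyed as
`"2015/GGE/HN_WF_RF"`. Management labels combine a nitrogen level (`HN`,
`LN`: 220 / 110 kg N ha^-1), a fungicide level (`WF`, `NF`) and a water
regime (`RF` rain-fed, `IR` irrigated, `RO` rain-out shelter); only the
nine combinations realised in the German winter-wheat trial network that
motivated the package are accepted by default.

Internally all data are long ("tidy"): one row per plot x trait
observation, because the 24 registered traits have very unequal coverage
across conditions. Wide per-plot CSVs are pivoted on input; arbitrary
source headers are absorbed by a column map. Row/column plot coordinates
are 1-based within a condition's field grid and may be missing, because
not every site recorded layout — every downstream step degrades
gracefully without them.

# Quality control

Two rules, applied in this order at plot level (the only level where a
negative raw value can exist):

1. **Range recoding** (`apply_range_rules()`): implausible values become
   `NA` but the record is kept. Shipped defaults: whole-plot grain yield
   above 3000 dt/ha and thousand grain weight above 80 g; negative values
   of any nonnegative-flagged trait. Observed trait ranges are *not* used
   as bounds — they describe data, they do not define plausibility.
2. **Four-sigma exclusion** (`apply_sd_rule()`): within each growing
   condition, observations of harvest index and spike number beyond the
   condition mean +/- 4 sample standard deviations (n − 1 denominator; the
   choice of denominator is a documented convention, nothing in the
   procedure pins it) are dropped. Groups with fewer than three values are
   skipped. The rule is restricted to those two traits by default and is
   user-configurable.

Both rules are idempotent, and the exclusion count is non-increasing in
the multiplier *k* — both properties are tested.

**Total fungal infection** (`compute_tfi()`): TFI is the plain sum of the
six disease severity scores of a plot (stripe rust, Septoria, powdery
mildew, leaf rust, leaf tan spot, Fusarium head blight), treating
infected leaf/spike areas as additive. Under the strict default policy a
plot missing any component has a missing TFI; `na_rm = TRUE` sums what is
available. Strictness is the default because a missing severe disease
would otherwise bias TFI downward exactly where infection is informative.

# BLUEs with row and column random effects

Per trait and growing condition the model is

$$y_{irc} = \mu + g_i + R_r + C_c + \varepsilon_{irc},$$

with genotype fixed effects $g_i$, independent random row and column
intercepts for the field grid (capturing soil-fertility gradients), fitted
by REML (`lme4::lmer`, cell-means coding, optimizer tolerance 1e-8, max
200 evaluations). The BLUE of genotype *i* is $\hat\mu + \hat g_i$ — the
adjusted genotype mean on the observation scale, with $\hat\mu$ the mean
of genotype means (sum-to-zero convention). Replicate blocks are not
modelled separately: the model contains exactly the terms above.

**Variance-component screening.** A REML fit happily estimates a small
positive row or column variance from pure noise; keeping such a component
perturbs the BLUEs away from the genotype means for no gain, while a
component estimated at zero contributes nothing. Each component is
therefore retained only when a boundary-corrected restricted likelihood
ratio test supports it (statistic against the model without the
component, reference $0.5\,\chi^2_1$, alpha 0.05). If neither survives,
the fit collapses to per-genotype arithmetic means, flagged
`fallback = "means"` — the same flag used when layout is unusable (row or
column missing for more than half the plots, fewer than two levels) or
the REML fit errors. This selection, rather than a blanket
"singular-fit-means-fallback", keeps the column adjustment when only a
column gradient exists and reproduces the exact means identity when no
gradient exists; both behaviours are asserted in the test suite.

# Trait consistency (SMA)

Consistency of a trait between two growing conditions is the coefficient
of determination of a standardized major axis fit of one condition's
BLUEs on the other's, over the genotypes present in both (at least 3).
SMA is symmetric in the axes — appropriate since neither condition is a
predictor of the other. Numerically $R^2_{sma}$ equals the squared
Pearson correlation (SMA and OLS share the coefficient of
determination); slope $\mathrm{sign}(r)\,s_y/s_x$ and intercept are still
reported because the line itself is SMA. All $\binom{k}{2}$ unordered
pairs of eligible conditions are computed.

Grouping: a pair belongs to a level of a grouping iff both conditions
agree on every fixed factor (year, location and/or management); pairs
that differ on a fixed factor are dropped from that grouping. Double
groupings key on the level combination, so e.g. management–location
levels contain only pairs differing in year.

Levels are compared by one-way fixed-effects ANOVA; when the gate passes
(p < 0.05) all pairwise t tests use the pooled within-group mean square
and its degrees of freedom (unprotected Fisher LSD beyond the gate —
deliberately, as the procedure is descriptive). The compact letter
display is computed as the maximal cliques of the
not-significantly-different graph, ordered so letter "a" contains the
largest mean, ties in means broken by level name. Cliques make the
"share a letter iff not significantly different" property hold by
construction; the classical insert-and-absorb algorithm targets the same
display.

# Breeding progress

Breeding progress (BP) of a trait in a condition is the OLS slope of
cultivar BLUEs on cultivar year of release (trait units per release
year), with its two-sided p-value. The decomposition regresses, across
growing conditions (one observation each, unweighted — weighting by BP
standard errors is a documented option left off because condition BPs
enter the published analyses unweighted),

$$\mathrm{BP}_{GY} = \beta_0 + \beta_1\,\mathrm{BP}_{TGW} +
\beta_2\,\mathrm{BP}_{HI} + \beta_3\,\mathrm{BP}_{Straw} +
\beta_4\,\mathrm{BP}_{GpS} + \beta_5\,\mathrm{BP}_{SN} + \varepsilon,$$

one model per grouping level plus a pooled "all" model. Levels with fewer
than (regressors + 2) conditions are skipped; constant regressors are
dropped with a warning. Significance stars follow the 0.05/0.01/0.001
convention.

# Stability indices

On the complete genotype x environment BLUE matrix (complete cases only;
genotypes with any missing cell are dropped and counted), with row means
$\bar x_{i.}$, column means $\bar x_{.j}$, grand mean $\bar x_{..}$ and
environment effects $e_j = \bar x_{.j} - \bar x_{..}$, nine classical
indices are computed per genotype (`stability_indices()`): environmental
variance (Roemer), Finlay–Wilkinson regression slope, Eberhart–Russell
deviation mean squares, Pinthus coefficient of determination, Wricke
ecovalence, Shukla stability variance, Hanson genotypic stability (with
$b_{min} = \min_k b_k$), Lin–Binns superiority, and Nassar–Huehn
corrected-rank variance. The sources name the indices but print no
formulas; the classical definitions above are the package's documented
choice, and each is verified against an independently coded brute-force
summation oracle and against exact algebraic identities
($\sum_i W_i$ = interaction SS, $\overline{b_i} = 1$,
$\overline{\sigma^2_i}$ = interaction MS).

Numerical choices: the deviation mean squares omit the plot-error
correction term ($-s^2_e/r$) because BLUEs, not plot replicates, are the
input; with E = 2 environments $s^2_{di}$ is undefined and reported
missing, with G = 2 genotypes $\sigma^2_i$ is undefined (G ≥ 3 required).
Before ranking, corrected values are rounded to 12 significant digits so
that floating-point noise cannot break exact ties (a purely additive
matrix must rank all-tied and give $S_{i4}=0$). "Variance of rank" is
implemented as the corrected-rank variance; superscript conventions for
this family vary in the literature and the choice is recorded here.
`si_direction()` exposes, per index, whether smaller values mean more
stable.

The stability-of-yield decomposition regresses, across genotypes, each
index of yield on the same index of the component traits plus a total
fungal infection term. Whether that term should be the genotype-mean TFI
or the stability of TFI is ambiguous in the source analyses; both modes
are implemented (`tfi_regressor()`), with mean TFI the default.

# Relative importance (LMG)

For both decompositions the R² is attributed to regressors by LMG:
each regressor's sequential R² gain averaged over all orders of entry,
computed by the subset-weighted formula with exhaustive enumeration of
all $2^p$ subsets ($p \le 10$ enforced; the decompositions here use 5 and
at most 7 regressors, so sampling approximations are pointless). Shares
are nonnegative for OLS with intercept and sum to the full-model R²; the
stacked reporting emits both the R²-scale shares and shares normalised to
proportions of R², since either rendering is common.

# Field-vs-simulation correlation comparison

Trait–trait Pearson correlations (pairwise complete, at least 3 shared
observations) from a field BLUE table are compared with those from any
external genotype x trait table (a crop model's output being the
motivating case; no crop model is run). Each pair is a point
$(r_{field}, r_{sim})$; its distance to the identity line is the
perpendicular $|r_{field} - r_{sim}|/\sqrt 2$ — perpendicular because
"distance of a point to a line" is read geometrically; users preferring
the vertical reading can rescale the threshold by $\sqrt 2$. A pair is
concordant when the distance is below 0.09 and both correlations exceed
0.5 in absolute value. Field correlations pool genotype mean BLUEs across
the selected conditions; per-year correlations are a documented
alternative the user can compute by subsetting.

# The synthetic MET generator

`simulate_met()` exists so that every stage can be tested against known
truth. Per trait, a plot value is

grand mean + genotype effect + BP slope x (release year − span midpoint)
+ condition effect + management shift + genotype-x-condition interaction
+ row effect + column effect + residual,

all Gaussian; each genotype draws its own interaction sd uniformly from a
range, making "true stability" a property the stability indices should
recover (tested via rank correlation with environmental variance).
Disease scores are latent Gaussian with a resistance trend in release
year, clamped to \[0, 100\]. Genotype placement is randomised within each
replicate block of a per-condition row x column grid; row and column
gradient shapes are shared across traits and scaled by per-trait sds.
Everything is reproducible from one integer seed.

Default magnitudes are chosen so simulated values fall inside the
observed ranges of German winter-wheat trials (whole-plot yield within
0–141.6 dt/ha, TGW below 80 g) with a grain-yield BP slope of 0.37
dt/ha/year, the magnitude reported for long-term German panels;
within-plot error variances are free parameters of the config, not claims
about any real dataset. `met_design_reference()` emulates the trial
network's structure (29 of 36 year x location environments, nine
managements with irrigation only in Gross Gerau and the rain-out shelter
only in Kiel, a 220-cultivar phase-I panel with a 52-cultivar phase-II
subset, three replicates for Kiel rain-fed). The published record names
only some of the seven absent environments; the remainder of the mask is
this package's choice and the design is an emulation, not a
reconstruction. `met_design_validation()` is the balanced 45-condition
subset (3 years x 5 locations x 3 rain-fed managements) used by the demo
pipeline and the acceptance script.

What the generator does *not* emulate: weather-driven responses, spatial
autocorrelation beyond additive row/column effects, non-Gaussian trait
distributions, missing-data mechanisms correlated with treatment, and
genotype-by-management interaction beyond additive shifts. Tests passing
on synthetic data therefore demonstrate correctness of the estimators
under the stated model, not robustness to every feature of real field
data.

# Problem sizes used in the checks

The test suite and the acceptance script run the full pipeline at the
validation-subset scale (220 genotypes, 45 conditions, 2 replicates,
seven agronomic traits plus six diseases), recovery studies at 100–200
genotypes with 100–200 seeded replicates, and identity checks on
100 random 20 x 10 matrices — sizes chosen to make Monte-Carlo standard
errors small relative to the tolerances while keeping a full run in the
minutes range on one core.

# Known limitations

- Per-condition BLUE fitting treats conditions independently; no joint
  phase-II factorial model is attempted (the per-condition model is the
  one the analyses define).
- Fisher LSD is unprotected beyond the ANOVA gate; letters should be read
  descriptively.
- The LMG implementation refuses rank-deficient designs rather than
  pseudo-inverting; drop collinear columns first.
- Stability indices assume a complete matrix; heavy missingness shrinks
  the genotype set via complete-case filtering.
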