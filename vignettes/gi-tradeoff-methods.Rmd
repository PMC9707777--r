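---
title: "Quantifying cooperation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopgi)
```

## The model

A genotype's agronomic value in a dense stand is not its individual
competitive ability but its contribution to group yield, and the two are
antagonistic: traits that grab resources from neighbours raise individual
fitness while lowering the stand's total. `coopgi` quantifies this
group-versus-individual (G-I) trade-off from a two-context experiment in
which every focal genotype is measured (a) in monoculture, facing its own
strategy, and (b) in pairwise mixture with each member of a fixed tester
set spanning the population's range of strategies.

Write $x_g$ for the block-adjusted mean individual shoot biomass of
genotype $g$ across all its mixtures and $y_g$ for its monoculture biomass
per individual. Across genotypes the two are strongly positively related —
vigorous plants do well everywhere — so neither axis alone reveals
cooperation. The package fits the empirical vigor curve

$$q(t) = \beta_0 + \beta_1 t + \beta_2 t^2$$

by ordinary least squares of $y$ on $x$ and decomposes each genotype's
position into two orthogonal coordinates: the foot-point abscissa
$t^\ast_g$ (position *along* the curve, general vigor) and the signed
orthogonal distance

$$d_g \;=\; \mathrm{sign}\!\left(y_g - q(t^\ast_g)\right)
\sqrt{(t^\ast_g - x_g)^2 + \left(q(t^\ast_g) - y_g\right)^2},$$

the G-I trade-off value. $d_g > 0$ (above the curve) means the genotype
yields more in monoculture than its vigor predicts: it is cooperative.
The curve is a heuristic — its exact shape is unimportant, which is why a
quadratic suffices and why no errors-in-variables fitting is attempted;
only the *distance* is orthogonal, not the regression. A partial F test
(RSS comparison of the linear against the quadratic model, on 1 and
$n-3$ degrees of freedom) reports whether the curvature is supported.

### Numerical treatment of the foot point

The squared distance $D(t) = (t-x)^2 + (q(t)-y)^2$ has the stationarity
condition

$$\tfrac12 D'(t) = (t - x) + \left(q(t) - y\right)(\beta_1 + 2\beta_2 t) = 0,$$

a cubic in $t$ whenever $\beta_2 \ne 0$. Rather than a local descent from a
single start — which can land on the wrong branch of a curved parabola —
the cubic is solved analytically (`polyroot`), all real roots are compared
on $D$, and ties are broken toward the smaller $t$. For $\beta_2 = 0$ the
perpendicular projection onto the line is used in closed form, and the
solver approaches that limit continuously. The test suite checks the
solver against a dense grid search (step $10^{-5}$) on a thousand random
curve/point instances, and the worked case $q(t) = t^2$, point $(0,1)$:
feet at $t = \pm 1/\sqrt2$, distance $\sqrt3/2$.

The sign of $d$ is taken from the side of the curve (above/below), not
from the vertical residual $y - q(x)$; for strongly curved fits the two
can disagree for extreme points, and the curve-side convention matches the
geometric definition of the orthogonal axis. Distances are computed in raw
grams on both axes — the performance measures live on a common scale, and
standardising would silently reweight the two contexts.

### Performance estimation

$x_g$ comes from the fixed-effects model `biomass ~ block + genotype`
fitted to focal plants in mixtures, evaluated at equally weighted block
levels (the standard LS-means convention; with one block this is the
arithmetic mean). $y_g$ halves each monoculture pot total and averages
over pots. Single-plant pots and pots in which a plant died are excluded
beforehand, with a per-pot exclusion log; a pot with more than two plants
is treated as a data error, not silently truncated. A companion test
regresses focal biomass on the mean biomass of the neighbouring tester
(plus block) — strong competition shows up as a large negative slope.

## Association scan

The G-I values are scanned marker by marker: OLS of $d_g$ on the binary
dosage, F test on $(1, n-2)$ degrees of freedom, and variance explained
$r^2 = F/(F + n - 2)$. Markers with minor allele frequency strictly below
5% are removed first. Deliberately, there is **no kinship or population
structure correction**: the synthetic panel is unstructured by
construction, and mixed-model association (EMMAX-style) is out of scope.
On structured natural panels the scan as shipped will inflate; the
`covariates` argument of `gi_scan()` is the hook for supplying
pre-computed structure covariates (e.g. principal components). Missing
dosages are handled marker-wise (complete cases), the simplest defensible
rule. Marker coordinates are 1-based and chromosome-local (`chr:pos`).

Companion tests mirror the downstream biology: linear regression of a
trait on the G-I value (axes untransformed — the G-I value is centred at
zero, so log-log allometry is inappropriate); two-level allele ANOVA with
the percent effect size $100(1 - \bar m_C/\bar m_A)$; Fisher's exact test
of allele × resistance tables (2×3 tables are collapsed to susceptible
versus the rest before the 2×2 test); and one-way ANOVA of G-I values
across resistance classes.

## Density gradient

Monoculture stands sown at 9, 16 and 25 plants per 64 cm² pot lose
seedlings early, so the regressor is the *realized* area per individual
$A$ — available space — rather than density, whose relationship with
biomass is nonlinear. Pot productivity is modelled as

`biomass ~ area * allele + mixture_covariate + (1 | genotype) + (0 + area | genotype)`

with Satterthwaite-approximate denominator degrees of freedom for the F
tests (hence fractional dfs). The genotype's individual mixture
performance enters as a covariate because it was used to stratify the
genotype sample by size. Pots whose realized count exceeds the sown count
were evidently not thinned and are excluded. The response is pot-level
biomass by default, with a `per_individual` switch. Singular or failed
random-effects fits fall back to the fixed-effects model, flagged — as
does any design with fewer than four genotypes, where the random terms are
confounded with the allele contrast.

## Payoff matrices and the game structure

For near-isogenic line (NIL) pairs differing only at the focal region, the
payoff of allele $f$ against neighbour allele $n$ is the biomass
*reduction* relative to growth alone:
$\mathrm{red}(f,n) = \overline{m}_{\text{single},f} - \overline{m}_{f|n}$,
with standard error propagated as
$\sigma_{\text{payoff}} = \sqrt{\mathrm{sem}^2_{\text{single}} +
\mathrm{sem}^2_{f|n}}$ (the $\sigma$ terms are standard errors of the two
means — the quantity propagated is a difference of means). Monoculture
pots contribute both plants to the same-allele cell and mixture pots each
plant to its own cell; pooling of monocultures into the diagonal cells is
the default and can be disabled. On the benefit scale
($-\mathrm{red}$), Temptation $T$ = compete-vs-cooperate, Reward $R$ =
cooperate-vs-cooperate, Punishment $P$ = compete-vs-compete, Sucker's
payoff $S$ = cooperate-vs-compete; `classify_game()` reports
`prisoners_dilemma` iff $T > R > P > S$, `neutral` for a constant matrix,
and the observed ordering string otherwise. Root browning scores (ordinal
0/1/2) are modelled with a proportional-odds cumulative-logit regression
on community type, background and allele, mixtures excluded; the allele
coefficient's Wald test is reported.

## The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which the pipeline is validated. Genotype $g$ carries a latent vigor
$v_g \sim \mathcal N(\mu_v, \sigma_v^2)$ (truncated at $0.1\mu_v$;
defaults 1.0 and 0.15 g), a causal allele $a_g \sim
\mathrm{Bernoulli}(0.18)$, and a competitiveness
$s_g = s_0 - \gamma_a a_g + \mathcal N(0, \sigma_s^2)$ with $s_0 = 0.5$,
$\gamma_a = 0.3$, $\sigma_s = 0.1$: the minor allele lowers
competitiveness, i.e. it is the cooperative allele. A plant's shoot
biomass is

$$b = \mathrm{sat}\!\left(v + \theta_\text{self}\, s -
\theta_\text{neigh}\, s_\text{neigh} + \text{block} +
\varepsilon\right),\qquad
\mathrm{sat}(u) = \frac{b_{\max} u}{b_{\max} + u},$$

with $\theta_\text{self} = 0.2 < \theta_\text{neigh} = 0.4$ — a plant's
competitiveness costs its neighbour more than it earns itself, the
tragedy-of-the-commons structure that makes cooperative monocultures
outyield competitive ones while cooperative individuals lose in mixtures.
The concave saturating map (ceiling $b_{\max} = 2$ g) produces the
curvature of the vigor relation that motivates the quadratic heuristic;
any concave increasing map would do, and the Michaelis–Menten form is the
simplest. Residual noise is $\sigma_e = 0.05$ g per plant, independent
across plants (the within-pot covariance is not specified by the design
the generator emulates, so independence is assumed); block 2 sits
$-0.05$ g below block 1.

Design: the panel holds `n_tester` dedicated testers plus `n_focal` focal
genotypes (defaults 10 and 98). Per block, each focal genotype gets one
monoculture pot and one mixture pot with every tester, so the two-plant
pot count is exactly `n_blocks * n_focal * (n_tester + 1)`; testers are
additionally grown once per block as single plants, which the filter then
excludes — keeping the exclusion path exercised. Genotypes are inbred
lines, so marker dosages are binary; the causal marker sits at coordinate
`3:15294955` among 999 null markers with frequencies drawn from
$\mathrm{U}(0.05, 0.5)$, independent of the phenotype. Root biomass is
shoot biomass times a root-to-shoot ratio (baseline 0.25, lognormal noise)
that is 19% lower in cooperative-allele carriers — the effect size the
package's trait tests are exercised against.

The density generator applies a crowding response $A/(A + A_0)$ with
$A_0 = 3$ cm² to the per-plant biomass $v + (\theta_\text{self} -
\theta_\text{neigh}) s$, kills each sown seedling with probability 0.1,
and samples six cooperative-allele genotypes matched by vigor with seven
alternative-allele genotypes, four replicate pots per genotype × density.
The NIL generator grows four backgrounds × two alleles as singles,
monocultures and mixtures (16/16/32 pots); competitive-allele plants in
susceptible backgrounds (33RV113 strongly, 33RV142 mildly — penalties 0.4
and 0.15 g) lose biomass under competition, which is what breaks the
prisoner's-dilemma ordering there. Root scores are drawn from a
cumulative-logit model with an allele shift of 1.5 log-odds. Each table
runs on its own seed offset (panel +0, competition +1, density +2, NIL
+3), so any table can be regenerated independently; identical seed and
configuration give bit-identical tables.

What the generator does *not* emulate: spatial arrangement within trays,
growth over time, flowering, kinship structure among genotypes, linkage
between markers, within-pot noise correlation, and any pathogen dynamics
beyond a static biomass penalty. Passing tests therefore demonstrate that
the estimators recover the quantities this generative model encodes — not
that real greenhouse data meet the model's assumptions; in particular the
scan's calibration on structured natural panels is untested by design.

## Choices a user may want to revisit

- **MAF threshold** 0.05, strict inequality (a marker at exactly 5% is
  kept).
- **Sign convention**: $d > 0$ above the curve. If your performance axes
  are swapped, cooperation flips sign.
- **Foot-point tie-break** toward smaller $t$; ties occur only on the
  symmetry axis of the parabola, a measure-zero set.
- **Monoculture pooling** into diagonal payoff cells (default on).
- **Density response** per pot (default) or per individual.
- **Block weighting** in LS means: equal weights across blocks.

## Problem sizes

The shipped tests run the full decomposition and scan on panels of up to
200 focal genotypes with 1,000 markers (twenty replicate seeds), null
calibrations with 200 replicates per test, and a thousand random
curve/point instances against the grid-search oracle; the acceptance
script regenerates the default 98-genotype study end to end. These sizes
give stable Monte-Carlo behaviour for every check while keeping a full
run in the low minutes on one core; all of them scale linearly if larger
panels are wanted.

## Known limitations

- No kinship correction in the scan (see above); the hook is the
  `covariates` argument.
- The quadratic heuristic is global; a panel whose vigor relation is
  non-monotone over the observed range would need a different curve
  family, though the orthogonal-distance machinery is agnostic to it.
- Payoff SEMs for cells with a single observation are reported as `NA`
  rather than guessed.
- The tester-effect test fits no genotype term, so with large
  genotype-level variance it is conservative (its null calibration is
  exact when residuals are exchangeable across pots).
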