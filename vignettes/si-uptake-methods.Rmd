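---
title: "Modelling actor influence on sustainable-intensification uptake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling actor influence on sustainable-intensification uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siuptake)
```

## The problem

In peri-urban agricultural landscapes, whether farmers take up
sustainable-intensification (SI) measures — maintaining small landscape
elements (SLEs), farm-level efficiency measures, direct sales — depends not
only on farm economics but on the web of actors around the farm: retail and
purchasers, labels, consumers, the farmers' peer network, farmer
organizations, the province, and national/EU government. `siuptake`
implements a quantitative pipeline for studying this: a weighted social
network of actor influence, discrete Bayesian belief networks (BBNs) for the
dairy and fruit sectors that chain actor attitudes through advice and
intention to realized uptake, and a scenario suite that asks which coalitions
of actors enable or block uptake.

The original farm-level data (interviews, farm accountancy records, CAP
payment records, parcel maps) are confidential, so the package is driven
entirely by a synthetic farm population whose *structure* — sector counts,
characteristic marginals, spatial location classes — reproduces the reported
summary tables. Passing tests therefore demonstrate that the *methods* behave
as documented on a population with the reported structure; they say nothing
about confidential farm-level microdata.

## The synthetic farm population

The default configuration generates 284 dairy farms and 71 fruit growers (the
27 arable farms of the study area are excluded from all analyses). Six
characteristics are assigned per farm: intrinsic attitude, age class,
innovativeness, successor, farm-size class and location class, with
per-sector marginals taken from the reported baseline table. Rows of that
table that do not sum to 100% (e.g. the fruit location row) are renormalized
ratio-preserving, with a warning; we treat the printed values as containing
rounding/typographic slips and preserve their ratios.

Two sampling modes exist. **Quota** mode (the default) apportions class
counts by largest remainder, so every marginal is matched to within 1/n at
any population size, and assigns exactly `round(0.10 * n)` farms per sector
as intrinsically innovative (the stakeholder-elicited 10%). Ties in the
largest-remainder step are broken by class order as listed. **Bernoulli**
mode draws every class independently per farm and is retained for stochastic
studies; over repeated seeds its empirical marginals are unbiased.

Farm sizes are drawn uniformly within size-class hectare bands (dairy: 5–25,
25–60, 60–120 ha; fruit: 1–10, 10–25, 25–60 ha). The reported procedure
derives hectares from the basic CAP payment at €260/ha; the bands were chosen
once as plausible Dutch sector ranges — within-class distribution is not
reported. `farm_size_from_payment()` provides the exact €260/ha conversion.

Coordinates are a seeded scatter around configurable village centers: each
farm is placed at a distance drawn from its location class's band (0.5–2.5,
6–9, 13–17 distance units) at a random bearing. The default centers are
mutually far apart so the sampled center is always the nearest. Location
classes are then *re-derived* with Jenks natural breaks (Fisher's optimal
1-D classification, implemented as an exact dynamic program) on
distance-to-nearest-center, exactly as the reported procedure classifies
distance; because the bands are well separated the Jenks classes coincide
with the quota assignment. Real geography (parcel maps, cartogram mass
allocation) is out of scope; the coordinates only support Fig.-style mapping
of per-farm scenario differences.

Initial direct-sales status is assigned preferentially to close-to-village
farms (odds multiplier, default 2), reflecting the observed pattern that
direct-sale farms sit closer to villages. Default initial uptake levels are
the observed adoption shares (dairy 29% SLE / 11% direct sales; fruit 14% /
9%).

```{r population}
pop <- generate_farm_population()
table(pop$sector)
round(prop.table(table(pop$location_class[pop$sector == "dairy"])), 3)
```

## Influence network indicators

Actor-on-actor influence per topic is ordinal: none / low (advisory) / high
(e.g. financial dependency) / mandatory. We code these 0/1/2/3 — an
equal-step ordinal coding, configurable — with `none` meaning no edge.
Indicators per actor are the weighted indegree and outdegree (influence
experienced / exerted) and unnormalized betweenness, counting ordered
source–target shortest paths through the actor with fractional credit for
ties. Shortest paths are hop counts on the unweighted digraph: the influence
weights are ordinal intensities, not distances, so using them as path costs
would be meaningless.

The empirical matrix is in unavailable supplementary material. The package
ships a clearly-labelled *synthetic* stand-in
(`extdata/influence_matrix_synthetic.csv`) constructed to match the reported
qualitative findings — farmers hold the highest weighted indegree on every
topic, and on direct sales also the highest outdegree and betweenness — and
the tests assert those orderings, not exact values.

## The belief-network engine

`bbn()` represents discrete networks with named states and CPT rows ordered
with the first-listed parent varying fastest. `infer_marginal()` performs
exact inference by variable elimination with barren-node (ancestral) pruning
and a min-degree elimination heuristic; correctness is independent of the
order, which the tests verify by randomizing it. `enumerate_joint()` is a
deliberately naive full-joint reference implementation used as the oracle.
Probabilities are kept in linear space — the networks here are small (24
nodes, ≤ 3 states) and far from underflow; CPT normalization is checked to
1e-9. Soft evidence is implemented as prior replacement on root nodes, which
is exactly what scenario runs need (group attitudes are distributions over
root actor nodes); likelihood-style virtual evidence on internal nodes is
not supported.

## The sector SI model

Each sector network has 24 nodes: 7 actor roots (Labels has no unsupportive
state and a 50/50 supportive/neutral prior; the Consumers prior is
sector-specific; all others uniform), 6 characteristic roots with the
sector marginals, Subsidies and Regulations nodes (children of Province and
NL&EU), and per measure an advice, an intention and an uptake node.

**Advice elicitation.** The reported scheme quantifies actor influence by
rank: the top-ranked actor sets a baseline, lower-ranked actors modify it in
rank order. We implement this as

$$P(\text{advice}^+\mid a_1,\dots,a_K) \;=\;
\Big[\, b(a_1) + \textstyle\sum_{k\ge 2}\operatorname{sign}(a_k)\,
\delta\,\gamma^{\,r_k-2}\Big]_\varepsilon^{1-\varepsilon}$$

with sign(supportive/neutral/unsupportive) = +1/0/−1, baseline
$b = b_n \pm s$ for supportive/unsupportive top actors (spread $s = 0.3$),
modifier magnitude $\delta = 0.08$, geometric rank decay $\gamma = 0.7$, and
clamping bound $\varepsilon = 0.02$. The rank table reconstructed from the
reported importance ranking contains tied ranks (e.g. retail and labels for
SLEs); tied actors each contribute the decay weight of the shared rank, and
only the baseline (rank-1) actor must be unique. The farmers' rank is carried
by the Network node and farmer organizations by NGOs, matching the node
roster of the belief network; NGOs belong to the external/informal groups
only, so they sit at neutral in market/government scenarios. $\delta > 0$
makes advice monotone in every actor's attitude, a property the tests sweep.

**Intention.** A full CPT over 7–8 parents is infeasible to elicit, so the
intention CPT is generated by an additive log-odds (logistic) rule:
advice (±`advice_weight`), the policy context (Subsidies, Regulations — for
the SLE and efficiency measures), and the characteristics with non-negative
weights: intrinsic attitude (weight 1.0, the strongest, per the stakeholder
statement that intrinsic attitude dominates outside influence),
innovativeness 0.5, young age 0.4, successor 0.2, farm size 0.3, and — for
direct sales only — closeness to villages 0.5. These weights encode the
qualitative elicitation (young farmers and farmers with a successor more
likely to implement; larger farms more likely; direct sales favoured close to
villages); their exact magnitudes are free parameters of the package, held
fixed across sectors.

**Uptake.** Intention and uptake marginals differ in the reported baseline,
but no mechanism is given; we use a two-probability link,
$P(\text{uptake}\mid \text{intention}^{+}) = \pi_1$ and
$P(\text{uptake}\mid\text{intention}^{-}) = \pi_0$ with
$\pi_0 = 0.25\,\pi_1$, so the uptake marginal is the convex combination
$\pi_0 + (\pi_1 - \pi_0) P(\text{intention}^{+})$.

**Policy nodes.** Subsidies and Regulations tilt their printed target
distribution toward the favourable end by the mean attitude of Province and
NL&EU (exponential tilting, strength 0.8). The reported table prints
Regulations separately per measure with nearly identical rows; the model uses
a single Regulations node whose target is the mean of those rows, keeping the
documented 24-node structure.

**Calibration.** Nine printed baseline marginals per sector (advice,
intention, uptake × three measures) are calibration targets.
`calibrate_si_network()` solves them by coordinate search with local
refinement, measure by measure: the per-measure advice baseline $b_n$ by
grid bracketing plus root-finding on the exact marginal (monotone in $b_n$),
then the intention intercept the same way on the assembled network, then
$\pi_1$ in closed form from the achieved intention marginal. This reproduces
all nine targets to machine precision (tolerance for acceptance: 0.01, the
table prints whole percentages), never increases the initial loss, and
returns the initial parameters untouched when they already fit.

```{r calibrate}
cal <- calibrate_si_network("dairy")
cal
do.call(rbind, cal$achieved)
```

## Scenario analysis

The sensitivity suite holds the four reported groupings: external vs local,
government vs market, informal vs formal (four combinations each, following
the block pattern X unsupportive/Y neutral, X unsupportive/Y supportive,
X supportive/Y unsupportive, X supportive/Y neutral) and the two all-actor
runs — fourteen scenarios. Actors in no assigned group stay neutral, which
keeps their *baseline* prior (for Labels and Consumers these are not
uniform, so neutral preserves the baseline attitude rather than forcing a
uniform one). Supportive/unsupportive assignments are degenerate hard states;
Labels, which has no unsupportive state, remains at baseline when a group it
belongs to is set unsupportive.

Percent change is relative: $100 (p_s - p_0)/p_0$ against the calibrated
model's own baseline uptake by default; an external observed-adoption
baseline can be substituted (the reported table is ambiguous about which
baseline its percentages reference, and about relative vs percentage-point
changes — both choices are exposed). Change vectors are classified S+ (all
three increase), S− (all decrease), T (otherwise mixed), with an exact zero
vector mapped to a `none` sentinel: reported T rows contain 0% entries, so
zeros inside a mixed vector do not block T, and a vector like (+, +, 0) is
classified T rather than S+ because not all indicators increase.

The reported percentage magnitudes depend on the unavailable supplementary
CPT quantification and are deliberately not calibration targets; what the
package reproduces is the direction structure — all-supportive is a synergy
for both sectors, all-unsupportive a dairy S− — plus the full monotonicity
property: for every sector, measure and observable characteristic
combination, uptake under all-supportive ≥ baseline ≥ all-unsupportive.

`spatial_impact()` maps the all-supportive minus all-unsupportive uptake
difference per farm (evidence: location, size, age, successor,
innovativeness; computed once per unique combination) onto the synthetic
coordinates and writes GeoJSON for mapping.

```{r scenarios}
run_scenario_suite(cal$net, make_scenario_suite()[13:14], sector = "dairy")
```

## Efficiency adoption score

The efficiency (FoA2) uptake proxy scores 12 accounting-derived measures: a
farm adopts a measure when its value, on the favorable scale, is at or
beyond the lower 10% quantile of all farms in the reference table (boundary
counts as adoption — the decile is "a threshold" below which farms are
non-adopters). The quantile uses linear interpolation between order
statistics (type 7); the reported procedure does not specify a definition,
and the choice is configurable. Each measure carries an orientation flag
because some measures are favorable when low (input intensities); the
identities of the 12 real measures are not public, so the default set is a
named synthetic placeholder. By construction the decile rule marks ≈90% of
reference farms as adopters per measure, so the synthetic accounting
generator defaults to adopter prevalence 0.9 with a component shift of 4
within-component standard deviations; recovery of arbitrary prevalences is
exercised with explicit mixture-midpoint thresholds instead. The reported
national averages (2.6 fruit / 4.3 dairy measures) come from restricted
microdata and are out of scope; only the procedure is validated, on synthetic
tables.

## Numerical choices and problem sizes

* Marginal normalization tolerance 1e-9; CPT validation likewise.
* Jenks classification: exact dynamic program; ties in the within-class SSE
  broken toward the earlier split; equal test-oracle losses are compared at
  1e-9.
* Calibration root-finding tolerance 1e-7 on marginals; 25-point bracketing
  grids on the clamped probability range.
* Test problem sizes were chosen for desk-scale runs: inference oracles use
  100 random networks of ≤ 7 nodes; network-indicator oracles use digraphs of
  ≤ 8 nodes; scoring recovery uses 2 000 farms; the Bernoulli bias check uses
  200 seeds × 284 farms.
* All generators take explicit integer seeds and restore the caller's RNG
  state; seeds are recorded on the population object.

## Known limitations

* The reconstructed rank table and the advice/intention functional forms are
  the package's own quantification; the original CPTs are unavailable, so
  reported scenario *magnitudes* are not reproducible and non-monotone
  reported responses (e.g. a fruit efficiency increase under all-unsupportive
  actors) lie outside this monotone model class by design.
* The exact edge set of the original network figure is not fully enumerable
  from the text; the assembly rule here (whether size feeds intention rather
  than advice, etc.) is the documented reconstruction.
* Soft evidence is restricted to root-node prior replacement.
* Synthetic coordinates emulate distance structure only — no roads, parcels
  or accessibility surfaces.
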