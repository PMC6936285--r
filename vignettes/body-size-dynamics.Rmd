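---
title: "Methods: body-size dynamics of belemnite assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: body-size dynamics of belemnite assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(belemsize)
```

## The problem

Body-size reduction is one of the canonical biotic responses to rapid
warming, both in modern oceans and across hyperthermal crises in the fossil
record (the "Lilliput effect"). For extinct cephalopods such as belemnites,
the observable is a stratigraphic series of rostrum measurements: bulleted
calcite internal skeletons collected bed by bed through a section, each
specimen assignable (when sufficiently complete) to a taxon and an
ontogenetic stage. The scientific difficulty is that an assemblage-level
median size can fall for very different reasons — large taxa leaving, small
taxa arriving, juveniles becoming relatively more common, or genuine
within-lineage dwarfing — and only the last is the Lilliput effect *sensu
stricto*. `belemsize` implements the full chain of analyses needed to
separate these mechanisms and to relate the surviving signal to
environmental proxies.

## Size proxy

Each complete rostrum contributes a geometric-mean size
$\mathrm{GM} = (D_v \cdot D_l \cdot l)^{1/3}$ (apical dorsoventral height,
apical lateral width, length; all mm), a unidimensional proxy that is robust
to shape differences between taxa and stages. $\mathrm{GM}^3$ serves as a
rostrum volume proxy; on the log-ratio percent scale used throughout
(`proportional_change()` returns $\ln(m_{t+1}/m_t)\times 100$), a GM change
maps to exactly three times itself on the volume scale, which is why
magnitudes above 100% are legal and meaningful. Fragments never enter size
analyses; they count only toward per-square-metre abundance from the quadrat
collections.

## Shift testing

Between consecutive occupied beds the package reports the median log-ratio
change plus two-sided Mann–Whitney U and Kolmogorov–Smirnov p-values.
Because per-bed samples are small and heavily tied (calliper-resolution
measurements), both p-values are computed **exactly** under the permutation
null whenever $n \cdot m \le 10\,000$: the null distributions are built by
dynamic programming over tied-value groups with binomial multiplicities
(integer arithmetic throughout — doubled midranks for MW, the integer
numerator $|im - jn|$ for KS), which is equivalent to exhaustive enumeration
of all $\binom{n+m}{n}$ label assignments without ever enumerating them.
Above that size the tie-corrected normal approximation (with continuity
correction) and the asymptotic two-sample KS distribution take over. A bed
pair is called *significant* only when **both** tests fall below
$\alpha = 0.05$; no multiple-testing correction is applied across pairs
(each pair is a separate geological question), and per-test p-values are
always emitted so users can apply either rule. Degenerate pairs (all pooled
values identical) return $p = 1$ and are flagged.

## Decomposing a shift

For beds $t \to t+1$ with boundary-crosser set $C$ (taxa with at least one
complete specimen in both beds; the literal placeholder `"indet"` can never
cross), the assemblage median shift telescopes into

* disappearance: $\tilde x_C^{(t)} - \tilde x_{\mathrm{all}}^{(t)}$
* within-lineage: $\tilde x_C^{(t+1)} - \tilde x_C^{(t)}$
* appearance: $\tilde x_{\mathrm{all}}^{(t+1)} - \tilde x_C^{(t+1)}$

whose sum is the total shift *identically* — provided the medians are taken
over pooled individual specimens of each taxon set, which is the only
reading under which the identity holds and is therefore the one
implemented. Shares are signed (an effect opposing the total is negative)
and sum to 100% whenever the total exceeds $10^{-12}$ mm; below that they
are reported as undefined rather than allowed to explode. A `scale = "log"`
flag decomposes median log-GM instead; the default is the mm scale of the
defining equations.

## Ontogenetic structure and the hypothesis ladder

Juvenile proportions per bed carry 95% Wilson score intervals — chosen for
their behaviour at the n of a typical bed (no zero-width collapse at 0
or 1); indeterminate-stage specimens are excluded from both numerator and
denominator rather than imputed. The mechanism ladder for a bed pair is:

* **H1** assemblage size shift (MW + KS on all GM values),
* **H2** composition shift (two-proportion tests of relative frequency for
  the most abundant taxa, fragments included since field frequencies count
  them),
* **H3** within-taxon shift (per boundary crosser),
* **H4** intraspecific adult shift (H3 restricted to adults),
* **H5** stage-structure shift (two-proportion test on the juvenile
  fraction).

Verdicts are directional, following the hypotheses themselves: H1/H3/H4
require a significant *decrease*, H5 a significant *increase* in the
juvenile fraction, and H2 a significant frequency change consistent with a
shift toward smaller taxa (a below-median taxon rising or an above-median
taxon falling). Two-proportion tests use the pooled-variance z-test with
continuity correction, replaced by Fisher's exact test when any expected
cell is below 5. All five hypotheses are always evaluated and reported;
subsets too thin to test are marked `insufficient_data`. Note that parts of
the literature number the intraspecific adult hypothesis inconsistently (H4
vs H5); here H4 is the adult shift and H5 the stage-structure shift.

## Variation partitioning

With a univariate response (GM), partial-RDA variation partitioning across
taxonomy, ontogeny and bed separation reduces *exactly* to
inclusion–exclusion over the adjusted $R^2$ (Ezekiel adjustment) of the
seven subset regressions on treatment-coded dummies, so the package runs
those regressions directly instead of routing through an ordination engine;
`vegan::varpart` agrees to numerical precision and stands as a cross-check
in the test suite. Reference levels are the most frequent factor level
(lexicographic tie-break). Aliased columns — e.g. a taxon confined to a
single bed, which the default synthetic scenario deliberately contains —
are absorbed by projecting onto the design's column space and adjusting by
its effective rank, the standard behaviour of partitioning software.
Negative fractions are reported as computed, never clamped. Significance:
unique (conditional) fractions are tested by permuting residuals of the
reduced two-factor model, marginal single-factor models by permuting the
response; $p = (1 + \#\{ \text{perm} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$
with 999 permutations by default, observations canonically sorted by
specimen id first so input order cannot change the result. The three-way
joint fraction has no valid permutation test and requesting one is an
error. Both analysis windows of interest — the whole series and a single
(event) bed pair — are first-class.

## Environmental drivers

The driver analysis regresses per-specimen GM (optionally first
residualized by OLS on bed lithology and quadrat-derived absolute
abundance, the two sedimentary nuisances) on per-bed proxies: d18O
(palaeotemperature), d13C_carb (carbon-cycle state) and Hg/TOC
(volcanogenic outgassing). Seven fixed candidate models — the null, the
three single-proxy and the three two-proxy combinations — are fitted by
**maximum likelihood under AR(1) errors** along the stratigraphic ordering
(specimens sorted by bed `order_index`, then `specimen_id`; the within-bed
sub-ordering is a documented deterministic convention, and on synthetic
data coefficient estimates are insensitive to it at well below one standard
error). For fixed $\rho$ the Prais–Winsten transform whitens the series and
the exact Gaussian log-likelihood is profiled over $\rho \in (-0.999,
0.999)$ by bounded scalar optimization to $10^{-8}$; estimates at the
boundary are flagged. The parameter count $k$ includes intercept, slopes,
$\rho$ and the residual variance, kept consistent across candidates so that
AICc differences are well defined; $\Delta$ is always computed against the
global minimum over all candidates including the null, ties broken by fewer
parameters then lower model id, and models with $\Delta < 2$ are retained.
The best model is tested against the null by likelihood ratio
($\chi^2$ with df = difference in fixed-effect terms). Collinearity
screening (pairwise Pearson $|r| \ge 0.7$ flags) is advisory only: the
candidate set is fixed, and a flagged pair simply warns that its joint
model cannot separate the two effects.

A structural caveat worth knowing: when the truth is a single-proxy model,
its two-proxy supersets beat it by AICc with probability
$\approx P(\chi^2_1 > 2.07)$ *each*, purely by chance and independently of
effect size or sample size, so the true model is the unique top model in
only ~72% of replicates even under ideal conditions. A selection-consistency
claim should therefore be phrased as "a model carrying the true proxy wins"
(which happens essentially always at moderate effect sizes), not "the exact
true model wins ≥ 90% of the time".

## The synthetic section generator

`simulate_section()` emulates the data structure the analyses assume: an
ordered sequence of beds; per-bed quadrat sampling (Poisson counts per
species, fragments included) plus a fixed number of off-quadrat complete
specimens allocated by species abundance; lognormal sizes
$\log \mathrm{GM} \sim N(\log\mu_s + \beta_s \cdot \mathrm{d18O}(b) +
\delta_s \cdot \mathrm{juvenile}, \sigma_s)$; and AR(1) proxy series around
configurable mean paths. d18O enters directly, so $\beta_s > 0$ means a
negative (warming) excursion shrinks the species. Measurement triples are
back-solved from the drawn GM with fixed per-species aspect ratios, so the
morphometric layer is exact by construction. Ground truth — per-bed
population medians, decomposition components (via numeric quantile
inversion of the lognormal mixtures, tolerance $10^{-10}$, species weighted
by expected complete-specimen counts), species' $\beta$ values and juvenile
fractions — is derived in closed form from the configuration and the
realized proxy series, which is reproduced deterministically from the seed.

The default scenario (`peniche_like_config()`) mirrors the shape of a
classic Lower Jurassic crisis section: 13 beds across three ammonite-zone
labels, 7 species with two dominants (~60%/25%), a warming excursion of
−1 ‰ d18O at beds B4→B5 driving constructed within-lineage log-GM shifts
of −0.17 and −0.07 in the dominants and +0.08 in a small hastitid-like
taxon, rare-taxon range truncations away from the boundary, a barren
interval (B11–B12) and a depauperate resurgence bed (B13). Composition and
stage structure are constant across the boundary pair, so the constructed
truth supports H1/H3/H4 and not H2/H5. Two choices are deliberately more
generous than a typical field collection and are stated here as design
decisions: within-stage $\sigma = 0.12$ log units (consistent with the very
small within-taxon p-values real adult series produce at modest n), and a
5× abundance multiplier on the two boundary beds (condensed, highly
fossiliferous event horizons), sized by an a-priori power analysis so that
the constructed contrasts are recovered with high probability in a single
seeded run. What the generator does **not** emulate: taphonomic
time-averaging, within-bed spatial patchiness, growth-trajectory
(sclerochronological) structure, or measurement error on the triples — so
passing recovery tests demonstrates correctness of the statistical
machinery under the stated model, not robustness to those real-data
complications.

## Numerical conventions and degenerate inputs

* Medians of even samples: mean of the two central order statistics;
  quartiles are type-7.
* Summaries with $n < 5$ are flagged `low_n` rather than suppressed; bed
  pooling (`pool_beds()`, contiguity-checked, proxies averaged over
  members) is the intended remedy.
* Pooled-bed metadata: lowest member's `order_index`, height, zone,
  lithology; summed `n_quadrats`.
* Proxies sampled at their own stratigraphic heights are matched to beds by
  nearest height, ties to the lower sample (`assign_proxies()`); this is a
  package convention, stated because no universal field rule exists.
* Missing values are empty CSV cells (also accepted: `NA`, `NaN`); missing
  numerics are never silently zero.
* Errors are classed (`belem_schema_error`, `belem_validation_error`,
  `belem_referential_error`, `belem_domain_error`) and name the offending
  column, bed or taxon.

## Problem sizes used by the shipped tests

The test suite exercises the telescoping identity on 1,000 fuzzed bed
pairs; exact-test equivalence against brute-force enumeration for all
sample-size pairs with $n + m \le 8$ (200 datasets); GLS-AR(1) recovery at
$n = 400$ over 100 replicates; selection consistency at $n = 300$ over 100
replicates; Wilson coverage with 10,000 binomial draws; and one full
pipeline run of the default scenario with 999 permutations. These sizes
were chosen to give stable Monte Carlo estimates while keeping a complete
run of the suite in the minutes range on a single core.

## Known limitations

* The hypothesis battery tests each taxon/scope at $\alpha$ without a
  family-wise correction, mirroring standard practice in this literature;
  the emitted table lets users apply their own.
* The AR(1) ordering treats same-bed specimens as consecutive observations
  with equal proxy values; alternative orderings change coefficients by far
  less than a standard error on synthetic data, but an exchangeable-within-
  bed error structure would be the natural next refinement.
* Wilson intervals at small n are conservative at some $(n, p)$ — their
  exact coverage at $n = 20, p = 0.3$ is 0.975 — which is the price of
  never collapsing at the boundaries.
* Abundance is raw density per square metre; no rarefaction and no
  time-calibration of beds is attempted.
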