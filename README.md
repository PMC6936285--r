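# belemsize

Body-size dynamics of belemnite assemblages across stratigraphic sections.

Fossil assemblages routinely shrink through environmental crises, but an
assemblage-level size drop can come from entirely different mechanisms:
large taxa disappearing, small taxa appearing, juveniles becoming more
common, or genuine within-lineage dwarfing (the Lilliput effect *sensu
stricto*). `belemsize` is for palaeobiologists who have bed-by-bed rostrum
measurements (one row per specimen: taxon, ontogenetic stage, completeness,
three linear measurements in mm, quadrat membership) plus per-bed
environmental proxies, and want the full statistical chain:

* **Size proxy** — geometric mean `GM = (Dv · Dl · l)^(1/3)` per complete
  specimen, with `GM^3` as a volume proxy; changes are expressed as
  percentages of the log ratio, `ln(m_t+1 / m_t) × 100`.
* **Shift tests** — per-bed medians and Mann–Whitney U / Kolmogorov–Smirnov
  tests between consecutive beds, computed *exactly* under the permutation
  null (ties included) for small samples.
* **Shift decomposition** — each assemblage median shift splits identically
  into disappearance + within-lineage + appearance components built from
  the boundary-crossing taxa:
  `total = [med(crossers,t) − med(all,t)] + [med(crossers,t+1) −
  med(crossers,t)] + [med(all,t+1) − med(crossers,t+1)]`.
* **Ontogeny** — juvenile proportions with Wilson intervals and a
  hierarchical hypothesis ladder H1–H5 (assemblage shift, composition
  shift, within-taxon shift, adult intraspecific shift, stage-structure
  shift).
* **Variation partitioning** — unique and joint adjusted-R² fractions of
  size variation across taxonomy, ontogeny and bed separation, with
  permutation tests.
* **Environmental drivers** — seven candidate GLS models with AR(1) errors
  (ML, exact profile likelihood over rho) relating size to d18O, d13C and
  Hg/TOC proxies, ranked by AICc with a Δ < 2 retention rule.
* **Synthetic sections** — a generator with closed-form ground truth for
  validating the entire pipeline.

## Worked example

Run the bundled 13-bed, 7-species synthetic crisis scenario and interrogate
its constructed event horizon (beds B4 → B5):

```r
library(belemsize)

cfg <- peniche_like_config()       # seed 1 by default; fully deterministic
sim <- simulate_section(cfg)
obs <- size_observations(sim$dataset)

consecutive_shifts(obs, sim$dataset$beds) |> subset(bed_from == "B4")
#>  bed_from bed_to      scope pct_change_logratio p_mannwhitney         p_ks
#>        B4     B5 assemblage           -10.56375  0.0001044718 9.705386e-05
#>  n_from n_to significant low_n
#>     270  298        TRUE FALSE
```

The assemblage median falls by 10.6% on the log-ratio scale (≈ 32% in the
volume proxy, via `gm_to_volume_change()`), and both two-sample tests call
the change significant. Is it turnover or dwarfing?

```r
decompose_shift(obs, "B4", "B5")
#> <shift_decomposition> B4 -> B5 (mm scale)
#>   total -1.4430 = disappearance 0.0000 + within -1.4430 + appearance 0.0000
#>   shares (%): disappearance -0.0, within 100.0, appearance -0.0
#>   boundary crossers: Hastitidae sp. C, Parapassaloteuthis-like sp. E,
#>     Passaloteuthidae sp. B, Passaloteuthidae sp. D, Pseudohastitidae sp. A
```

The entire 1.44 mm median drop is a within-lineage effect — exactly what the
generator constructed (a −1 ‰ warming excursion in d18O acting on the
dominant species). The hypothesis ladder agrees, and rejects the
composition and stage-structure mechanisms:

```r
hypothesis_battery(sim$dataset, "B4", "B5")
#> <hypothesis_battery> B4 -> B5 (alpha = 0.05)
#>   H1: supported
#>   H2: not_supported
#>   H3: supported
#>   H4: supported
#>   H5: not_supported
```

The full pipeline — every stage, CSV outputs, a markdown report — is one
call (or `inst/scripts/run_pipeline.R` from a shell):

```r
res <- run_all(cfg, "results/", seed = 42, n_perm = 999)
```

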