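---
title: "Agreement analysis between semi-quantitative allergen panel analyzers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agreement analysis between semi-quantitative allergen panel analyzers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastagree)
```

## The problem

Multiple allergen simultaneous tests (MAST) are immunoblot panels that
measure specific IgE against dozens of allergens from one serum sample and
report each as a semi-quantitative class 0–6. No analyzer is a reference
method: allergen source materials, extraction and detection chemistry all
differ by manufacturer, so a new instrument is evaluated by *agreement* with
an established one, not by sensitivity against truth. `mastagree`
implements that comparison design: the unit of analysis is the matched pair —
one (patient, allergen) with readings from both analyzers on the same
serum — and everything downstream is computed from the paired 2×2 table
after dichotomization.

## The statistics

With cutoff class $t$ (a class $\ge t$ is positive; $t = 2$ is the
clinical convention, since class 1 is often read as insufficient clinical
significance), each matched pair falls into one cell of a 2×2 table with
counts $n_{++}, n_{+-}, n_{-+}, n_{--}$ and $N$ their sum:

* **Total agreement** $= (N - n_{+-} - n_{-+}) \cdot 100 / N$.
* **Concordant positive rate (CPR)** $= n_{++} \cdot 100 / N$ — a guard
  against agreement driven purely by shared negatives, which dominates when
  an allergen is rare.
* **Cohen's kappa** $\kappa = (p_o - p_e)/(1 - p_e)$ with $p_o$ the observed
  and $p_e$ the chance agreement from the marginals. $\kappa$ is
  **undefined** exactly when $p_e = 1$ (all pairs concordant in one
  category); the package returns `NA`, never a silent zero, matching the
  "NA" cells of published comparison tables.
* **Kappa SE and CI**: the delta-method (Fleiss–Cohen–Everitt) large-sample
  standard error, with a normal interval $\kappa \pm z \cdot SE$. The bounds
  are deliberately *not* truncated to $[-1, 1]$: published comparison tables
  print upper bounds like 1.28, and truncation would hide the small-sample
  character of the interval. A `clip` flag restores conventional output.
  The SE formula is the single most consequential numerical choice in the
  package: it was selected because it exactly reproduces printed reference
  intervals, including the zero-width interval of the degenerate one-sided
  single-discordance table, for which the three variance terms cancel
  symbolically (the implementation snaps the floating-point residue of that
  cancellation to zero).
* **Positive propensity** $= (n_{+-} - n_{-+}) \cdot 100 / N$: a signed,
  directional discordance statistic. A value $\ge 10\%$ is read as a
  positive propensity of analyzer A (it systematically calls the allergen
  positive where B does not); magnitudes below $5\%$ are reported NS.
  Values in $[5\%, 10\%)$ are labelled `reported`: comparison tables print
  them without the $\ge 10\%$ interpretation, and the three-way category
  keeps both conventions visible. Both thresholds are configuration, not
  constants, because the listing convention between 5% and 10% is
  ambiguous in practice. No multiple-testing adjustment is applied — the
  rule is a reporting threshold, not a test — and this mirrors how the
  statistic is used in the field.

```{r worked}
tab <- paired_table(n_pp = 21, n_pn = 1, n_np = 1, n_nn = 20)
total_agreement(tab)
concordant_positive_rate(tab)
cohen_kappa(tab)
kappa_ci(cohen_kappa(tab), kappa_se(tab))
```

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `cutoff` | class | 2 | clinical convention; class 1 often insufficient |
| sweep `cutoffs` | class | 1:3 | the conventional sensitivity range |
| propensity `presence` | % of pairs | 10 | the declaration threshold |
| propensity `ns` | % of pairs | 5 | below this, discordance reported NS |
| CI `level` | — | 0.95 | standard reporting level |
| CI `clip` | — | FALSE | reproduce untruncated published bounds |

Reporting rounds percentages to 1 decimal place and kappa terms to 2,
half away from zero (`round_half_up()`); all computation is at full
floating precision, and the report writers emit both display and
`*_full` machine-readable columns.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes: per patient and allergen, a joint positivity cell is drawn from
probabilities obtained by *inverting the kappa definition* — the generator
is parameterized by marginal prevalence, target kappa and a prevalence
difference (the generative analogue of propensity), so the quantities the
pipeline estimates can be recovered from the generator's own parameters.
Class magnitudes are drawn relative to a single generative cutoff:
negatives uniform below it, positives truncated-geometric above it
(`class_shape`, default 0.5, a moderate severity decay).

`study_sim_config()` states the emulated world once: food-panel N of 30–43
and inhalant-panel N of 79–93 patients, as in clinic-scale comparisons; a
dust-mite tier (prevalence ≈ 0.3–0.5) with κ ≈ 0.9 between same-manufacturer
instruments; a mid tier near κ ≈ 0.7; a rare tail (prevalence ≤ 0.05). The
`vs_reference` variant adds one-sided deltas of 0.10–0.25 on the mite and
house-dust allergens — and, necessarily, moderate kappa targets (0.2–0.5),
because a large one-sided prevalence gap caps the attainable kappa: the
both-positive cell cannot exceed the smaller marginal. Reconstructed
reference tables show exactly this pattern (a fully one-sided table with no
concordant positives has κ = 0 identically).

What a green test does **not** establish: the generator draws allergens
independently (no cross-reactivity networks), has no patient covariates,
and calibrates agreement only at the generative cutoff — sweeps across
other cutoffs are exercised for monotonicity properties, not for
calibrated agreement values.

`reference_fixture()` datasets are deterministic stand-ins reconstructed
from printed N / agreement / CPR cells of published tables; they are
synthetic (positives class 3, negatives class 0) and only their 2×2 tables
at cutoff 2 are faithful. Where a printed row does not determine the
discordance split $n_{+-}$ vs $n_{-+}$, the split consistent with the
printed confidence interval is used.

## Numerical and design choices

* Undefined kappa is detected by the integer condition
  $n_{++} = N$ or $n_{--} = N$, not by floating comparison of $p_e$ with 1.
* The normal quantile is the exact 97.5% point (≈ 1.959964); printed 2-dp
  intervals are insensitive to 1.96 vs exact.
* Per-allergen N is computed per allergen rather than fixed per comparison:
  insufficient sample volume makes one-sided readings common, and the drop
  log (patient, allergen, present side) is always produced as the audit
  trail of the matched-pair exclusion rule.
* The default registry's per-analyzer panels are reconstructed from names
  appearing in published comparisons, so they under-count the advertised
  panel sizes (40–60 per panel); advertised counts are soft checks
  (warnings) because no full enumeration is published. Spelling drift
  across sources ("D. farina" vs "D. farinae", "Weat flour") is absorbed
  by the alias map rather than guessed about further.
* Simulation substreams are derived deterministically from (seed, allergen)
  so adding an allergen to a config does not perturb the draws of others.
* Infeasible generator parameter combinations (kappa target incompatible
  with the marginals) fail loudly, naming the violated cell.

## Limitations

Instrument chemistry and the signal-to-class conversion are out of scope
(class boundaries are manufacturer-specific and unpublished), as are
weighted kappa over the full ordinal scale, multi-rater designs, formal
tests of marginal homogeneity, and any clinical interpretation of results.
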