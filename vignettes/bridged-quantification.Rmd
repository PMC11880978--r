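---
title: "Bridged quantification of the AXIN1:AXIN2 protein ratio and pool composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridged quantification of the AXIN1:AXIN2 protein ratio and pool composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axinpool)
```

## The problem

AXIN1 and AXIN2 are homologous scaffold proteins of the β-catenin
destruction complex. In colorectal cancer cells, loss of AXIN2 raises the
AXIN1 protein level, and the natural quantitative question is whether the
*combined* AXIN1+AXIN2 pool shrinks, holds, or grows. Answering it
requires comparing the absolute amounts of two different proteins from
western blots — which a naive comparison of band intensities cannot do,
because the anti-AXIN1 and anti-AXIN2 antibodies have different, unknown
binding affinities.

`axinpool` implements the full quantification chain for this question:
a three-antibody *bridging calibration* for the endogenous AXIN1:AXIN2
ratio, a *pool-composition engine* that propagates per-condition fold
changes into combined-pool percentages (the pie-chart quantities), and
the auxiliary assay models used alongside (TOP/FOP reporter
normalization, cycloheximide-chase decay kinetics, recruitment-fraction
statistics, replicate summaries and Student's *t*-tests).

## The bridging model

Write $a_1, a_2$ for the unknown endogenous amounts of AXIN1 and AXIN2,
$g_1, g_2$ for the (also unknown) amounts of transfected GFP-AXIN1 and
GFP-AXIN2, and $\alpha_{A1}, \alpha_G, \alpha_{A2}$ for the antibody
affinities (intensity per unit amount). A band's expected intensity is

$$ I = \alpha \cdot x \cdot d, $$

where $x$ is the analyte amount and $d \in (0,1]$ the loaded dilution.
Three same-antibody comparisons are run on shared lysates:

| comparison | antibody | measures |
|---|---|---|
| 1 | anti-AXIN1 | $r_1 = \dfrac{\alpha_{A1} a_1}{\alpha_{A1} g_1} = a_1/g_1$ |
| 2 | anti-GFP | $r_2 = \dfrac{\alpha_{G} g_1}{\alpha_{G} g_2} = g_1/g_2$ |
| 3 | anti-AXIN2 | $r_3 = \dfrac{\alpha_{A2} g_2}{\alpha_{A2} a_2} = g_2/a_2$ |

so the chained product telescopes:

$$ r_1 \, r_2 \, r_3 \;=\; \frac{a_1}{a_2}, $$

with every affinity and every construct amount cancelling exactly. This
identity is what the package's noise-free tests assert to $10^{-9}$ over
random affinities and construct amounts.

Two model assumptions deserve emphasis. First, the anti-GFP step assumes
the antibody detects GFP-AXIN1 and GFP-AXIN2 with equal affinity — both
carry the same tag, but the assumption is not verifiable from the data
itself; `chained_ratio()` exposes a `gfp_affinity_correction` factor
(default 1) should an empirical correction become available. Second,
band intensity is treated as proportional to *molar* amount with no
molecular-weight correction, matching the convention of the assays the
package models.

### Dilution fits and saturation

Each analyte is loaded at a short dilution series (defaults 1:10, 1:2,
undiluted). `fit_dilution_response()` fits a least-squares line through
the origin, $I = s\,d$, and the two slopes of a comparison give its
ratio. The series also acts as a linearity check: film and detector
saturation compresses the brightest lanes, which would bias the slope
downward. The rule flags a lane as saturated when its intensity falls
below $(1 - \texttt{saturation\_tolerance})$ — default 20% — of the
origin-line prediction anchored at the *lowest* dilution (the lane least
likely to saturate), working from the highest dilution downward and
stopping at the first lane on the line; at least one lane is always
retained. The anchoring choice and the tolerance are declared package
conventions: clips shallower than the tolerance are indistinguishable
from noise and pass through undetected, which bounds the residual bias
at roughly the tolerance itself on a single lane of the fit.

### Aggregation

Per-experiment chained ratios are averaged arithmetically with the SEM on
the ratio scale (`aggregate_ratio()`), matching the mean-±-SEM reporting
convention of the assays; geometric-mean aggregation is available via
`log_scale = TRUE`. Intensities in bridging are used raw, not
loading-normalized, because all lanes of one comparison come from one gel
of one lysate; a loading-normalized path exists in `quant_core` for
cross-gel fold-change designs.

## Pool composition and the rounding convention

For a ratio $r$ of AXIN1 to AXIN2, the wild-type combined pool of 100%
splits as

$$ \text{AXIN2\%} = \frac{100}{1+r}, \qquad
   \text{AXIN1\%} = \frac{100\,r}{1+r}, $$

giving 21.9% / 78.1% at $r = 3.56$. Each other condition scales these
components by its fold change relative to the untreated parental line,
and the total is the component sum.

The propagation arithmetic carries a deliberate rounding convention
(`rounding = "table"`, the default): fold changes and percentages are
rounded to **one decimal, half away from zero, before propagation** —
e.g. a measured 615.4% becomes fold 6.2, and the AXIN2 component is
$21.9 \times 6.2 = 135.8$. This is the only convention that reproduces
the published pool table cell-for-cell (including the tie case
$21.9 \times 13.5 = 295.65 \to 295.7$); carrying full precision gives
slightly different totals (e.g. 131.5 rather than 131.6 for the
knockdown row). Base R's round-ties-to-even does *not* reproduce those
cells, hence `round_half_up()`. An `"exact"` mode disables intermediate
rounding for analyses where propagated precision matters more than
reproduction.

Knockout conditions are encoded as *component absent*
(`axin2_absent = TRUE`), not as fold 0: a structurally absent protein is
different from an unspecified fold, and the distinction keeps
missing-fold validation alive for genuinely unspecified conditions.

## Auxiliary assay models

**TOP/FOP reporter.** Each luciferase readout is normalized to its
same-well β-galactosidase activity (transfection control); the TOP/FOP
ratio of normalized activities reports β-catenin-dependent transcription.
The FOP control is matched per replicate — same day, parallel wells —
and cross-replicate borrowing is deliberately not supported.

**Cycloheximide chase.** Levels (percent of $t=0$) are fitted by
ordinary least squares of $\log(\text{level})$ on time with a free
intercept; $k = -\text{slope}$ and $t_{1/2} = \ln 2 / k$. With the two or
three timepoints a chase affords, log-linear OLS is the model the data
can support; nonlinear least squares would add parameters without
information. Slopes within numerical noise of zero
($k \le \sqrt{\epsilon}$) are flagged non-decaying with infinite
half-life rather than reporting an astronomically large finite number.
Fitting per replicate and averaging the fits is the default analysis
route; fitting the per-timepoint means is also possible by summarizing
first.

**Recruitment fractions.** The independent experiment — not the cell —
is the replication unit: each experiment contributes one percentage
$100\,n_\text{recruited}/n_\text{total}$, and setups are compared by the
unpaired two-tailed Student's *t*-test on those percentages. Treating
cells as units would overstate precision roughly $\sqrt{n_\text{cells}}$-fold.

**Statistics conventions.** Unpaired tests use the classical
equal-variance Student's *t* (Welch's correction is available behind
`welch = TRUE` but is not the default, matching the source convention);
paired tests pair by experiment. The degenerate paired case of all-zero
differences returns $p = 1$ — degenerate but user-reachable — rather
than NaN. Stars map as `***` $p<0.001$, `**` $p<0.01$, `*` $p<0.05$,
`ns` otherwise; no multiple-testing correction is applied, matching the
assay conventions being modelled.

## The synthetic-data generators

No raw densitometry is deposited for studies of this kind, so the
package ships generators for every input it consumes, with known ground
truth. The band model is

$$ I = \min\!\big(\text{cap},\;
     \alpha \, x \, d \, L \, e^{\varepsilon}\big), \qquad
   L \sim \text{LogNormal}(0, \text{cv}^2),\;
   \varepsilon \sim N(0, \sigma^2), $$

with $L$ shared by all bands of a lane (loading error, cancelled by
loading-control normalization) and $\varepsilon$ per band (densitometry
error). The error is multiplicative log-normal, not additive Gaussian:
densitometry errors scale with signal, and intensities stay positive.
Defaults $\sigma = 0.15$ and $\text{cv} = 0.1$ are plausible magnitudes
for quantitative immunoblots — configuration knobs, not claims about any
particular dataset. Draw order is fixed (lanes in output row order, lane
load before band noise, loading control before target within a lane), so
a seed fully determines the output within this implementation.

The generators emulate the *measurement* process only: no gel artifacts,
no antibody cross-reactivity, no image segmentation. Passing recovery
tests therefore demonstrates that the estimators invert the stated
measurement model — not that real blots satisfy it.

### What the simulations show

* **Noise-free round trips.** At $\sigma = 0$ every generator composed
  with its pipeline stage is the identity on ground truth: the chained
  ratio returns the encoded ratio to $10^{-9}$ for arbitrary affinities,
  condition panels return their fold maps exactly (folds specified at
  one decimal, the propagation resolution), decay fits return $k$
  exactly, and reporter activities return their truths.
* **Recovery under noise.** The study-level check runs 200 independent
  six-experiment bridging studies with densitometry noise at
  $\sigma = 0.15$ and a true ratio of 3.56: the grand mean recovers the
  truth with under 5% relative bias, and each study's mean ± 3 SEM
  covers the truth in at least 95% of studies. The linear-scale
  arithmetic mean of slope ratios is upward-biased by approximately
  $\exp(3 w \sigma^2) - 1$ (with $w \approx 0.67$ the effective weight
  the through-origin fit places on its noisiest configuration), about
  4–5% at this $\sigma$ — an inherent property of averaging ratios on
  the linear scale, which the reporting convention prescribes; log-scale
  aggregation removes it at the cost of departing from that convention.
  Adding lane-loading variation on top (cv = 0.1, the generator default)
  raises the bias above the linear-scale bound, which is why the
  bias check isolates densitometry noise while the coverage property is
  additionally verified at full default noise.
* **Problem sizes.** Simulation sizes mirror the study designs being
  modelled: 6 bridge experiments, 4 replicates for fold changes and
  reporter assays, 3 chase timepoints (0, 4, 8 h), 4 recruitment
  experiments of ~350 cells total per setup, and 100–200 study
  repetitions for Monte-Carlo properties.

## Numerical and degenerate-input choices

* Reference conditions map to exactly 100.0 in `relative_to_reference()`
  (set, not divided) so reference identity survives floating point, and
  the operation is idempotent on its own output.
* `round_half_up()` adds $\sqrt{\epsilon}$ before flooring so products
  whose binary representation sits infinitesimally below a tie (the
  295.65 case) round the way their decimal value dictates.
* A dilution fit refuses all-zero series; a single positive lane fits
  through the origin (no saturation call possible with one lane).
* SEM of a single value is 0 by convention (`n = 1` summaries are legal;
  several published panels have $n = 1$ pilot lanes).
* Knockout bands simulate as exactly zero intensity; downstream fold
  recovery returns fold 0 rather than erroring, while log-decay fitting
  (where zero is genuinely undefined) errors explicitly.

## Limitations

* The equal-affinity assumption of the anti-GFP step is structural; the
  correction factor is exposed but defaults to 1.
* Saturation shallower than the tolerance passes undetected by
  construction; the tolerance bounds, but does not remove, that bias.
* The pool table propagates *means*; no uncertainty is attached to the
  pool percentages (the source convention reports none).
* Linear-scale ratio averaging carries the small upward bias analysed
  above; it is the reporting convention, not an estimator recommendation.
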