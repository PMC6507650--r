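---
title: "Modelling cell-size dynamics under chronic spindle-checkpoint activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cell-size dynamics under chronic spindle-checkpoint activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacsize)
```

## The biological problem

Budding yeast under chronic activation of the spindle assembly checkpoint
(SAC) — by partial microtubule depolymerization or by Mad2 overexpression —
does not arrest indefinitely. Cells eventually slip out of mitosis
("adaptation"), divide, and keep proliferating through long, highly
variable cycles, at the price of frequent chromosome mis-segregation.
Because growth continues while division is delayed, cells become very
large; yet the population's size distribution stabilizes rather than
diverging. This package implements the quantitative machinery to study
that behaviour: a stochastic growth/division model, the pipeline that
cleans single-cell size trajectories, the statistics that quantify size
control and cycle variability, the mis-segregation-to-aneuploidy
estimator, and a stress-response score for expression profiles.

## The growth/division model

A single cell's area follows a logistic growth term multiplied by a linear
term:

$$A(t) \;=\; \frac{A_0\,A_{max}\,e^{rt}}{A_{max} + A_0\,(e^{rt}-1)}
\cdot \Big(1 + \frac{m}{A_{max}}\,t\Big),$$

exponential ($\sim e^{rt}$) for small $t$ and approaching a straight line
of slope $m$ for large $t$; $A_{max}$ sets where the transition happens.
Division halves the area instantaneously and the daughter jumps back to
the curve position matching its new size, so the whole lineage lives on
one curve.

Parameters, with defaults and units:

| parameter | default | units | meaning |
|---|---|---|---|
| `A0` | 20 | µm² | area at $t=0$; smallest size on the curve |
| `Amax` | 120 | µm² | exponential-to-linear transition scale |
| `r` | ln(2.5)/100 ≈ 0.00916 | min⁻¹ | exponential rate, calibrated below |
| `m` | 0.3 | µm²·min⁻¹ | asymptotic linear slope |
| `T_unperturbed` | 100 | min | reference unperturbed cycle length |

`r` is not free: requiring an unperturbed cell to double over one cycle
($A(T) = 2A_0$ with $m = 0$) gives the closed form

$$r = \frac{\ln\big(2(A_{max}-A_0)\big) - \ln\big(A_{max}-2A_0\big)}{T},$$

which at the defaults is `r signif(compute_growth_rate(20, 120, 100), 4)`
min⁻¹. The slope `m` has no published value; 0.3 µm²·min⁻¹ keeps the
SAC-active steady entry size a few-fold above `A0`, in the qualitative
range of the imaging data, and it is exposed as an ordinary parameter so
any sensitivity to it can be probed directly. It should not be read as a
measured quantity.

Cycle lengths are phenomenological, not mechanistic:

* unperturbed: Normal(100, 10) minutes, redrawing the (astronomically
  rare) non-positive values so the stated mean and SD are preserved;
* SAC-active: 200 min of deterministic arrest plus an Exponential tail
  with mean 200 min — a memoryless waiting time to slippage. Mean 400
  min, CV exactly 0.5.

At a regime switch the distribution changes for the *next drawn*
duration: a cycle already in progress keeps the length it was born with.

Two structural consequences carry the model's main claims. First, because
late growth is linear, a cell that divides late adds roughly $m\,d$ µm²
regardless of how large it already is, so entry sizes follow a contracting
map and their variance stabilizes; replacing the curve by unbounded
exponential growth with the same cycle draws turns log-size into a random
walk whose variance grows without bound. `simulate_entry_sizes()` exposes
both laws for exactly this contrast. Second, the timing noise (CV 0.5) is
much larger than the resulting size noise (CV ≈ 0.2 at steady state):
sizes are buffered by the growth law.

`simulate_withdrawal()` runs the reverse experiment: lineages equilibrate
under SAC-active cycling (15 burn-in cycles by default, comfortably past
the ~5-cycle relaxation time of the entry-size map), then revert to
unperturbed draws; the post-division size of the first five recovery
cycles shows a monotone relaxation toward the unperturbed steady state,
quantifiable with `density_overlap()`.

Numerical choices: the curve is inverted analytically when `m = 0` and by
bracketed root search (`uniroot`, relative tolerance 10⁻⁹) otherwise; if
a halved size ever falls below `A0` the lineage restarts at `A0` with a
warning (impossible once a default-parameter lineage has equilibrated).
All stochastic functions draw from R's global RNG, so a single
`set.seed()` call at the top of a script reproduces an entire analysis.

## Cleaning single-cell size trajectories

Segmented time-lapse areas carry two kinds of error: small frame-to-frame
jitter and occasional single-frame spikes where segmentation failed. The
filter works on the local variations $\Delta A_i = A_{i+1} - A_i$:

1. pool the $(A_i, \Delta A_i)$ pairs of a condition's trajectories and
   split them into size clusters (default edges 0–40–80–120 µm²);
2. per cluster, set Tukey fences $Q_1 - 1.5\,\mathrm{IQR}$ and
   $Q_3 + 1.5\,\mathrm{IQR}$ on the $\Delta A$ distribution (type-7
   quartiles — the fences depend on the quartile convention, so it is
   fixed and documented);
3. iteratively (at most 10 passes) replace outlier points by the mean of
   their two neighbours; endpoints are never replaced, and sizes beyond
   the last cluster edge are never flagged.

One genuinely open design point is which variation condemns a point,
since each $\Delta A_i$ sits between two points. The package's default
(`flag_rule = "both"`) replaces a point only when the variation *into* it
and the variation *out of* it both leave their fences — the signature of
an isolated spike, which is then restored in a single pass without
touching its neighbours. The two one-sided alternatives are available as
options but misbehave on exactly the data the filter targets: pairing
each point with its outgoing variation also condemns the spike's
predecessor, whose replacement (computed from the still-spiked neighbour)
sends a decaying copy of the spike walking backwards through later
passes, and flagging on *either* violating variation smears every spike
into both neighbours. The `both` rule's known blind spot — two
consecutive spiked frames are only partially corrected — is mitigated by
how rare consecutive segmentation failures are.

After adjustment, trajectories are smoothed with a centred moving average
(window shrinking symmetrically at the edges): 3 points for unperturbed
conditions, 8 for the longer, noisier SAC trajectories. Local growth rate
is the central finite difference of the smoothed series (one-sided at the
ends), paired with local area and typically binned in 10-µm² windows;
population mean trajectories only report timepoints supported by more
than five cells.

## Cycle statistics and size control

`phase_durations()` applies the landmark definitions — mitosis from the
Clb2 rise to the Clb2 fall, cycle length from budding to budding — and
propagates censoring; censored groups are compared with the log-rank test
(`survival::survdiff`). Fold increases are ratios of condition medians
for the mitotic phase and for the remainder of the cycle.

Size control during mitosis is measured on the size-growth plot: the OLS
slope $\lambda$ of $G_{mitosis} = \ln(A_{ANA}/A_{PM})$ against
$\ln(A_{PM})$ is 0 for a pure timer and −1 for a perfect sizer. On
records generated from the growth model under SAC-active cycling,
$\lambda$ is significantly negative — the saturating growth law itself
produces size control, with no regulatory feedback in the model.

Two distributions are compared for location and correlation only after a
normality gate: Lilliefors, Anderson–Darling, Jarque–Bera and one-sample
Kolmogorov–Smirnov (against a Normal with the sample moments) are run on
each variable, and normality stands when at least three of the four
p-values exceed 0.05. Both variables normal → Pearson / Welch's t;
otherwise Spearman / Mann–Whitney. Note that even for genuinely Normal
data at $n = 200$ the gate picks Pearson only ~93% of the time — the
3-of-4 rule still rejects a few percent of true Normals. The Jarque–Bera
test is implemented in the package (skewness/kurtosis χ², 2 df) since no
installed dependency provides it; the other tests delegate to `nortest`
and `stats`.

The overlap of two size distributions is
$O(f,g) = \int \min(f, g)\,dv$ on kernel density estimates sharing one
grid (512 points spanning both samples ± 3 bandwidths, Scott's reference
bandwidth per sample, trapezoidal quadrature, clipped to [0, 1]). $O$
depends mildly on the bandwidth rule — tests allow ±0.02 around closed
forms — and the integration runs over the full shared support.

## Aneuploidy from mis-segregation counts

With a per-chromosome mis-segregation rate $R$ measured on one marked
chromosome and the (admittedly coarse) assumption that all 16 chromosomes
mis-segregate independently at the same rate, the probability that a cell
acquires at least one aneuploid chromosome is $P = 1 - (1-R)^{16}$.
Replicates are aggregated by averaging the per-replicate $P$ values
(replicates are independent scorings and are reported as separate
points); pooling the counts before the probability map is available as an
option and lands within a few points of the mean-of-$P$ value on the
shipped counts. For small $R$, $P \approx 16R$.

## Stress response intensity

For a fold-change profile annotated with environmental-stress-response
(ESR) classes, with $x_i$ the log2 fold changes of ESR-induced genes and
$y_j$ of ESR-repressed genes,

$$\mathrm{SRI} \;=\; \frac{\sum_i x_i + \sum_j (-y_j)}
{\sum_i |x_i| + \sum_j |y_j|} \in [-1, 1],$$

reaching +1 exactly when every induced gene is up and every repressed
gene down. The package ships no ESR gene lists — any user-supplied
annotation works — and the synthetic generator builds profiles with a
configured strength for recovery tests. Cross-sample comparison first
z-normalizes each profile, then clusters on the distance
$1 - \rho_{Spearman}$ with complete linkage.

## What the synthetic data do and do not show

The generators reproduce the *structure* the methods assume: growth-curve
dynamics with the stated cycle-length distributions, isolated
single-frame spikes (uniform 30–80 µm² amplitude — a failed segmentation
is wrong by the order of a cell's area) on top of 1% multiplicative
jitter, uniform censoring within a cycle, a fixed mitotic fraction per
regime (0.3 unperturbed, 0.5 SAC-active — a generator knob, not a
measurement), and Gaussian ESR fold changes. Real data violate several of
these idealizations: segmentation errors can persist for several frames,
measurement noise is autocorrelated, mitotic fraction varies per cell,
Clb2 landmarks carry their own detection error, and real expression noise
is heavy-tailed. Passing the recovery tests therefore demonstrates that
the implementations compute their definitions correctly and behave
sensibly under the stated noise model — not that the pipeline is optimal
on any particular microscope's output.

## Problem sizes and determinism

The shipped analyses and tests use 50 trajectories for filter recovery,
200 lineages for the withdrawal experiment, 500 lineages × 30 cycles for
the homeostasis contrast, 500 records per regime for the duration
statistics, and 10⁵ draws where a Monte Carlo estimate is compared with a
closed form — sizes at which each check's sampling error is far from its
acceptance margin. Every stochastic result is reproducible from a single
seed.

## Known limitations

* The model is phenomenological: no SAC/APC biochemistry, no
  mother/daughter asymmetry (division is symmetric halving), no
  size-dependent transcription.
* `m` is a free parameter; conclusions that depend on its exact value
  (e.g. the steady SAC entry size) are qualitative.
* The aneuploidy map assumes equal, independent per-chromosome rates.
* The trajectory filter's cluster fences are only defined where data
  exist; sizes beyond the last edge pass through unfiltered by design.
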