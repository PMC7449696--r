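---
title: "Models and methods behind phshock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phshock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phshock)
```

`phshock` analyses how transient intracellular acidification gates the
Hsf1-mediated heat shock response in budding yeast. This vignette is the
package's account of the models it fits, the assumptions behind them, the
tunable parameters that matter, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was
genuinely open.

## Ratiometric pH calibration

pHluorin is a GFP variant whose fluorescence excited at 405 nm versus
488 nm shifts with pH, so the per-cell 405:488 ratio reports intracellular
pH independent of expression level. Calibration equilibrates cells in
buffers of known pH (ionophore-permeabilized, typically 0.5-unit steps
from 4.5 to 8.5) and fits the per-buffer median background-corrected ratio
to a four-parameter logistic

$$R(\mathrm{pH}) = \frac{a}{1 + e^{-b(\mathrm{pH} - c)}} + d,$$

with span $a$, steepness $b$ (1/pH), midpoint $c$ (pH) and offset $d$. The
effective pKa is defined operationally as the pH where the ratio is midway
between its asymptotes $R_{min} = d$ and $R_{max} = a + d$, found by
root-finding $\log\{(R - R_{max})/(R_{min} - R)\} = 0$ on the fitted
curve. For this parameterization the root coincides with $c$, and the
numerical route is kept (and tested against the identity) so that the
*definition* is what the code computes. The pKa is the gain-independent
summary of a calibration: rescaling $(a, d)$ — different laser powers or
detector voltages — leaves it essentially unchanged, which is why
calibrations are comparable across days even when raw ratios are not.
A calibration is an explicit input to every conversion step: each
experiment carries its own fit.

Numerical choices:

* **Optimizer.** Bounded Levenberg-Marquardt (`minpack.lm::nlsLM`) from
  four deterministic starts (midpoint/quartile heuristics, both signs of
  $b$); lowest RSS wins, ties broken by smallest $|b|$. A dense two-stage
  grid search serves as the oracle in the tests, never as the
  implementation.
* **Sign convention.** $a > 0$ is enforced through the reflection symmetry
  $(a,b,c,d) \to (-a,-b,c,a+d)$; descending-ratio filter sets are thereby
  handled without a second code path.
* **Refusals.** Fewer than 5 points, a pH span under 2 units, or a ratio
  range below a configurable floor (default 0.05) refuse to fit rather
  than return a meaningless sigmoid.
* **Inversion.** $\mathrm{pH} = c - \ln(a/(R-d) - 1)/b$ is applied only to
  ratios strictly inside $(R_{min}, R_{max})$; everything else becomes a
  counted missing value. Clamping would fabricate probability mass at the
  ends of the pH scale exactly where the biology (severely acidified or
  alkalinized cells) is of interest.

## Event selection

Three deterministic gates replace interactive gating so that analyses are
reproducible: (i) a central-quantile scatter gate (default 98% joint
coverage) placed on unstressed reference cells; (ii) threshold exclusion
of a handling-dependent BV421-bright artifact population, thresholded by
default at the unstressed control's 99.9th percentile since no instrument
constant is transferable; (iii) a 488-channel threshold separating
pHluorin-expressing cells from dim unlabeled spike-in cells, derived when
unspecified from a two-component mixture fit on log ch488, with an
optional ambiguity margin (default 0, a hard split). The partition
labeled + spike + ambiguous is exhaustive by construction, gate labels are
order-invariant, and every excluded-event count is reported — exclusion
fractions are scientific outputs here, not diagnostics.

## Induction kinetics

Chaperone induction is summarized per timepoint as the median over cells
of red fluorescence normalized to forward scatter, divided by the same
statistic in unstressed cells from the same experiment. The default
normalizes per cell (`ch_red/fsc_area`, then median); the ratio-of-medians
alternative is a configuration switch, and the two agree for scale-family
distributions. Curves are fitted in the log domain with the same logistic
form, constrained to baseline $d \ge 1$ (a fold change cannot sit below
its own baseline), and the fitted midpoint $c$ is the induction delay in
minutes. Flat curves return zero amplitude flagged as "no induction"
rather than an arbitrary midpoint. Log-domain fitting weights the
low-fold-change early points fairly — multiplicative measurement noise is
approximately homoscedastic in the log.

Sliding-window smoothing of continuous-time traces uses a centered window
with truncated edges. A centered window lets a sharp transition bleed into
earlier times (an apparent pre-stress drift when smoothing across the
shock onset); this artifact is a property of the window and is documented
rather than hidden, since the alternative (causal smoothing) distorts the
recovery side instead. The default window is a configuration choice, not a
measured constant.

## Subpopulation classification

Expression level and budding state are both bimodal readouts, classified
with a hand-rolled two-component Gaussian-mixture EM chosen over a generic
library fit because its determinism rules are part of the method: three
hard-split initializations (median, quartiles), best log-likelihood wins
with ties broken toward larger separation, a $\sigma$ floor of $10^{-6}$
of the data range against collapse, and components ordered by mean.
Expression mixtures are fitted on the log scale (fluorescence is
multiplicative); FSC pulse-width mixtures on the linear scale (pulse width
tracks cell-plus-bud length). A fit is flagged *poorly separated* when the
means are closer than one pooled standard deviation **or** the fitted
mixture density has no dip between the means — the latter catches the
common failure mode where EM describes one mode with two overlapping
components whose means are nonetheless more than a pooled sd apart.

Cells are assigned to a class only when their posterior reaches 0.90 (the
cutoff shared by the expression and budding analyses); the rest stay
ambiguous and are excluded from class statistics, and the test suite
verifies that every assigned cell really carries posterior $\ge 0.90$.
Raising the cutoff can only grow the ambiguous band.

Resting-pH-range fractions use a default range of 7.3–7.8 pH. This
brackets the canonical unstressed resting pH of about 7.5, but no
published numeric bounds exist for the range; the default is an assumption,
is recorded as such in pipeline manifests, and is configurable. Rank
comparisons of pH between classes use the two-sided Mann-Whitney U test
(`stats::wilcox.test`: exact for small untied samples, normal
approximation with tie and continuity corrections otherwise), with the
degenerate all-tied case pinned to $p = 1$.

## Competitive fitness

With unlabeled exponentially growing spike-in cells as an internal
reference, the log count ratio normalized to its initial mixing fraction,
$y(t) = \ln[(n_{lab}(t)/n_{spk}(t)) \cdot (n_{spk}(0)/n_{lab}(0))]$, is
linear in time under constant exponential growth with slope
$r_{lab} - r_{ref}$ — the selection coefficient. Counts are gated,
BV421-filtered event counts; zero-count timepoints are dropped with a
logged reason rather than pseudocounted, because a pseudocount would bias
exactly the steep series it is meant to rescue. Fitting is ordinary least
squares restricted to the linear early window (defaults: under 100 min for
untreated series, under 160 min when ionophore treatment delays recovery),
with a curvature warning when the excluded tail departs strongly from the
windowed line.

Controls combine subtractively in rate space, since rates add under
exponential growth: a mix-in control (both strains handled identically)
isolates the label's strain effect, a mock control (treatment handling
without heat) adds the handling effect, and the corrected slope is
raw − mixin − (mock − mixin) = raw − mock, with all components retained
for reporting and standard errors combined in quadrature. The published
record describes these controls procedurally without stating the
arithmetic; rate-space subtraction is this package's choice. Estimates can
be re-expressed relative to the fully arrested bound: an arrested
population (absolute rate 0) maps to 0, a population matching the
reference maps to $r_{ref}$ (e.g. $\ln 2 / 70$ per minute for a 70-minute
doubling time).

## Regulon pH sensitivity

From a tpm matrix and sample metadata, replicates are averaged within
condition *before* ratios are taken (a per-replicate-ratio alternative
exists for sensitivity checks). Two per-gene quantities drive everything:
the heat-shock fold change (shock vs mock) and the acidification fold
change (shock with acidification vs shock with acidification prevented,
always within one translation state). Ratios get a default pseudocount of
1 tpm — zero handling is unstated in the source analyses, so the
pseudocount is documented as an assumption and 0 is allowed for exact toy
checks. Summaries and tests operate in log2 (ratios are multiplicative);
ECDFs are reported on the ratio scale.

Regulon rules: genes under Hsf1 or Msn2/4 control are excluded from every
other regulon, only regulons with at least 4 genes are scored, and the
rank-test background is all scored genes outside any regulon. Because tpm
is compositional, a strongly induced regulon depresses every other gene's
apparent abundance; planted-effect simulations show member ratios slightly
below the planted fold and background ratios slightly below 1, with the
ratio of medians preserved — the tests pin this closure property down
exactly. Across regulons, Benjamini-Hochberg adjustment is applied by
default (the source analyses report raw p-values; both are in the output).

## Synthetic data: what it emulates, and what it does not

All four generators share explicit seeds (byte-identical reruns; the
caller's RNG state is restored) and multiplicative lognormal noise with
median exactly 1, so a CV of 0 reproduces every closed form to machine
precision — the basis of the exact tests. No noise magnitudes were
published for any channel; all CV defaults below are stated as
configuration, not measurement.

* **Calibration sets** place the noise-free median ratio exactly on the
  generating sigmoid at each buffer pH, plus additive channel backgrounds.
  Defaults: 9 buffers (pH 4.5–8.5), 10000 events, 5% channel CV.
* **Recovery time courses** draw, per cell: pH from a recovered
  (7.45 ± 0.08) or non-recovered (6.8 ± 0.12) class; red fluorescence from
  a two-component lognormal in which high expressors occur *only among
  pH-recovered cells* — this generative link is a simulation choice that
  encodes the observed single-cell dependency so that recovery tests are
  meaningful, not a claim the pipeline could verify from its own output;
  FSC pulse width from a budded/unbudded two-component Gaussian; plus
  configurable spike-in and BV421-bright fractions. The population
  induction profile is a logistic in time (defaults: amplitude 9, rate
  0.05/min, midpoint 120 min) so end-to-end midpoint recovery has a known
  truth. The 405:488 ratio carries its own small CV (default 0.05),
  separate from the intensity-channel CV (default 0.25): ratiometric
  readout noise is far smaller than absolute intensity noise because the
  ratio cancels expression level. Event depth defaults to 10000 per
  timepoint, a typical acquisition depth.
* **Competition series** draw binomial splits of a fixed acquisition depth
  around exact exponential expectations; infinite depth disables sampling
  noise for closed-form checks.
* **Expression matrices** are lognormal around basal × heat-shock fold ×
  (acidification fold, only in the shock-with-acidification condition and
  only for designated gene sets), two replicates per condition, columns
  renormalized to $10^6$ (tpm).

Not emulated: instrument optics (spectral spillover, compensation,
doublet physics beyond pulse width), fluorophore maturation kinetics,
read-level sequencing (tpm is the boundary), biological covariance between
channels beyond the class structure, and real regulon databases (gene sets
are input files). Passing tests therefore demonstrate estimator
correctness under the stated generative families — recovery of planted
parameters, calibration of error rates, exactness of closed forms — not
robustness to instrument effects absent from the generators.

## Problem sizes and reproducibility

The validation suite exercises the study-scale conditions where they are
cheap (10000-event depths, 100-seed calibration recovery, 200-seed fitness
calibration, 1000-simulation null calibration of the rank test) and
reduced event counts (1500–5000 per sample) for the end-to-end pipeline
checks, sizes chosen to keep the whole suite fast while leaving every
statistical criterion well-powered. `scripts/acceptance.R` recomputes the
headline quantities from scratch at any seed; pipeline runs write a
manifest with the seed and a hash of the configuration (excluding the
output path), and contain no timestamps, so identical configurations
produce byte-identical bundles.

## Known limitations

* Conversion runs per-cell ratios through the population-level calibration
  fit; per-cell calibration is not attempted (and not identifiable from
  these data).
* No temperature-dependent recalibration: buffer-pH vs computed-pH
  concordance is exposed as a report instead.
* The mixture model is strictly two-component; model selection over more
  components is out of scope.
* Growth fitting assumes exponential kinetics inside the window; saturating
  models are deliberately excluded.
* The mock/mix-in correction arithmetic and the resting-pH range are
  package choices where the published record is procedural only; both are
  configurable and flagged in outputs.
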