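---
title: "Competitive-binding qPCR screens: model, inference and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive-binding qPCR screens: model, inference and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dianascreen)
```

## The assay and its forward model

In a DNA-linked Inhibitor Antibody Assay (DIANA) screen, an immobilised
target protein (here PD-L1) is incubated with a detection probe — a
target-binding ligand conjugated to a DNA oligonucleotide — together with a
test compound. Probe retained after washing is quantified by qPCR. The
readout is the quantification cycle Cq: each halving of bound probe adds
one cycle (at perfect amplification efficiency), so displacement of the
probe by a competitor shifts Cq upward. The working statistic is

$$\Delta C_q(w) \;=\; C_q(w) \;-\; \overline{C_q}(\text{noninhibited wells}),$$

and the dynamic range is the *assay window*, the Cq difference between
maximally inhibited and noninhibited control wells (about 13 cycles at the
default calibration, i.e. a $2^{13.03} \approx 8{,}370$-fold signal range —
we report the exact fold-range rather than the rounder "four orders of
magnitude" phrasing, since $\log_{10} 2^{13.03} \approx 3.9$).

`dianascreen` models one well as a three-species competitive equilibrium.
With total target $T$, probe $P$ (dissociation constant $K_P$) and
compound $I$ (dissociation constant $K_I$), mass action leaves a single
monotone equation in free target $t$:

$$t\left(1 + \frac{P}{K_P + t} + \frac{I}{K_I + t}\right) = T,$$

solved by bracketed root finding on $[0, T]$ (tolerance $10^{-10}$
relative, then Newton polishing; the bracket is guaranteed and monotone, so
no closed-form cubic branch hazards). The same equation with a sum over
competitors handles compound pools and counter-screen wells exactly.
`cq_from_bound()` then maps bound probe $b$ to
$C_q = C_q^{\mathrm{ref}} - \log(b/b_{\mathrm{ref}})/\log(1+e)$ with
efficiency $e = 1$ by default (exposed for sensitivity analyses, since all
$2^{\Delta C_q}$ arithmetic assumes perfect doubling). Non-positive bound
quantities map to the censored "no amplification" marker, never a number.

## Single-well Kd inference

When target depletion is negligible ($T \ll K_P$), the equilibrium inverts
in closed form to the single-well estimator

$$K_I \;=\; \frac{2^{-\Delta C_q}}{1 - 2^{-\Delta C_q}}\cdot
\frac{I_{\mathrm{tot}}}{1 + P_{\mathrm{tot}}/K_P},$$

with the working defaults $P_{\mathrm{tot}} = 0.2$ nM (200 pM) and
$K_P = 1.32$ nM. `kd_single_well()` implements exactly this, with typed
censoring instead of numerical blow-ups:

* $\Delta C_q \le 3\,\sigma_{\mathrm{neg}}$ (the low-censor default) yields
  "no measurable inhibition" plus the implied Kd *lower bound*, so noise is
  never reported as affinity;
* $\Delta C_q$ at or beyond the assay window minus $3\,\sigma_{\mathrm{inh}}$
  keeps its point estimate but is flagged "saturated".

`kd_average()` pools a dilution series: per-well $\Delta C_q$ against the
plate's noninhibited mean, per-well Kd, then the arithmetic mean ± sample
SD over non-censored wells. Arithmetic (not log-scale) averaging was chosen
because the field reports "average ± SD" of per-well values; a geometric
mode is available. All non-censored wells are pooled with equal weight
across concentrations (a per-concentration breakdown is returned, since
equal-weight pooling versus per-concentration averaging is genuinely
ambiguous in practice). The estimator's validity regime $T \ll K_P$ is
enforced with a warning when `t_tot > 0.05 * kd_probe`.

Two intrinsic biases of this published estimator are worth knowing, and the
parameter-recovery test quantifies both implicitly:

1. *Depletion bias*: the forward simulation solves the exact equilibrium,
   the inversion uses totals; at the default $T = 0.01$ nM this contributes
   well under 2% for the validated designs.
2. *Convexity (Jensen) bias*: $K_I$ is convex in $\Delta C_q$, so Gaussian
   Cq noise of SD 0.14 inflates the mean estimate by roughly
   $\tfrac12 (\ln 2)^2 \sigma^2 \cdot 2^{\Delta}(2^{\Delta}+1)/(2^{\Delta}-1)^2$
   relative — about 0.5–2% across the positive-control series. This is a
   property of per-well inversion plus arithmetic averaging, not of the
   implementation; accordingly the recovery check asserts that the truth
   lies within twice the spread of the recovered means (distribution
   coverage), not within twice the standard error of their grand mean,
   which the small intrinsic bias would fail by construction at 200
   replicates.

`probe_kd_fit()` calibrates the probe Kd itself from a titration against
fixed target, fitting the exact two-species isotherm (so probe depletion is
handled) by one-dimensional least squares on $\log_{10} K_P$ — robust, no
multistart needed. Titrations must span ≥ 10-fold in probe and bracket the
Kd to determine it well; flat or saturating titrations raise a typed fit
error or a wide-confidence flag.

## Plate QC and hit calling

`qc_metrics()` pools control wells across plates (interplate QC) and
reports means, sample SDs ($n-1$ denominator throughout; the convention is
not universal, so it is stated here), the assay window
$\mu_{\mathrm{inh}} - \mu_{\mathrm{neg}}$ and the Z′-factor
$1 - 3(\sigma_{\mathrm{inh}} + \sigma_{\mathrm{neg}})/|\mu_{\mathrm{inh}} -
\mu_{\mathrm{neg}}|$. Statistics are rounded only at report time (2
decimals).

`call_hits()` uses an inclusive threshold ($\Delta C_q \ge$ threshold), the
published convention. The pooled-screen default is the absolute 0.80
cycles (more than eight noninhibited SDs in the campaign that motivated
it); `threshold_from_sd()` supports the $k\sigma$ policy (individual-format
screens used $k = 3$). Note the published individual-format cutoff 0.66
does not equal 3 × its printed SD 0.18 (= 0.54); both a $k\sigma$ and an
absolute override are therefore supported, and no attempt is made to
resolve which SD produced 0.66. Likewise the Z′ formula applied to the
printed individual-format control statistics gives 0.91, not the printed
0.94 (the control subset used there is unstated); only the pooled-screen
Z′ is treated as reproducible.

## Counter-screen interference filtering

Compounds can shift Cq without binding the target — chelators that strip
the His-tag capture metal, or qPCR inhibitors. The counter-screen re-tests
every well with a saturating concentration of a known reference ligand
(83 nM, Kd 0.26 nM): genuine competitors can displace no further probe,
interferers still shift Cq. Counter $\Delta C_q$ is computed against the
counter plate's *own* saturated compound-free baseline (the original
negative controls, now ligand-containing), since "no additional change"
is only meaningful within the counter plate.

Two deliberate design choices:

* **Significance multiplier 4, not 3.** The filter is applied per hit well
  in singlicate. At $3\sigma$ the per-well false-"interferer" probability
  is ≈ 1.3 × 10⁻³, so across replicated validation screens a genuine
  binder would occasionally be discarded — contradicting the published
  outcome that every pooled hit survived deconvolution. A $4\sigma$ default
  keeps family-wise false flagging negligible while retaining ≈ 6σ power
  against the ≥ 1.5-cycle shifts modelled. The multiplier is configurable
  (`counter_k`), as the underlying campaign reported only "a significant
  change".
* **A documented physical limitation.** At the 9 µM screening
  concentration, a binder with Kd ≲ 50 nM out-competes 83 nM of a 0.26 nM
  reference ligand ($9000/K_I \gg 319$) and therefore *does* shift Cq in
  the counter-screen: the filter would discard a genuinely superb binder as
  an interferer. The logic is sound only for the weak-hit regime the
  original campaign encountered. A test asserts this behaviour explicitly,
  and the end-to-end validation plants binders with Kd 0.5–5 µM, the regime
  the counter-screen design actually covers.

`deconvolution_plan()` expands each surviving hit pool into individual
retests at 10 µM; `confirm_hits()` re-applies the threshold per compound (a
pool may confirm several compounds); `screen_summary()` reports counts and
percentage rates at 2 significant figures.

## The synthetic-data generator: what it emulates, what it does not

`generate_library()` plants three compound classes: inactive (Kd = ∞),
binders (log-uniform Kd over 0.1–5,000 nM unless given explicitly), and
interferers, modelled as an additive Cq shift (default +1.5 cycles,
matching the magnitude needed to clear the hit threshold the way chelator
artefacts did) present identically in screen and counter-screen — the
minimal mechanism reproducing "still shifts Cq under saturating ligand".
By default actives are placed at evenly spaced plating positions so that
sequential pooling yields at most one active per pool; this matches the
pooled format's operative assumption and the strongest-competitor pool
approximation (`exact_pool = TRUE` solves the full multi-competitor
equilibrium for stress tests; with one active per pool the two agree to
numerical precision).

`layout_plates()` fills 384-well (or 96-well) plates with sequential pools
of 11 plus per-plate controls: 12 negative, 8 maximally inhibited
(reference ligand at 2,500 nM — chosen because it reproduces the ≈ 13-cycle
window; the composition of the real most-inhibited wells is unpublished),
and a positive-control series of six 3-fold dilutions from 100 nM in
duplicate (the published series used six points in duplicate but did not
print its concentrations). `simulate_cq()` adds homoscedastic Gaussian Cq
noise, SD 0.15 by default (between the reported 0.14 and 0.18); noise in
the Cq domain is how variability is reported for this assay. A single
global seed drives every draw; identical seeds give byte-identical outputs.

What the generator does **not** emulate — so a green end-to-end test does
not establish robustness against it: spatial plate effects (edge,
evaporation, row/column gradients; the original campaign applied no
correction either), compound carry-over, heteroscedastic or non-Gaussian
Cq noise, amplification-curve artefacts below the Cq abstraction, and
pool-level synergy between multiple actives (available only behind
`exact_pool`).

## Numerical choices and degenerate inputs

* Equilibrium root: bracketed on $[0, T]$, relative tolerance $10^{-10}$,
  Newton-polished; conservation is verified and violation is an error, not
  a warning.
* `Inf` is the sentinel for inactive compounds; all expressions are written
  in forms where it contributes exactly zero occupancy.
* Cq values are never rounded internally; report writers round to 2
  decimals, rates to 2 significant figures.
* Ties at thresholds are inclusive (≥) everywhere, per the published
  convention.
* Censored measurements are typed flags (`"low"`, `"high"`, `"missing"`),
  never `NaN`/`Inf`; all-censored series return a flagged estimate with
  `n_used = 0`.
* Concentrations are nM internally; file I/O uses explicitly named
  `i_tot_nM` columns, so unit mix-ups fail loudly at parse time.
* Configuration files are JSON (human-readable, schema-checked);
  stage outputs are plain CSV with stable column order.

## Known limitations

* The counter-screen blind spot for very strong binders described above.
* The single-well estimator's small positive bias under Cq noise (Jensen);
  use the dilution-series average, as the published procedure does, and
  treat sub-percent systematic shifts as below the method's resolution.
* `run_pipeline()` on files analyses whatever stages have inputs present;
  it does not impute missing stages.
* No dose–response (IC50) fitting and no kinetic modelling: the assay is
  equilibrium-only by design.
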