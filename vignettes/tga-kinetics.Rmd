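---
title: "Modelling multi-step thermal decomposition kinetics with tgakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multi-step thermal decomposition kinetics with tgakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

tgakin describes the thermal decomposition of an organic solid as a chain of
three consecutive transformations, A → B → C → D, each governed by an
Arrhenius rate constant $k_x(T) = A_x \exp(-E_x/RT)$ and an autocatalytic
Šesták–Berggren rate function $f(\alpha) = \alpha^M (1-\alpha)^N$. The
observable is the relative sample mass, reconstructed from the state
occupations $m_A \dots m_D$ through the balance

$$m_{rel} = w_1 (1-m_A) + w_2 (m_C+m_D) + (1-w_1-w_2)\, m_D, \qquad
  m = m_{t=0} + \Delta m \; m_{rel},$$

so that $w_1, w_2$ are the fractional contributions of the first two steps
to the total mass change $\Delta m$ (negative for loss). The model assumes:

* decomposition is strictly sequential — no parallel channels, no
  re-combination;
* each step's temperature dependence is Arrhenius with either a constant
  $E$ or a temperature-dependent $E(T)$ from a curved Kissinger plot;
* mass transport, heat transport and atmosphere chemistry are not modelled
  explicitly — different atmospheres are represented by different parameter
  sets.

## Conversion conventions, seeding and gating

The rate equations couple the steps through the conversion argument fed to
each $f$. tgakin provides two conventions.

The default, `conversion = "step"`, gives each step its own conversion
coordinate: $\alpha_1 = 1-m_A$, $\alpha_2 = (m_C+m_D)/(1-m_A)$,
$\alpha_3 = m_D/(m_C+m_D)$. Each rate then vanishes both before its step
has started and once its source species is exhausted, occupations stay in
$[0,1]$, and well-separated steps produce distinct derivative (DTG) peaks —
the morphology a three-step TGA record actually shows. The alternative,
`conversion = "product"`, feeds the raw product amounts ($m_B$, $m_C$,
$m_D$) to the respective rate functions. Taken alone, that form has two
defects: a rate does not stop when its *source* species runs out (so
occupations can leave $[0,1]$), and the coupling lets a later step drain an
earlier step's rate argument, which merges and displaces the DTG peaks.
The step convention was therefore made the default; the product convention
remains available for comparison.

Two regularisations apply in both conventions:

* **Seeding.** The pristine state $(1,0,0,0)$ is a fixed point of any
  product-catalysed form ($f(0)=0$ for $M>0$), so the integrator starts at
  $m_B = m_C = m_D = \varepsilon$, $m_A = 1-3\varepsilon$ with
  $\varepsilon$ = `seed_eps` (default $10^{-8}$). Halving the seed changes
  $m_{rel}$ by less than $10^{-4}$ everywhere on the reference models; a
  test asserts this.
* **Source gating.** Every rate is multiplied by a $C^1$ smoothstep of its
  source species over $[0, 10^{-6}]$. In the product convention this is
  what stops an exhausted step. In the step convention it matters
  numerically: in the supply-limited regime the decelerating factor
  $(1-\alpha_2)^{N_2} = (m_B/(1-m_A))^{N_2}$ with $N_2 < 1$ is not
  Lipschitz in $m_B$ at zero, and a stiff solver can stall on that sliding
  boundary; the gate makes the right-hand side Lipschitz while only acting
  below one ppm of source material.

## Numerical integration

The three-state system ($m_D$ is closed algebraically as
$1 - m_A - m_B - m_C$, so conservation is exact by construction) is solved
with deSolve's `lsoda` and a compiled right-hand side, at `rtol = 1e-8`,
`atol = 1e-10`. These defaults resolve the steep autocatalytic onsets
(where $\alpha^M$ with $M<1$ has unbounded slope) over rate constants
spanning many decades across a 30–550 °C scan. If a pathologically stiff
parameter draw exhausts the step budget, the solver retries with a larger
budget and finally with tolerances relaxed to $10^{-6}/10^{-8}$ —
conservation is unaffected, and the tight-tolerance result is used whenever
it converges. Temperature programs are piecewise linear (ramp and hold
segments, kelvin and seconds internally, °C only at I/O boundaries);
queries beyond the program end raise an error rather than extrapolate. For
temperature-dependent $E$, the exponent uses $E(T)$ at the instantaneous
program temperature, clamped at the validity-window edges with a warning.

The adaptive solver is validated two ways: against an independently written
fixed-step RK4 oracle (on a smooth product-convention toy, where a fixed
step converges; the step convention's seed-scale boundary layer is
resolvable only by an adaptive method and is instead checked on a
single-step model), and against the plain-R implementation of the same
right-hand side.

# The synthetic study design

`generate_study()` emulates a two-atmosphere, ten-heating-rate measurement
series: linear scans 30–550 °C at $q^+ \in \{0.1, 0.2, 0.5, 1, 2, 3, 5, 7,
10, 20\}$ °C/min, one fresh sample per scan, sampled once per second and
capped at 20 000 points per curve (slow scans are sampled proportionally
more coarsely). The two built-in truth models are synthetic stand-ins, not
fitted values for any real substance: their activation energies lie in
150–220 kJ/mol, their pre-exponents were calibrated once (by root-finding
on the forward model) so the three DTG peaks at 10 °C/min fall near 275,
315 and 350 °C with realistic overlap, and their weights reproduce
three-plateau mass-loss patterns (100 → 88 → 44 → 9 % for the inert-like
set, 100 → 88 → 57 → 20 % for the oxidising-like set).

The noise model reflects instrument reproducibility rather than white
noise alone:

* a single per-curve temperature-axis offset, uniform in ±2 °C (run-to-run
  reproducibility is a systematic shift, not point jitter);
* per-curve relative perturbations of the step weights (σ = 3 %) and of the
  total mass change (σ = 2 %) — these perturb the *generating* parameters,
  i.e. sample-to-sample variability, and the realised values are recorded
  in the study manifest as each curve's own truth;
* per-point Gaussian balance noise, σ = 0.05 % of initial mass.

All randomness flows from one master seed, split per curve as
`seed*1000 + index`; the manifest records each curve's seed so any single
curve can be regenerated bit-exactly. What the generator does *not*
emulate: baseline curvature and buoyancy drift, oxygen-diffusion-limited
char formation, melting events, and mass-gain artefacts. Passing the
closed-loop tests therefore demonstrates correctness of the estimators
under the stated noise structure, not robustness to every instrumental
pathology of real data.

# Peak detection and the Kissinger analysis

dm/dT is estimated by local linear regression of mass on temperature over a
fixed ΔT = 2 °C window centred on each grid temperature — exact for linear
data and robust to uneven sampling and point noise. For peak picking the
derivative is additionally smoothed by a ±2 °C moving average, and the
`n_steps` most prominent local minima above a prominence threshold
(default 5 % of the global maximum loss rate) are taken, ordered by
temperature. Prominence (depth below the lower of the two barriers
separating a minimum from deeper minima) suppresses noise wiggles without
biasing peak positions.

Each step's peak temperatures across heating rates enter the Kissinger
coordinates $y = \ln(q^+/T_p^2)$, $x = 1/T_p$ (with $q^+$ converted to K/s
internally — the unit choice shifts only the intercept, a property under
test). A straight line gives $E = -R \cdot \mathrm{slope}$. Curved plots
are fitted with $y = a + bx + cx^2$ *in these coordinates* (the quadratic
could equally be taken in $T_p$; the 1/T choice makes
$E(T) = -R\,dy/dx = -R(b + 2c/T)$ exact), valid over the observed $T_p$
range. Mode selection is deterministic: quadratic iff the
extra-sum-of-squares F-test for the quadratic term has $p \le 0.05$ *and*
the implied $E(T)$ stays positive over the window; ties go to quadratic.
For the per-curve fit hand-off, constant-E steps pass their global $E$;
temperature-dependent steps pass $E(T_p)$ evaluated at that curve's own
peak.

# The per-curve fit (sc-MKA)

Each curve is fitted separately by bounded Levenberg–Marquardt least
squares (minpack.lm) on the unweighted residuals of the mass signal in
percent units, with the three activation energies fixed and
$\log_{10} A_{1..3}$, $M_{1..3}$, $N_{1..3}$, $w_1$, $w_2$ free (bounds:
$\log_{10}A \in [2,20]$, $M \in [0,3]$, $N \in [0.05,12]$, $w \ge 0$ with
$w_1 + w_2 \le 1$ enforced by a soft penalty residual). Design choices:

* **Δm** is fixed from the data's final plateau by default (mean of the
  last 2 % of points, after checking that the regression slope of the last
  5 % is below 0.02 %/°C) — optimising it adds a degenerate direction; a
  free mode and a fixed-value mode exist.
* **Forward model on the curve's grid.** The model is integrated under a
  linear ramp through the curve's recorded temperature endpoints, on the
  curve's own time grid thinned to at most 800 points. The thinning sets
  the per-iteration cost; 800 points leave the estimates indistinguishable
  from full-grid fits on the reference study.
* **Initialisation and multistart.** Autocatalytic fits are multi-modal,
  so a 3×3 grid over $M_0 \in \{0.1, 0.5, 1.0\}$, $N_0 \in \{0.5, 1.5, 4\}$
  defines nine starts; per start, $\log_{10}A$ is initialised by matching
  each detected peak's loss rate ($k(T_p) f(0.5) \approx$ observed peak
  step-conversion rate), and $w_1, w_2$ from the mass levels at the
  inter-peak valleys. All nine starts are evaluated; the four with the
  lowest initial RSS are probed with 12 LM iterations each and the best
  probe is polished to convergence. The final RSS is asserted against
  every start's initial RSS.
* **Determinism.** There is no randomness anywhere in the fit; identical
  inputs give bit-identical results. Integration failures at pathological
  trial points return a large penalty residual instead of aborting.

Fit quality is reported as the squared Pearson correlation between the
observed and calculated mass series. Because $E$ and $\ln A$ compensate
(the kinetic compensation effect), a few-percent error in a fixed $E$
shifts the fitted $\log_{10} A$ by several tenths while leaving the curve
description and the step weights essentially unchanged — the tests assert
the positive sign of that co-movement, and the acceptance script reports
parameter recovery both with Kissinger-derived and with truth activation
energies for exactly this reason.

# Predictions

`predict()` integrates a fitted (or constructed) model over an isothermal
hold, optionally preceded by a heating ramp. Conversion is reported as the
total-mass-loss-normalised progress ($\alpha \equiv m_{rel}$), alongside
percent mass loss $|\Delta m| \cdot m_{rel} \cdot 100$. The reporting clock
starts at the hold onset; conversion accumulated during the ramp appears as
a separate pre-conversion figure, which makes the question "does the
pre-heat matter?" directly quantifiable. Threshold times (default 0.1 %,
1 %, 5 %) are found by linear interpolation between bracketing grid points;
thresholds not reached within the hold return `NA`. For
temperature-dependent $E$ bases, $E(T)$ is clamped at its validity-window
edges with a warning — extrapolating a quadratic Kissinger fit outside the
measured peak range is not defensible, so the package pins it instead.

`compare_bases()` tabulates conversion at fixed report times and the time
to 1 % conversion for several parameter bases (e.g. fits from different
heating rates or atmospheres) against a declared reference — the tool for
judging how strongly a prediction depends on which measurement the kinetics
came from.

# Problem sizes and limitations

The test-suite defaults keep everything desk-scale: curves capped at
20 000 points, fits on 800-point grids, the closed-loop study at its full
2 × 10 design, conservation sweeps over 100 random parameter draws at 150
output points, and the RK4 oracle at 10 000 fixed steps on a 100-second
window. The acceptance script runs the full pipeline in a few minutes on
one CPU.

Known limitations: exactly three steps (the scheme is not generic in the
number of states); no heat-flow (DTA/DSC) modelling; no mass gain; no
oxygen-transport term (atmospheres differ only via parameter sets); joint
multi-curve (global) fitting is deliberately out of scope — sc-MKA's point
is the per-curve resolution of parameter trends; and the step-identity
assignment is by temperature order, so steps that cross or merge between
heating rates would need manual curation.
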