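# tgakin

Solid-state decomposition kinetics from thermogravimetric (TGA) mass-loss
curves, for thermal-analysis and formulation scientists who need to know how
fast a drug substance (or any organic solid) degrades at processing
temperatures — e.g. during hot-melt extrusion (minutes at 120–170 °C) or
fused-deposition 3D printing (tens of seconds at 150–230 °C).

## The model

A three-step consecutive decomposition scheme

    A -> B -> C -> D

in which each transition x has Arrhenius kinetics with an autocatalytic
Šesták–Berggren rate function,

    dα_x/dt = A_x · exp(−E_x / RT) · α_x^{M_x} (1 − α_x)^{N_x},

and the observable relative mass is reconstructed from the state occupations
m_A … m_D via

    m_rel = w1·(1 − m_A) + w2·(m_C + m_D) + (1 − w1 − w2)·m_D
    m     = m(t=0) + Δm · m_rel,

where w1, w2 are the fractional contributions of the first two steps to the
total mass change Δm. The workflow mirrors standard practice in
multi-heating-rate kinetic analysis:

1. **Peak temperatures** — the derivative dm/dT is estimated by local linear
   regression over a ΔT = 2 °C window and the three most prominent
   loss-rate peaks are located per curve.
2. **Activation energies** — the Kissinger method, ln(q⁺/Tp²) = −E/(R·Tp) +
   const, fitted per step across heating rates; visibly curved plots are
   handled with a quadratic extension whose derivative gives a
   temperature-dependent E(T) = −R(b + 2c/T).
3. **sc-MKA** — single-curve multivariate kinetic analysis: per-curve
   bounded Levenberg–Marquardt least squares with E fixed per step (E(Tp)
   for curved steps), leaving log10 A, M, N, w1, w2 free; this resolves the
   heating-rate dependence of the kinetic parameters.
4. **Predictions** — the fitted model extrapolated to isothermal holds
   (optionally after a heating ramp), with time-to-threshold degradation
   summaries.

A synthetic-data generator (`generate_study()`) emulates a two-atmosphere,
ten-heating-rate study design (0.1–20 °C/min scans, 30–550 °C) with the
reproducibility figures of a modern simultaneous thermal analyser, so the
entire pipeline can be validated closed-loop without any measured data.

## Worked example

```r
library(tgakin)

study <- generate_study(study_design(q_list = c(0.5, 2, 5, 10, 20)),
                        noise = noise_spec(seed = 42))
ka <- kissinger_analysis(study$curves)
ka$fits[["N2.1"]]
#> Kissinger fit (linear): E = 175.5 kJ/mol, r^2 = 0.99754

fe  <- fixed_E_for_curve(ka, "N2_q10")
fit <- fit_curve(study$curves[["N2_q10"]], fit_spec(fixed_E = fe))
summary(fit)
#> sc-MKA fit of curve N2_q10 (q+ = 10 C/min, 800 fit points)
#> fixed E: 175.5, 204.7, 236.7 kJ/mol
#>     lA1     lA2     lA3      M1      M2      M3      N1      N2      N3      w1
#> 15.2069 16.6641 18.2473  0.4477  0.4240  0.4453  1.1951  1.4318  1.5375  0.1368
#>      w2
#>  0.4594
#> delta_m = -0.8807, RSS = 2.009, r^2 = 0.999998, winning start 5

predict(fit, prediction_protocol(230, 3600, resolution = 1))
#> Prediction: hold at 230 C for 3600 s
#>   conversion at end of hold: 0.12586 (pre-conversion 0)
#>   time to alpha = 0.001: 95.1 s
#>   time to alpha = 0.01: 412.0 s
#>   time to alpha = 0.05: 1219.4 s
```

Reading the output: the Kissinger step-1 fit across five heating rates gives
E = 175.5 kJ/mol with an essentially linear plot (r² = 0.998). Fixing the
three step energies and fitting the 10 °C/min curve recovers the per-step
pre-exponents (as log10 A), the autocatalytic exponents M and N, and the
step weights — here steps 1–3 carry 13.7 %, 45.9 % and 40.4 % of an 88.1 %
total mass loss — with a fit r² of 0.999998. Extrapolated to a 230 °C hold,
the fitted kinetics predict 1 % conversion after about 7 minutes, i.e. a
printing-scale exposure of ~30–60 s at that temperature stays well below 1 %
degradation.

The same pipeline is scriptable from a shell via `inst/cli/tgakin`
(subcommands `simulate`, `kissinger`, `fit`, `predict`, `report`); see
`?tga_cli`.

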