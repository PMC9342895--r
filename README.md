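# kaifluor

Deconvolution and rhythm analysis of KaiC tryptophan fluorescence.

The cyanobacterial circadian oscillator can be reconstituted in vitro from
the proteins KaiA, KaiB and KaiC. KaiC cycles daily through four
phosphorylation states of its Ser431/Thr432 sites, in the order
ST → SpT → pSpT → pST → ST, and its tryptophan emission — integrated over
the 320–370 nm band and normalized to protein concentration and an
N-acetyl-L-tryptophan amide (NATA) standard — tracks that cycle. `kaifluor`
is for biochemists and clock researchers who record such fluorescence time
courses alongside gel-quantified phosphostate abundances and want to ask:
*how much fluorescence does each phosphostate contribute, and how
temperature-compensated is the rhythm?*

## The model

The apparent fluorescence is modelled as a linear mixture of the four
states,

```
F_app(t) = F_SpT·A_SpT(t) + F_pSpT·A_pSpT(t) + F_pST·A_pST(t) + F_ST·A_ST(t) [+ offset]
```

where `A_i(t)` are the relative state abundances (a point on the
3-simplex). The per-state intensities `F_i` are estimated by ordinary least
squares. Because the abundances sum to one, a free constant offset is
exactly collinear with the mixture and is instead estimated in a second
stage with the `F_i` held fixed (`fit_offset()`), which mirrors how such
backgrounds — e.g. KaiA fluorescence — are handled in practice. The
contribution of an engineered tryptophan probe (F419W) is the per-state
difference between two constructs (`extract_w419()`).

Rhythms are quantified by nonlinear least-squares cosine–Fourier fitting
(`fit_period()`, harmonics K = 1–3), and temperature compensation by the
Arrhenius analysis of the cycle frequency 24/period: the slope of
ln(24/period) against 1/T gives the activation energy `E_a = −slope·R`
(R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹), and
`Q10 = exp[(E_a/R)(1/T₁ − 1/T₂)]` for T₁ = 303.15 K, T₂ = 313.15 K.
A perfectly compensated clock has Q10 = 1; an ordinary reaction with
Q10 = 2 corresponds to E_a ≈ 13.1 kcal/mol.

A synthetic-data module generates phosphostate relaxation kinetics (matrix
exponential of a first-order rate map), periodic simplex-valued oscillation
waveforms, per-state skew-normal emission bands, and noisy `F_app` traces,
so the whole pipeline is testable without instrument data.

## Worked example

```r
library(kaifluor)

rep <- run_pipeline(run_config(rng_seed = 7))
subset(rep$recovery, quantity %in% c("F_SpT", "F_ST", "period_h", "q10"))
```

```
   temperature_c quantity     true estimated          se
1             30    F_SpT 40.00000 48.567534 6.647278113
4             30     F_ST 38.00000 37.795352 0.129408544
6             30 period_h 24.70000 24.670124 0.042750569
8             35 period_h 23.00677 22.969372 0.039395534
10            40 period_h 21.47826 21.493253 0.031533769
12            NA      q10  1.15000  1.147825 0.001836748
```

The pipeline (i) simulates an auto-dephosphorylation experiment (KaiC
alone) and refits the per-state intensities from 2%-noise data — the
poorly populated SpT state is recovered with an honest, large standard
error while the dominant ST state is tight; (ii) simulates oscillations at
30/35/40 °C with true period 24.7 h at 30 °C and Q10 = 1.15, estimates
each period by cosine fitting (all within ±0.04 h here); and (iii) pools
them into an Arrhenius fit whose Q10 estimate, 1.148 ± 0.002, matches the
generating value of 1.15 — a temperature-compensated rhythm.

Single steps are available directly: `fit_state_fluorescence()`,
`fit_offset()`, `extract_w419()`, `fit_period()`, `arrhenius_fit()`,
`q10_ea_convert()`, `integrate_band()`, `find_lambda_max()`,
`difference_spectrum()`. A command-line wrapper lives at
`inst/scripts/kaifluor-pipeline.R`.

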