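# kvrecoil

Rheological analysis of laser-ablation recoil in epithelial tissue.

When a pulsed laser cuts a few cells in a stressed epithelium (the
*Drosophila* pupal wing is the motivating system), the tissue recoils. The
kinetics of that recoil carry mechanical information that a single "initial
recoil velocity" number conflates: how much displacement is released, how
fast, and by which structures. `kvrecoil` is for experimentalists and
modellers who want to go beyond the velocity proxy: it fits the full recoil
kinetics with a two-timescale viscoelastic model, extracts the input traces
from kymographs, and provides the surrounding quantification — cell
elongation tensors, a coarse shear decomposition, and the group-comparison
and subsampling-power statistics used to interpret weak genotype phenotypes.

## The model

Post-ablation bond displacement is described by two Kelvin–Voigt elements in
series released from a constant pre-stress σ:

    Δx(t) = X_f (1 − e^(−t/τ_f)) + X_s (1 − e^(−t/τ_s))

with `X_f,s = σκ/k_f,s`, `τ_f,s = η_f,s/k_f,s`, `κ = k/(k + k̄)`,
`k̄ = k_f k_s/(k_f + k_s)`. The fast mode (τ_f ≲ 1 s) reflects the ablated
cell's own cortical mechanics; the slow mode (τ_s ~ 20 s) the collective
relaxation of the surrounding network. Because the ablation itself blanks
the first δt = 0.65 s of imaging, the conventional initial recoil velocity
`v = Δx(δt)/δt` is dominated by the fast mode: about 63% of X_f but only
~3% of X_s has relaxed at first observation, so the fast mode contributes
over 80% of v at typical displacement magnitudes. The package's central
point is that a genotype difference in v need not be a difference in tissue
stress — it can sit entirely in the fast elastic constant.

## Worked example

Simulate a kymograph at the measured acquisition settings (0.2 µm/px,
0.09 s frames, 0.65 s dark gap), track the two membranes, extract the
displacement trace and fit the model:

```r
library(kvrecoil)

p   <- relaxation_params(X_f = 2.2, X_s = 7.0, tau_f = 0.65, tau_s = 20)
kym <- generate_kymograph(p, noise_sd = 0.05, seed = 42)

track <- track_membranes(preprocess_kymograph(kym))
tr    <- extract_displacement_trace(track, kym)
fit   <- fit_relaxation(tr)
summary(fit)
#> Kelvin-Voigt recoil fit, model order 2
#>       Estimate Std. Error
#> X_f      2.186      0.004
#> X_s      7.004      0.004
#> tau_f    0.629      0.006
#> tau_s   19.935      0.032
#> residual RMS 0.01403 um on 660 points
```

All four generating parameters are recovered from the image alone: 2.19 vs
2.2 µm and 0.63 vs 0.65 s for the fast mode (most of whose relaxation is
hidden inside the dark gap), 7.00 vs 7.0 µm and 19.9 vs 20 s for the slow
mode. The residual RMS (0.014 µm) reflects the sub-pixel tracking noise.
The image-based initial recoil velocity agrees with the closed form:

```r
recoil_velocity_from_kymograph(track, kym)   # 2.624 um/s
initial_recoil_velocity(p)                   # 2.484 um/s
compare_exponential_orders(tr)$preferred     # 2 -- one timescale is not enough
```

and a single-exponential fit is decisively rejected (residual RMS 0.42 vs
0.014 µm; AICc −1149 vs −5622): the recoil genuinely has two timescales.

Other entry points: `mean_Q()` / `elongation_tensor()` for the PD cell
elongation on segmented polygons, `align_to_peak()` for the hRPCE time
origin, `coarse_shear_decomposition()` for total = cell-shape +
rearrangement accounting, `dispatch_test()` / `power_curve()` for the
genotype statistics, and `genotype_scenario()` + the `generate_*` family for
fully seeded synthetic inputs. A thin CLI wrapping the same functions is
installed as `exec/kvrecoil` (subcommands `simulate-*`, `fit`, `recoil`,
`trace`, `elongation`, `decompose`, `align-peaks`, `compare-groups`,
`power`).

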