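# retronmr

Low-field time-domain ¹H NMR relaxometry analysis of starch retrogradation.

When a gelatinized starch paste is stored, its polymers (amylose quickly,
amylopectin slowly) re-order into a network that binds water and expels the
rest — retrogradation. Benchtop NMR watches this through the water protons:
the spin–lattice relaxation time T1 reports the bulk-to-bound water balance,
the spin–spin relaxation time T2 reports water mobility, and a
multi-component T2 decay signals distinct water pools (a short "bound"
component T2s and a long "bulk" component T2l in high-amylose pastes). Both
relaxation times are macroscopic; the microscopic quantity of interest is the
mean rotational correlation time τ_c of the water molecules, which spans
about 10⁻¹² s (pure water) to 10⁻⁶ s (ice) and so resolves subtle changes in
paste microviscosity over weeks of storage.

`retronmr` is for researchers in food/biopolymer physical chemistry who want
that whole chain as tested, reusable code:

1. **Simulation** (`synthetic_truth()`, `generate_inversion_recovery()`,
   `generate_cpmg_train()`, `generate_storage_series()`): inversion-recovery
   curves `Mz(t) = M0 (1 − 2 e^{−t/T1})` and CPMG echo trains
   `Mxy(kTE) = M0 Σᵢ pᵢ e^{−kTE/T2ᵢ}` with known ground truth and seeded
   Gaussian amplitude noise. A bundled reference table
   (`corn_starch_relaxation()`) carries measured T1/T2 values for 5% pastes
   of normal (NCS), waxy (WCS) and Hylon (HCS) corn starch with Arabic, guar
   and xanthan gum over 1–90 days of cold storage, and drives the default
   study design.
2. **Fitting** (`fit_t1_inversion_recovery()`, `fit_t2_multiexponential()`,
   `select_component_count()`): Marquardt nonlinear least squares with the
   fraction constraint Σpᵢ = 1 built into the parameterization, AICc-based
   "spin grouping" to choose the number of discrete proton pools, curvature
   standard deviations, and bound/bulk water labels
   (`label_water_fractions()`).
3. **BPP inversion** (`bpp_rates()`, `t1_t2_ratio()`, `solve_tau_c()`,
   `tau_c_uncertainty()`): the Bloembergen–Purcell–Pound relations
   1/T1 = (6/20) C [τ_c/(1+x²) + 4τ_c/(1+4x²)] and
   1/T2 = (3/20) C [3τ_c + 5τ_c/(1+x²) + 2τ_c/(1+4x²)], x = ϖτ_c,
   whose coupling-free ratio R(x) = T1/T2 is strictly monotone — so a
   measured (T1, T2) pair at a known Larmor frequency inverts to a unique
   τ_c by bisection, with the coupling constant C (and an effective
   interproton distance) recovered afterwards, plus delta-method intervals
   from the reported ± SDs.
4. **Storage trends** (`build_series()`, `percent_change()`,
   `compare_groups()`, `summarize_table()`): per-sample day series, percent
   changes of τ_c over storage, one-way ANOVA with Tukey HSD homogeneous
   subsets, and mean ± SD tables with significance letters in the layout
   conventional for storage studies.

The `analysis/` directory holds the study as four numbered drivers
(`01_simulate.R` → `04_storage_trends.R`): simulate the full 12-sample ×
5-day design at SNR 200 in triplicate, fit every curve, invert to τ_c, and
write trend and summary tables under `results/`.

## Worked example

Simulate a noisy two-pool Hylon-style echo train, let spin grouping find the
pools, and invert the bound-water pair to a correlation time:

```r
library(retronmr)

curve <- generate_cpmg_train(
  synthetic_truth(m0 = 100, t2_ms = c(220, 785), fractions = c(0.3, 0.7),
                  noise_sd = 0.5),                       # SNR 200
  cpmg_protocol(n_echoes = 1024), seed = 7)

fit <- select_component_count(curve, max_components = 3)
fit
#> <relaxation_fit> T2, 2 component(s), M0 = 100, RSS = 87.2
#>   T21 = 220.9 +/- 2.2 ms  (p = 0.302 +/- 0.004)
#>   T22 = 786.6 +/- 2.1 ms  (p = 0.698 +/- 0.002)

label_water_fractions(fit)
#> # A tibble: 2 x 4
#>   component time_ms fraction label
#>       <int>   <dbl>    <dbl> <chr>
#> 1         1    221.    0.302 bound_s
#> 2         2    787.    0.698 bulk_l

solve_tau_c(1401, fit$components$time_ms[1])
#> <correlation_time> tau_c = 2.621e-08 s (x = 2.471, dispersive)
#>   from T1 = 1401 ms, T2 = 220.9 ms at 15 MHz
```

The fitter recovers the generating pools (220/785 ms, fractions 0.3/0.7)
within their reported standard deviations, and the bound-water τ_c of
2.6 × 10⁻⁸ s sits where a starch-gel bound fraction should: well above pure
water (10⁻¹² s), far below ice (10⁻⁶ s). With the measured ± SDs,
`tau_c_uncertainty(1401, 4, 220, 1)` gives τ_c = 2.63 × 10⁻⁸ s with a 95%
interval of [2.61, 2.65] × 10⁻⁸ s.

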