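# dopatherm

Temperature-dependent thermodynamics of tyrosinase diphenol-oxidase
kinetics in R.

Tyrosinase oxidizes L-DOPA to dopaquinone, which cyclizes to dopachrome —
an orange-red product whose absorbance at ~475 nm is the standard readout
for diphenol-oxidase activity. Because the Michaelis constant approximates
the dissociation constant when product release is much slower than complex
dissociation (k₂ ≪ k₋₁), measuring Km at several temperatures gives access
to the *apparent thermodynamic signature* of L-DOPA binding through a
van 't Hoff analysis. `dopatherm` implements that pipeline for people who
run plate-reader kinetics and/or consume docking output: assay curves in,
(ΔH, ΔS, ΔG(T)) out, with a docking branch and an offset model connecting
the two.

The core relations:

- Beer–Lambert: `c (mM) = A / (ε·L)` with ε = 3700 M⁻¹cm⁻¹, L = 0.3 cm for
  dopachrome.
- Initial velocity: OLS slope of concentration over the first eight
  minutes of each reaction.
- Michaelis–Menten: `v = Vmax·S / (Km + S)`, fitted by nonlinear least
  squares in (log Km, log Vmax).
- van 't Hoff: `ln(K/[E]) = (−ΔH/R)·(1/T) + ΔS/R`, with K the association
  constant normalized by enzyme concentration and R = 8.314 J/(K·mol).
- Docking branch: a binding-energy magnitude E becomes a molar affinity via
  `Kd = exp(−E/RT)`, after "correctly docked" poses are selected by
  ligand-oxygen-to-copper distance (the CuA/CuB pair defines the active
  site).
- Dopachrome offset: the kinetics points sit a vertical distance DC from
  the docking association line, `ln Km-line(1/T) = ln K-line(1/T) + DC`;
  the corresponding free-energy cost is `ΔG_dc = R·T·|DC|`.

A synthetic-data module generates progress curves (fixed-step RK4
integration of Michaelis–Menten depletion + Beer–Lambert + Gaussian plate
noise), docking-energy tables with decoys, ligand-pose PDB fixtures, and
paired calorimetry/absorbance rate tables — all with known ground truth,
so every stage of the pipeline is testable without any external data.

## Worked example

```r
library(dopatherm)

params <- sim_params(seed = 1L)            # 2 mOD noise, 3 replicates
plate  <- simulate_progress_curves(params)
rates  <- plate |> subtract_baseline() |> initial_velocities()
km_tab <- rates |> fit_michaelis_menten_by() |> aggregate_replicates()
km_tab
#> # A tibble: 4 × 6
#>   temperature_C km_mM   sem_km vmax_mM_min   sem_vmax n_fits
#> 1            25 0.495 0.00275       0.0295 0.0000258       3
#> 2            31 0.624 0.00221       0.0326 0.0000454       3
#> 3            37 0.815 0.000720      0.0387 0.0000292       3
#> 4            43 0.808 0.000178      0.0591 0.00000604      3

sig <- km_tab |>
  build_vant_hoff_points(enzyme_conc_M = 1e-6) |>
  fit_vant_hoff()
sig
#> Apparent thermodynamic signature (van 't Hoff, OLS, n = 4)
#>   dH = -22.76 +/- 5.5 kJ/mol
#>   dS = -0.1282 +/- 0.018 kJ/(K mol)
#>   Pearson r = 0.947, adj R2 = 0.844
```

The Km column tracks the generating values (0.41–0.62 mM) with a
systematic upward shift of roughly 20% — the depletion bias of the
eight-minute initial-velocity window, discussed in the vignette. The
fitted ΔH ≈ −23 kJ/mol is the apparent binding enthalpy (negative:
enthalpy-driven association); ΔS here reflects the chosen [E]
normalization, which shifts only the intercept, never ΔH.

Two closed-form worked values:

```r
binding_energy_to_kd(25.71, 298.15)   # 0.0313 mM from a 25.71 kJ/mol pose
dopachrome_free_energy(6.07, 298.15)  # 15.05 kJ/mol for an offset of 6.07
```

`run_pipeline()` glues all stages together from a plate CSV, a docking
TSV and an optional receptor/pose PDB, and writes `fits.json`,
`thermo.json`, `dcshift.json`, a human-readable summary and a provenance
record. `autoplot()` methods and `plot_progress_curves()` cover each
result type; `tidy()`/`glance()` give broom-style access to every fitted
object.

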