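# cringpmf

Kinetic and thermodynamic simulation of the chloroplast proton motive force
(pmf) with variable ATP synthase c-ring stoichiometry.

## The scientific problem

The thylakoid F0F1-ATP synthase translocates one proton per c-subunit of its
rotor ring per rotation and releases three ATP per rotation, so its H+/ATP
ratio is `n = c/3`.  Across life the ring size varies from 8 to 17 subunits;
chloroplasts use an unusually large c14 ring (`n = 4.67`), which is
thermodynamically wasteful — more protons per ATP, and only 2.57 ATP per
2 NADPH from linear electron flow where the Calvin–Benson–Bassham cycle
needs 3.  This package models why the large ring may nonetheless be the
physiologically safer design.

The core thermodynamics: the pmf is `pmf = Δψ + z·ΔpH` with
`z = 2.303RT/F ≈ 0.0592 V`, and the dark pmf floor required to hold ATP
synthesis at equilibrium is

```
pmf_eq = ΔG_ATP / (n·F)
```

At ΔG_ATP = 40 kJ/mol this is ~89 mV for c14 but ~155 mV for c8.  With pmf
split 50/50 between Δψ and ΔpH, a c8 chloroplast would sit *in darkness* at
lumen pH 6.5 (photosynthetic control and qE quenching already engaged, b6f
turnover halved) and carry ~33 mV more membrane potential — and because the
PSII charge-recombination rate grows exponentially with Δψ (tenfold per
`0.06/f` volts), it would produce more singlet oxygen (¹O₂), especially
under fluctuating light.  The dynamic model (a stiff ODE system for
electron transfer, proton fluxes, the membrane capacitor, pH-gated b6f
control, qE, counter-ion movement and Δψ-dependent recombination) makes
those costs quantitative as orderings across ring sizes and light regimes.

See `vignettes/cring-pmf-model.Rmd` for the full model description,
parameter meanings, calibrations and limitations.

## Worked example

Dark ATP-synthase equilibrium across ring sizes (the closed-form table):

```r
library(cringpmf)
cmd_equilibrium(experiment_spec())
#>  c_subunits h_per_atp pmf_mv delta_psi_mv delta_ph_units lumen_ph b6f_relative_rate qe_extent atp_per_2nadph
#>           8      2.67  155.5         77.7          1.314     6.49             0.492   0.08604           4.50
#>          11      3.67  113.1         56.5          0.956     6.84             0.688   0.01213           3.27
#>          12      4.00  103.6         51.8          0.876     6.92             0.726   0.00741           3.00
#>          14      4.67   88.8         44.4          0.751     7.05             0.780   0.00334           2.57
#>          17      5.67   73.2         36.6          0.618     7.18             0.828   0.00140           2.12
```

Reading the c14 vs c8 rows: the c8 ring needs 155.5 mV of dark pmf instead
of 88.8 (a ΔpH of 1.31 units, lumen pH 6.49, where b6f is already slowed to
49% and qE is measurably engaged), while c14 rests at lumen pH 7.05 with
both regulatory systems off.  The `atp_per_2nadph` column shows the
trade-off: only c12 exactly matches the 3 ATP / 2 NADPH demand.

One hour of square-wave fluctuating light (0/200 µmol photons m⁻²s⁻¹,
period 600 s, same total dose as static 100):

```r
sq <- light_square_wave(0, 200, 600, 0.5, 3600)
simulate_run(cring_config(8),  thermo_params(), kinetic_params(), sq, grid_dt = 2)
#> trajectory: c8 ring, square_wave protocol, 3600 s, 1801 samples
#>   cumulative LEF 6e+04 e-/PSII, cumulative 1O2 191.7, min lumen pH 5.80, max dpsi 113.9 mV
simulate_run(cring_config(14), thermo_params(), kinetic_params(), sq, grid_dt = 2)
#> trajectory: c14 ring, square_wave protocol, 3600 s, 1801 samples
#>   cumulative LEF 9.107e+04 e-/PSII, cumulative 1O2 134.6, min lumen pH 6.39, max dpsi 86.6 mV
```

The small ring delivers ~34% less linear electron flow and ~42% more ¹O₂
over the hour — the modelled penalty of a small c-ring.  (Cumulative totals
are in events per mol PSII; absolute values depend on documented
calibrations, the orderings are the robust result.)

## Command line

```sh
Rscript inst/cli/cringpmf.R equilibrium                 # dark table
Rscript inst/cli/cringpmf.R fixtures  --out specs/      # default YAML specs
Rscript inst/cli/cringpmf.R simulate  --config specs/figure_fluctuating.yaml --out runs/
```

Exit codes: 0 success, 1 run failure, 2 configuration error.  `simulate`
writes one trajectory CSV and summary JSON per (ring, protocol) pair plus a
combined `comparison.csv`.

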