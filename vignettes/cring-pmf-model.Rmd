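---
title: "Modelling chloroplast pmf energetics across ATP synthase c-ring sizes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chloroplast pmf energetics across ATP synthase c-ring sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cringpmf)
```

## The question the model addresses

The F0F1-ATP synthase couples proton efflux from the thylakoid lumen to ATP
synthesis through rotation of its membrane-embedded c-ring.  One proton is
carried per c-subunit per rotation and one rotation yields three ATP, so the
H+/ATP ratio is $n = c/3$.  Known c-rings span 8 to 17 subunits;
photosynthetic organisms sit at the large end (chloroplasts: $c_{14}$,
$n = 4.67$).  Large rings are thermodynamically *inefficient* — more protons
are spent per ATP — so why did photosynthesis keep them?

The package implements a kinetic/thermodynamic model of the light reactions
in which the c-ring size is the only varied factor, and quantifies the
downstream consequences: the dark proton-motive-force (pmf) baseline, lumen
pH, photosynthetic control at the cytochrome $b_6f$ complex, qE-type
quenching, and — through the membrane potential $\Delta\psi$ — the rate of
charge recombination in photosystem II and the singlet oxygen ($^1O_2$) it
produces.

## Thermodynamic core

Two relations carry all the closed-form results.  The pmf is the sum of its
electric and osmotic components,

$$\mathrm{pmf} = \Delta\psi + z\,\Delta\mathrm{pH}, \qquad
  z = \frac{2.303\,R\,T}{F} \approx 0.0592\ \mathrm{V\ (25^\circ C)},$$

and at the ATP synthase equilibrium the free energy of ATP synthesis is
balanced by $n$ proton charges,

$$\Delta G_{\mathrm{ATP}} = n\,F\,\mathrm{pmf}_{\mathrm{eq}}
  \quad\Longrightarrow\quad
  \mathrm{pmf}_{\mathrm{eq}} = \frac{\Delta G_{\mathrm{ATP}}}{n F}.$$

With $\Delta G_{\mathrm{ATP}} = 40$ kJ/mol this gives the dark pmf floor:
$\approx 89$ mV for $c_{14}$ but $\approx 155$ mV for $c_8$.  Under the
equal-partition assumption (`fraction_psi = 0.5`) the $c_8$ ring must hold
$\approx 33$ mV more $\Delta\psi$ *and* a lumen at pH 6.5 instead of 7.0 —
acidic enough to engage photosynthetic control and qE in darkness, and a
higher $\Delta\psi$ baseline from which recombination accelerates.

```{r equilibrium}
cmd_equilibrium(experiment_spec(rings = c(8, 11, 12, 14, 17)))
```

`z` is always computed from temperature, never hard-coded to the 0.06 V
display value used in figure legends; between 293 and 303 K it spans
0.0581-0.0601 V (all of which print as 0.06 at two decimals, varying about
±1.7% around the midpoint), which is why printed pH-unit targets like 0.75
and 1.3 are reproduced to their rounding.

## The dynamic model

The ODE system tracks, per mole of PSII (pool ratios
PSII : PSI : $b_6f$ : PQ = 1 : 1 : 1 : 6): the fraction of closed PSII
centers ($Q_A^-$), the plastoquinone pool redox state, oxidized P700, lumen
pH, $\Delta\psi$, the S2/S3 donor-side fraction, PsbS protonation,
zeaxanthin, and running integrals of every flux (linear electron flow,
recombination, $^1O_2$, proton deposition and efflux).

Key constitutive choices:

* **Electron path** — light drives stable charge separation at PSII
  (attenuated by $1 - q_E$), mass-action transfer $Q_A^- \to$ PQ, pH-gated
  PQH$_2$ oxidation at $b_6f$, and PSI turnover into a non-limiting
  acceptor pool.  There is no cyclic electron flow, water-water cycle or
  malate valve, and no $\Delta\psi$ back-pressure on forward electron
  transfer.
* **Protons and charge** — each electron deposits 1 H$^+$ at the
  oxygen-evolving complex and 2 at the $b_6f$ Q-cycle, and moves three
  charges across the membrane (one at each of PSII, $b_6f$, PSI).
  $\Delta\psi$ integrates net electrogenic flux on a capacitor
  (`c_membrane`, 0.05 V per charge per PSII — one saturating flash gives
  the literature-typical ~50 mV); lumen pH integrates net proton flux over
  a buffering capacity `beta_lumen`.
* **Photosynthetic control** — $k_{b6f}(\mathrm{pH}) =
  k_{max} / (1 + 10^{\,n(\mathrm{p}K_a - \mathrm{pH})})$.  The only printed
  constraint is a ten-fold slowing from pH 7.5 to 5.5; for $n = 1$ the
  midpoint solving it exactly is p$K_a$ = 6.5 (closed form; other Hill
  coefficients are solved numerically).
* **ATP synthase** — permanently activated (thiol-reduced) and ohmic:
  proton efflux $= g_{\mathrm{ATPase}}(\mathrm{pmf} -
  \mathrm{pmf}_{\mathrm{eq}})$, negative below equilibrium.  No
  ADP/P$_i$ mass action: $\Delta G_{\mathrm{ATP}}$ is fixed, the stroma is
  an infinite buffer.
* **Recombination and $^1O_2$** — the recombination-competent pool is
  $[\mathrm{S_2Q_A^-} + \mathrm{S_3Q_A^-}] =$ `qa_reduced *
  s23_donor_frac`, and its decay rate rises tenfold per
  $0.06/f$ volts:
  $v = [\mathrm{S_{2,3}Q_A^-}]\,k_r\,10^{\,f\Delta\psi/0.06}$, with the
  charge-separated-state stabilization energy folded into $k_r$ (the
  printed form of the law renders its sign ambiguously; the accompanying
  text is unambiguous that recombination *accelerates* with $\Delta\psi$,
  which fixes the adopted sign).  $^1O_2$ production is a fixed yield
  `phi_1o2` per recombination.  S-state bookkeeping is a two-pool
  approximation: turnover drives the donor side toward an S2+S3 occupancy
  of 0.5 (two of four S-states), recombination and a slow dark decay reset
  it.
* **qE** — the product of fast PsbS protonation (Hill midpoint 6.2) and
  slow VDE-driven zeaxanthin formation (midpoint 6.0, Hill 2, ~1 min
  forward / ~4 min reverse), acting multiplicatively on PSII excitation.
  Both channels contribute to the reported dark "NPQ" observable.
* **Counter-ions** — a generic monovalent conductance
  $g_{\mathrm{ion}}(\Delta\psi - \psi_{\mathrm{ion,eq}})$ converts stored
  $\Delta\psi$ into $\Delta$pH.  $\psi_{\mathrm{ion,eq}}$ defaults to the
  dark-equilibrium $\Delta\psi$: this makes the partitioned dark state an
  exact fixed point of the full system (every derivative vanishes), which
  is the contract `dark_equilibrate()` verifies.  Biologically it says the
  counter-ion distribution has equilibrated with the dark membrane
  potential.

## Parameters: constraints versus calibrations

The source material prints *no* kinetic rate constants (they live in an
external repository this package deliberately does not consult).  The
package therefore distinguishes:

* **Imposed constraints** (reproduced exactly): $\Delta G_{\mathrm{ATP}}$ =
  40 kJ/mol, stromal pH 7.8, $n = c/3$, the ten-fold $b_6f$ span,
  3 H$^+$/e$^-$ (hence 2.57 ATP/2 NADPH at $c_{14}$ and 3.0 at $c_{12}$).
* **Calibrations** (documented defaults, overridable by key): antenna cross
  section 0.5 s$^{-1}$ per µmol photons m$^{-2}$s$^{-1}$; $k_{b6f,max}$ =
  300 s$^{-1}$; `c_membrane` = 0.05 V/charge (flash calibration);
  `beta_lumen` = 500 mol H$^+$/pH/PSII, set once so that 10 min of
  1000 µmol photons m$^{-2}$s$^{-1}$ with $c_{14}$ brings the lumen to
  pH ~6.1 (the stated high-light regime); $g_{\mathrm{ATPase}}$ = 4000
  mol H$^+$ s$^{-1}$V$^{-1}$ (maximal observed activity); $k_r$ = 0.3
  s$^{-1}$, $f$ = 0.6, $\phi_{^1O_2}$ = 0.3; $g_{\mathrm{ion}}$ = 5
  (a ~4 s $\Delta\psi\to\Delta$pH conversion time).

Because the trajectories depend on calibrated magnitudes, *no numerical
trajectory value is treated as reproducible*; what the model is asserted to
reproduce are the dark closed-form numbers and the orderings and
conservation laws in the test-suite (see below).

## Illumination protocols

Three generator kinds emulate the fluctuating-light experiment: static
light, a sinusoid starting at its minimum (simulations begin in darkness),
and a square wave starting in its low phase.  All expose closed-form total
photon dose, and the default 1-h trio (static 100; sinusoid 100 ± 100,
period 600 s; square 0/200, 50% duty, period 600 s) delivers identical dose
by construction — the equal-illumination contract.  The exact fluctuation
period and depth are not printed in the source; they are free parameters
with these defaults, and the package's claims about them are *orderings*
across regimes, not trace values.  Square-wave edges are true
discontinuities: the integrator is restarted at every breakpoint rather
than trusted to step over them.

What the generator does *not* emulate: sun-fleck statistics, cloud flicker,
spectral changes, or any light regime whose intensity is unbounded or
negative.  A green ordering test therefore establishes that the *mechanism*
(convexity of recombination in $\Delta\psi$ plus correlated closed-center
states) produces the fluctuation penalty, not that any particular field
light regime yields a particular $^1O_2$ dose.

## Numerical design

The system is stiff (ms-scale $\Delta\psi$ relaxation against ~minute
zeaxanthin kinetics), so the integrator is an L-stable Rosenbrock(2,3)
pair with step-doubling error control, numerical Jacobians, and dense
sampling forced onto the reporting grid (default 0.5 s) plus all protocol
breakpoints.  It is implemented in C++; a line-for-line R reference of the
right-hand side (`derivatives()`) is kept in exact agreement by a property
test, so every flux formula is independently readable and checkable.
Defaults: relative tolerance $10^{-8}$, per-state absolute tolerances
($10^{-11}$ V for $\Delta\psi$).  Tolerance-halving changes cumulative LEF
by $\ll 0.1\%$.

Degenerate-input policy: pool fractions are clamped to $[0,1]$ only within
$10^{-9}$ (larger excursions abort the run); non-finite fluxes abort naming
the offending term; near-singular Rosenbrock matrices are treated as failed
steps, never "solved approximately".  One numerical guard deserves mention:
the recombination exponent is capped at $10^{8}$-fold acceleration
(reached only near $\Delta\psi \approx 0.8$ V at default $f$).  No
physiological scenario comes near it; it exists because with the ATP
synthase disabled *and* weak counter-ion conductance the model — which has
no dielectric-breakdown or back-pressure physics — will drive $\Delta\psi$
to volt-scale transients, and $10^{19}$-scale Jacobian entries would
otherwise poison the linear algebra.  In that pathological regime the model
still shows the intended feedback: the lumen acidifies until photosynthetic
control throttles $b_6f$ and electron flow stalls.

## Design decisions that were genuinely open

* **Partition fraction.** No canonical $\Delta\psi$ fraction is given for
  the dark state; it is an explicit argument everywhere
  (`fraction_psi`, default 0.5, matching the equal-partition wording of
  the closed-form results).
* **Sign of the recombination law** — see above; rate increases with
  $\Delta\psi$, $\Delta E_{stab}$ folded into $k_r$ (kept as a field,
  default 0, so $k_r$ *is* the $\Delta\psi = 0$ rate).
* **S-state dynamics** are not specified; the two-pool approximation above
  preserves the structure of the recombination law with one target
  occupancy parameter instead of a four-state ladder.
* **Dark redox poise** of the PQ pool is a free parameter (default 0.1):
  in darkness the model has no flux through the pool, so any poise is a
  fixed point; 10% reduction is a typical dark value.
* **z at display precision.** The "0.06 V per pH unit" statement is treated
  as display rounding, valid across 293-303 K at two decimals; the claim
  that it holds "within 2%" is interpreted as the *spread* of $z$ over that
  range (±1.7% about the midpoint), since $z(293\,\mathrm{K}) = 0.0581$ V
  is 3.1% below 0.06 pointwise.

## What the tests establish — and what they do not

The suite verifies: every printed dark-equilibrium number at its printed
rounding; the ten-fold $b_6f$ calibration; exact equal-dose across protocol
kinds; the dark state as a fixed point (an all-dark hour is constant to
$10^{-6}$ V); pmf composition, charge conservation and electron
conservation along every trajectory at integrator tolerance; agreement of
the integrator with two closed-form linear subsystems (capacitor charging
by the two photosystems; counter-ion relaxation); and the four qualitative
claims — smaller rings give lower lumen pH and more qE pointwise, more
$^1O_2$ (monotone in $c$), less LEF under fluctuating light, and
progressively more $^1O_2$ from static to sinusoidal to square-wave light
at equal dose.

They do not establish absolute $^1O_2$ doses, absolute LEF, or the
time-course of any experimental trace: those depend on the calibrated rate
constants above.  Changing calibrations rescales the curves; the orderings
are the model's robust content.

## Known limitations

* No $\Delta\psi$ dependence of forward electron transfer, no acceptor-side
  limitation at PSI, no state transitions, no cyanobacterial respiratory
  chain, no Na$^+$-motive-force variant.
* $\Delta G_{\mathrm{ATP}}$ fixed: the ATP synthase can formally run in the
  hydrolysis direction below equilibrium, but no adenylate pool responds.
* The two-pool S-state model under-resolves flash experiments; it is meant
  for continuous-light regimes.
* The counter-ion is generic and single-valued; real partitioning involves
  K$^+$, Cl$^-$ and Mg$^{2+}$ with distinct reversal potentials.
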