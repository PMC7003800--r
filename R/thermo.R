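# Closed-form thermodynamics of the proton motive force and the ATP synthase
# equilibrium.  Everything here is algebra on Eq. (pmf = dpsi + z * dpH) and
# (dG_ATP = n * F * pmf at equilibrium); no kinetics.

#' Physical and thermodynamic constants of the simulation
#'
#' Bundles the free energy of ATP synthesis, the (fixed, infinitely buffered)
#' stromal pH, temperature and the physical constants, and derives
#' `z = 2.303 R T / F`, the volt-equivalent of one pH unit (~0.0592 V at
#' 298.15 K; figure legends in the field round this to 0.06 V).
#'
#' @param delta_g_atp Free energy of ATP synthesis, J/mol (default 40000,
#'   i.e. 40 kJ/mol, a standard daytime chloroplast value).
#' @param stromal_ph Stromal pH, held constant (default 7.8).
#' @param temperature Temperature in kelvin (default 298.15).
#' @return An object of class `thermo_params`: a list with the arguments plus
#'   `faraday` (C/mol), `gas_constant` (J/mol/K) and `z` (V per pH unit).
#' @examples
#' th <- thermo_params()
#' th$z # ~0.0592
#' @export
thermo_params <- function(delta_g_atp = 40000, stromal_ph = 7.8,
                          temperature = 298.15) {
  if (!is.numeric(delta_g_atp) || length(delta_g_atp) != 1 ||
    !is.finite(delta_g_atp) || delta_g_atp < 0) {
    stop_invalid("delta_g_atp must be a single non-negative finite number")
  }
  if (!is.numeric(stromal_ph) || length(stromal_ph) != 1 || !is.finite(stromal_ph)) {
    stop_invalid("stromal_ph must be a single finite number")
  }
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0) {
    stop_invalid("temperature must be a single positive number (kelvin)")
  }
  faraday <- 96485
  gas_constant <- 8.314
  z <- log(10) * gas_constant * temperature / faraday
  structure(
    list(
      delta_g_atp = delta_g_atp, stromal_ph = stromal_ph,
      temperature = temperature, faraday = faraday,
      gas_constant = gas_constant, z = z
    ),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(
    "thermo_params: dG_ATP = %.0f J/mol, stromal pH = %.2f, T = %.2f K, z = %.4f V/pH\n",
    x$delta_g_atp, x$stromal_ph, x$temperature, x$z
  ))
  invisible(x)
}

#' ATP synthase c-ring configuration
#'
#' The rotor ring of the F0F1-ATP synthase carries one proton per c-subunit
#' per full rotation, and one rotation releases three ATP from the F1 head,
#' so the H+/ATP ratio is `c_subunits / 3`.  The ring size is genetically
#' fixed: it is constant for the lifetime of a simulation and is the single
#' factor varied between simulations.
#'
#' @param c_subunits Integer number of c-subunits (known organisms span 8-17).
#' @return Object of class `cring_config` with fields `c_subunits` and
#'   `h_per_atp`.
#' @examples
#' cring_config(14)$h_per_atp # 4.67, the chloroplast value
#' @export
cring_config <- function(c_subunits) {
  structure(
    list(c_subunits = c_subunits, h_per_atp = h_plus_per_atp(c_subunits)),
    class = "cring_config"
  )
}

#' @export
print.cring_config <- function(x, ...) {
  cat(sprintf(
    "cring_config: c%d ring, H+/ATP = %.3f\n",
    x$c_subunits, x$h_per_atp
  ))
  invisible(x)
}

#' Protons required per ATP for a given c-ring size
#'
#' @param c_subunits Positive integer count of c-subunits.
#' @return `c_subunits / 3` (three catalytic sites per 360 degree rotation).
#' @examples
#' h_plus_per_atp(14) # 4.67
#' @export
h_plus_per_atp <- function(c_subunits) {
  if (!is.numeric(c_subunits) || length(c_subunits) != 1 ||
    !is.finite(c_subunits) || c_subunits < 1 ||
    c_subunits != round(c_subunits)) {
    stop_invalid("c_subunits must be a single positive integer")
  }
  c_subunits / 3
}

#' pmf at which the ATP synthase is at equilibrium
#'
#' The per-proton electrochemical potential at equilibrium satisfies
#' `dG_ATP = n * F * pmf` with `n = H+/ATP`, so the dark pmf floor is
#' `dG_ATP / (n F)`.  Smaller rings (larger steps per proton) need a larger
#' pmf: ~155 mV for c8 versus ~89 mV for the chloroplast c14 at 40 kJ/mol.
#'
#' @param thermo A [thermo_params()] object.
#' @param ring A [cring_config()] object.
#' @return Equilibrium pmf in volts.
#' @examples
#' equilibrium_pmf(thermo_params(), cring_config(14)) # ~0.0888 V
#' @export
equilibrium_pmf <- function(thermo, ring) {
  stopifnot(inherits(thermo, "thermo_params"), inherits(ring, "cring_config"))
  if (ring$h_per_atp <= 0) stop_invalid("h_per_atp must be positive")
  thermo$delta_g_atp / (ring$h_per_atp * thermo$faraday)
}

#' Compose or split the pmf into its electric and osmotic components
#'
#' `partition_pmf()` splits a total pmf into delta-psi (a fraction
#' `fraction_psi` of the total, in volts) and delta-pH (the remainder,
#' converted to pH units through `z`).  `pmf_total()` is the inverse
#' composition, `dpsi + z * dpH`.
#'
#' @param pmf_total Total pmf in volts (finite; may be negative).
#' @param fraction_psi Fraction of pmf stored as delta-psi, in `[0, 1]`.
#' @param thermo A [thermo_params()] object (supplies `z`).
#' @return Object of class `pmf_state`: list with `delta_psi` (V), `delta_ph`
#'   (pH units, stroma minus lumen) and `pmf_total` (V).
#' @examples
#' partition_pmf(0.0888, 0.5, thermo_params())$delta_ph # ~0.75 pH units
#' @export
partition_pmf <- function(pmf_total, fraction_psi, thermo) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (!is.numeric(pmf_total) || length(pmf_total) != 1 || !is.finite(pmf_total)) {
    stop_invalid("pmf_total must be a single finite number (volts)")
  }
  if (!is.numeric(fraction_psi) || length(fraction_psi) != 1 ||
    is.na(fraction_psi) || fraction_psi < 0 || fraction_psi > 1) {
    stop_invalid("fraction_psi must lie in [0, 1]")
  }
  delta_psi <- fraction_psi * pmf_total
  delta_ph <- (1 - fraction_psi) * pmf_total / thermo$z
  structure(
    list(delta_psi = delta_psi, delta_ph = delta_ph, pmf_total = pmf_total),
    class = "pmf_state"
  )
}

#' @rdname partition_pmf
#' @param delta_psi Electric field component, V.
#' @param delta_ph Proton gradient, pH units (stroma minus lumen).
#' @export
pmf_total <- function(delta_psi, delta_ph, thermo) {
  stopifnot(inherits(thermo, "thermo_params"))
  delta_psi + thermo$z * delta_ph
}

#' @export
print.pmf_state <- function(x, ...) {
  cat(sprintf(
    "pmf_state: pmf = %.1f mV (dpsi = %.1f mV, dpH = %.2f units)\n",
    1000 * x$pmf_total, 1000 * x$delta_psi, x$delta_ph
  ))
  invisible(x)
}

#' Per-proton electrochemical potential, J/mol
#'
#' @param pmf pmf in volts (or a `pmf_state`).
#' @param thermo A [thermo_params()] object.
#' @return `F * pmf` in J per mol H+.
#' @export
delta_mu_h <- function(pmf, thermo) {
  stopifnot(inherits(thermo, "thermo_params"))
  if (inherits(pmf, "pmf_state")) pmf <- pmf$pmf_total
  thermo$faraday * pmf
}

#' Lumen pH implied by a delta-pH against a fixed stromal pH
#'
#' @param stromal_ph Stromal pH.
#' @param delta_ph delta-pH in pH units (stroma minus lumen).
#' @return `stromal_ph - delta_ph`.
#' @examples
#' lumen_ph(7.8, 0.75) # ~7.05
#' @export
lumen_ph <- function(stromal_ph, delta_ph) {
  stromal_ph - delta_ph
}

#' ATP produced per 2 NADPH by linear electron flow
#'
#' Linear electron flow moves 4 electrons per 2 NADPH and deposits
#' `h_per_electron` protons in the lumen per electron (default 3: one from
#' water oxidation plus two from the b6f Q-cycle), so the ATP output per
#' 2 NADPH is `4 * h_per_electron / (H+/ATP)`.  The chloroplast c14 ring
#' gives 2.57, below the 3.0 demanded by the Calvin-Benson-Bassham cycle;
#' a c12 ring would give exactly 3.0.
#'
#' @param ring A [cring_config()] object.
#' @param h_per_electron Protons deposited in the lumen per electron
#'   (default 3, Q-cycle engaged).
#' @return ATP per 2 NADPH (dimensionless).
#' @examples
#' atp_per_two_nadph(cring_config(14)) # 2.57
#' @export
atp_per_two_nadph <- function(ring, h_per_electron = 3) {
  stopifnot(inherits(ring, "cring_config"))
  if (!is.numeric(h_per_electron) || length(h_per_electron) != 1 ||
    !is.finite(h_per_electron) || h_per_electron < 0) {
    stop_invalid("h_per_electron must be a single non-negative number")
  }
  (4 * h_per_electron) / ring$h_per_atp
}
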