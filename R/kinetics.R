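# Kinetic building blocks of the light-reaction ODE system and the pure-R
# reference right-hand side.  The C++ right-hand side used by the integrator
# (src/model.cpp) mirrors these formulas term for term; a property test keeps
# the two in exact agreement.

# state vector layout (shared with src/model.cpp)
.state_names <- c(
  "qa_reduced", "pq_reduced", "p700_ox", "lumen_ph", "delta_psi",
  "counter_ion_moved", "s23_donor_frac", "psbs_protonated", "zeaxanthin",
  "cumulative_lef", "cumulative_singlet_o2", "cumulative_psii",
  "cumulative_recombination", "cumulative_b6f", "cumulative_atp_h"
)

#' Kinetic parameters of the light-reaction model
#'
#' All pool sizes are expressed per mole of PSII, with PSII : PSI : b6f :
#' PQ = 1 : 1 : 1 : 6 (the PQ pool holds `n_pq_e = 12` electrons).  Rate
#' constants below are calibrations, not measured values: the quantities the
#' literature pins down (the 10-fold b6f slowing between lumen pH 7.5 and
#' 5.5; a ~50 mV membrane-potential jump per single-turnover flash; lumen
#' pH reaching ~6 after 10 min at 1000 umol photons m^-2 s^-1 with a c14
#' ring) are imposed as constraints and everything else is chosen at
#' physiologically typical magnitudes.  Every parameter can be overridden
#' by name; unknown names are rejected.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `kinetic_params` (a validated named list).
#'
#' @section Parameters:
#' \describe{
#'   \item{antenna_rate_per_intensity}{Excitation rate delivered to each
#'     photosystem per unit light, s^-1 per umol photons m^-2 s^-1
#'     (default 0.5: 1000 umol drives ~500 turnovers/s at open centers).}
#'   \item{k_qa_pq}{QA- to PQ pool electron transfer rate constant, s^-1
#'     (default 300).}
#'   \item{n_pq_e}{Electron capacity of the PQ pool (default 12).}
#'   \item{pq_dark}{Dark redox poise of the PQ pool, fraction reduced
#'     (default 0.1).}
#'   \item{k_b6f_max}{Maximal PQH2 oxidation rate constant at the b6f
#'     complex, s^-1 (default 300).}
#'   \item{n_hill_b6f}{Hill coefficient of photosynthetic control (default 1).}
#'   \item{pka_reg}{pH midpoint of photosynthetic control.  Default `NA`
#'     means: solve for the value that makes rate(pH 7.5)/rate(pH 5.5)
#'     exactly 10 (6.5 for `n_hill_b6f = 1`).}
#'   \item{k_r}{Intrinsic S2/S3 QA- recombination rate at delta-psi = 0,
#'     s^-1 (default 0.3); the charge-separated-state stabilization energy
#'     is folded into this number.}
#'   \item{delta_e_stab}{Residual stabilization free energy, eV (default 0;
#'     nonzero values rescale the recombination rate by
#'     `10^(-delta_e_stab/0.06)`).}
#'   \item{f_dist}{Dielectric-weighted fraction of delta-psi sensed by the
#'     recombining charge pair, in `[0,1]` (default 0.6).}
#'   \item{phi_1o2}{Singlet-oxygen yield per recombination event (default 0.3).}
#'   \item{g_atpase}{ATP synthase proton conductance, mol H+ s^-1 V^-1 per
#'     mol PSII (default 4000; held constant, i.e. fully thiol-activated).}
#'   \item{c_membrane}{Capacitance coefficient, V per mol charge per mol
#'     PSII (default 0.05: one charge/PSII across the membrane = 50 mV).}
#'   \item{beta_lumen}{Lumen buffering capacity, mol H+ per pH unit per mol
#'     PSII (default 500, calibrated so 10 min at 1000 umol photons m^-2 s^-1 with a c14 ring brings the lumen to pH ~6).}
#'   \item{g_ion}{Counter-ion channel conductance, mol charge s^-1 V^-1
#'     (default 5).}
#'   \item{psi_ion_eq}{Counter-ion Nernst potential, V.  Default `NA`:
#'     resolved at run time to the dark-equilibrium delta-psi so darkness is
#'     a true fixed point.}
#'   \item{pka_psbs, n_psbs, k_psbs}{PsbS protonation midpoint (6.2), Hill
#'     coefficient (1) and relaxation rate (0.2 s^-1).}
#'   \item{pka_vde, n_vde}{Violaxanthin de-epoxidase activation midpoint
#'     (6.0) and Hill coefficient (2).}
#'   \item{k_vde, k_ep}{Zeaxanthin formation (0.014 s^-1) and epoxidation
#'     reversal (0.004 s^-1) rate constants.}
#'   \item{qe_max}{Maximal fraction of PSII excitation quenched by qE
#'     (default 1).}
#'   \item{s23_target}{Steady illuminated S2+S3 donor fraction (default 0.5,
#'     two of the four S-states).}
#'   \item{k_s_decay}{Dark decay rate of S2/S3 to S1, s^-1 (default 0.03).}
#'   \item{recomb_exp_cap}{Numerical guard: the recombination exponent
#'     `(f_dist * delta_psi - delta_e_stab) / 0.06` is capped at this value
#'     (default 8, i.e. at most a 1e8-fold acceleration, reached only at
#'     delta-psi values far beyond the physiological range).  Keeps the
#'     Jacobian finite in pathological no-efflux scenarios.}
#' }
#' @examples
#' kp <- kinetic_params(g_ion = 0)
#' kp$pka_reg # 6.5, solved from the ten-fold constraint
#' @export
kinetic_params <- function(...) {
  defaults <- list(
    antenna_rate_per_intensity = 0.5,
    k_qa_pq = 300,
    n_pq_e = 12,
    pq_dark = 0.1,
    k_b6f_max = 300,
    n_hill_b6f = 1,
    pka_reg = NA_real_,
    k_r = 0.3,
    delta_e_stab = 0,
    f_dist = 0.6,
    phi_1o2 = 0.3,
    g_atpase = 4000,
    c_membrane = 0.05,
    beta_lumen = 500,
    g_ion = 5,
    psi_ion_eq = NA_real_,
    pka_psbs = 6.2,
    n_psbs = 1,
    k_psbs = 0.2,
    pka_vde = 6.0,
    n_vde = 2,
    k_vde = 0.014,
    k_ep = 0.004,
    qe_max = 1,
    s23_target = 0.5,
    k_s_decay = 0.03,
    recomb_exp_cap = 8
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop_config("kinetic_params overrides must all be named")
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop_config(paste0(
        "unknown kinetic parameter(s): ", paste(unknown, collapse = ", ")
      ))
    }
    defaults[names(overrides)] <- overrides
  }
  p <- defaults
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1) {
      stop_invalid(paste0("kinetic parameter ", nm, " must be a single number"))
    }
  }
  nonneg <- c(
    "antenna_rate_per_intensity", "k_qa_pq", "n_pq_e", "k_b6f_max",
    "n_hill_b6f", "k_r", "g_atpase", "c_membrane", "beta_lumen", "g_ion",
    "k_psbs", "k_vde", "k_ep", "k_s_decay", "recomb_exp_cap"
  )
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      stop_invalid(paste0(nm, " must be finite and >= 0"))
    }
  }
  for (nm in c("f_dist", "phi_1o2", "pq_dark", "qe_max", "s23_target")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop_invalid(paste0(nm, " must lie in [0, 1]"))
    }
  }
  for (nm in c("pka_psbs", "pka_vde")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 4 || p[[nm]] > 8) {
      stop_invalid(paste0(nm, " must lie in [4, 8]"))
    }
  }
  if (is.na(p$pka_reg)) {
    p$pka_reg <- b6f_pka_for_ratio(p$n_hill_b6f)
  }
  if (!is.finite(p$pka_reg) || p$pka_reg < 4 || p$pka_reg > 8) {
    stop_invalid("pka_reg must lie in [4, 8]")
  }
  if (p$beta_lumen <= 0) stop_invalid("beta_lumen must be > 0")
  structure(p, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("kinetic_params:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Solve the photosynthetic-control pKa from the ten-fold constraint
#'
#' Finds the midpoint `pka` of the sigmoid
#' `k(pH) = k_max / (1 + 10^(n (pka - pH)))` such that
#' `k(ph_hi) / k(ph_lo) = ratio`.  For `n = 1` and the canonical ten-fold
#' slowing between pH 7.5 and 5.5 the solution is exactly 6.5.
#'
#' @param n_hill Hill coefficient of the sigmoid.
#' @param ratio Target rate ratio (default 10).
#' @param ph_hi,ph_lo The two reference pH values (defaults 7.5 and 5.5).
#' @return The pKa in pH units.
#' @export
b6f_pka_for_ratio <- function(n_hill = 1, ratio = 10, ph_hi = 7.5, ph_lo = 5.5) {
  f <- function(pka) {
    log((1 + 10^(n_hill * (pka - ph_lo))) / (1 + 10^(n_hill * (pka - ph_hi)))) -
      log(ratio)
  }
  uniroot(f, c(4, 8), tol = 1e-12)$root
}

hill_protonation <- function(ph, pka, n) {
  1 / (1 + 10^(n * (ph - pka)))
}

#' pH-dependent PQH2 oxidation rate constant at the b6f complex
#'
#' Photosynthetic control: the rate constant falls sigmoidally as the lumen
#' acidifies, `k = k_b6f_max / (1 + 10^(n (pka_reg - pH)))`, saturating at
#' `k_b6f_max` for alkaline lumen and calibrated to a ten-fold slowing
#' between pH 7.5 and 5.5.
#'
#' @param lumen_ph Lumen pH (may be a vector).
#' @param params A [kinetic_params()] object.
#' @return Rate constant(s), s^-1.
#' @export
b6f_rate_constant <- function(lumen_ph, params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k_b6f_max /
    (1 + 10^(params$n_hill_b6f * (params$pka_reg - lumen_ph)))
}

#' Construct a model state vector
#'
#' @param ... Named state components (see Details); unspecified components
#'   default to zero except `lumen_ph` (7.8), `pq_reduced` (0.1).
#' @return Named numeric vector of class `model_state`.
#' @details Components: `qa_reduced`, `pq_reduced`, `p700_ox` (redox pool
#'   fractions), `lumen_ph`, `delta_psi` (V), `counter_ion_moved` (mol
#'   charge per mol PSII), `s23_donor_frac` (fraction of PSII donor sides in
#'   S2/S3), `psbs_protonated`, `zeaxanthin`, plus running integrals
#'   `cumulative_lef`, `cumulative_singlet_o2`, `cumulative_psii`,
#'   `cumulative_recombination`, `cumulative_b6f`, `cumulative_atp_h`.
#'   The recombination-competent pool of Eq.-3 type kinetics is the product
#'   `qa_reduced * s23_donor_frac`, see [s23_qa_frac()].
#' @export
model_state <- function(...) {
  x <- stats::setNames(numeric(length(.state_names)), .state_names)
  x["lumen_ph"] <- 7.8
  x["pq_reduced"] <- 0.1
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), .state_names)
    if (length(unknown) || is.null(names(overrides))) {
      stop_invalid(paste0(
        "unknown state component(s): ", paste(unknown, collapse = ", ")
      ))
    }
    x[names(overrides)] <- unlist(overrides)
  }
  validate_model_state(x)
  structure(x, class = "model_state")
}

validate_model_state <- function(x, tol = 1e-9) {
  fr <- c(
    "qa_reduced", "pq_reduced", "p700_ox", "s23_donor_frac",
    "psbs_protonated", "zeaxanthin"
  )
  bad <- fr[x[fr] < -tol | x[fr] > 1 + tol]
  if (length(bad)) {
    stop_invalid(paste0(
      "state fraction(s) outside [0, 1]: ", paste(bad, collapse = ", ")
    ))
  }
  if (!is.finite(x["lumen_ph"])) stop_invalid("lumen_ph must be finite")
  invisible(x)
}

#' Recombination-competent PSII fraction
#'
#' @param state A [model_state()].
#' @return `qa_reduced * s23_donor_frac`, the fraction of PSII with both a
#'   reduced QA and an S2/S3 donor side.
#' @export
s23_qa_frac <- function(state) {
  unname(state["qa_reduced"] * state["s23_donor_frac"])
}

#' PSII charge-recombination rate and its delta-psi dependence
#'
#' The recombination velocity of the S2/S3 QA- states is
#' `s23_qa_frac * k_r * 10^(f_dist * delta_psi / 0.06)` (times
#' `10^(-delta_e_stab / 0.06)` when a residual stabilization energy is
#' supplied): the membrane potential lowers the free-energy barrier of the
#' back-reaction, so the rate rises exponentially with delta-psi, tenfold
#' per `0.06 / f_dist` volts.  At `delta_psi = 0` the rate is
#' `s23_qa_frac * k_r` by definition of `k_r`.
#'
#' @param state A [model_state()].
#' @param params A [kinetic_params()].
#' @return Recombination rate, events s^-1 per mol PSII.
#' @seealso [singlet_o2_rate()]
#' @export
recombination_rate <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  s23qa <- state[["qa_reduced"]] * state[["s23_donor_frac"]]
  ex <- (params$f_dist * state[["delta_psi"]] - params$delta_e_stab) / 0.06
  s23qa * params$k_r * 10^min(ex, params$recomb_exp_cap)
}

#' Singlet-oxygen production rate
#'
#' @inheritParams recombination_rate
#' @return `phi_1o2 * recombination_rate(state, params)`, events s^-1.
#' @export
singlet_o2_rate <- function(state, params) {
  params$phi_1o2 * recombination_rate(state, params)
}

#' Ohmic ATP synthase proton efflux
#'
#' Above its activation threshold the thylakoid ATP synthase is essentially
#' ohmic in pmf; the enzyme is held permanently activated (thiol-reduced) at
#' constant conductance, so the proton efflux is
#' `g_atpase * (pmf - equilibrium_pmf)`.  Negative values (pmf below the
#' ATP equilibrium) correspond to the hydrolysis direction.
#'
#' @param pmf_total pmf in volts.
#' @param ring A [cring_config()].
#' @param thermo A [thermo_params()].
#' @param params A [kinetic_params()].
#' @return Proton flux lumen to stroma, mol H+ s^-1 per mol PSII.
#' @export
atp_synthase_flux <- function(pmf_total, ring, thermo, params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$g_atpase * (pmf_total - equilibrium_pmf(thermo, ring))
}

#' qE quenching extent
#'
#' The instantaneous quenching extent is the product of the PsbS
#' protonation state and the zeaxanthin fraction carried in `state`.  When
#' `state` is `NULL` the steady-state extent at the given lumen pH is
#' returned instead: PsbS protonation is a Hill function of pH around
#' `pka_psbs`, and zeaxanthin sits at the VDE/epoxidase balance
#' `k_vde * act / (k_vde * act + k_ep)` with the de-epoxidase activity
#' itself a Hill function of pH around `pka_vde`.  Around lumen pH 7 both
#' factors are near zero; by pH 6.5 the product is appreciable.
#'
#' @param lumen_ph Lumen pH.
#' @param state A [model_state()] or `NULL` for the steady-state value.
#' @param params A [kinetic_params()].
#' @return Quenching extent in `[0, 1]` (before scaling by `qe_max`).
#' @export
qe_extent <- function(lumen_ph, state = NULL, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(state)) {
    psbs <- hill_protonation(lumen_ph, params$pka_psbs, params$n_psbs)
    act <- hill_protonation(lumen_ph, params$pka_vde, params$n_vde)
    zx <- params$k_vde * act / (params$k_vde * act + params$k_ep)
    psbs * zx
  } else {
    unname(state["psbs_protonated"] * state["zeaxanthin"])
  }
}

#' Counter-ion channel flux
#'
#' A generic monovalent counter-ion conductance that relaxes delta-psi
#' toward the ion's Nernst potential `psi_ion_eq`, converting stored pmf
#' from the electric into the osmotic component:
#' `flux = g_ion * (delta_psi - psi_ion_eq)` (positive = charge leaving the
#' lumen).  With `g_ion = 0` the pmf stays in delta-psi; large `g_ion`
#' clamps delta-psi at `psi_ion_eq`.
#'
#' @param state A [model_state()].
#' @param params A [kinetic_params()]; `psi_ion_eq = NA` is treated as 0
#'   here (it is resolved to the dark delta-psi inside [simulate_run()]).
#' @return Charge flux, mol s^-1 per mol PSII.
#' @export
counter_ion_flux <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  eq <- if (is.na(params$psi_ion_eq)) 0 else params$psi_ion_eq
  params$g_ion * (state[["delta_psi"]] - eq)
}

#' Time derivative of the model state (reference implementation)
#'
#' Assembles every flux of the light-reaction network and returns
#' d(state)/dt.  Electron path: light-driven stable charge separation at
#' PSII (attenuated by `1 - qe_max * qe`), QA- to PQ transfer, pH-controlled
#' PQH2 oxidation at b6f, and PSI turnover into a non-limiting acceptor
#' pool.  Protons: 1 per electron into the lumen at the oxygen-evolving
#' complex, 2 per electron at b6f, efflux through the ATP synthase.
#' Delta-psi integrates the net electrogenic charge flux (one charge per
#' electron at each of PSII, b6f and PSI, minus recombination, ATP synthase
#' efflux and counter-ion flux) on a capacitor of coefficient `c_membrane`.
#'
#' This R version is the readable reference; [simulate_run()] uses the C++
#' twin in `src/model.cpp` (kept in exact agreement by the test-suite).
#'
#' @param t Time, s.
#' @param state A [model_state()] (or named numeric vector in state order).
#' @param ring A [cring_config()].
#' @param thermo A [thermo_params()].
#' @param params A [kinetic_params()].
#' @param light A `light_protocol`.
#' @return Named numeric vector d(state)/dt with attribute `"fluxes"`, a
#'   named vector of the individual fluxes.
#' @export
derivatives <- function(t, state, ring, thermo, params, light) {
  stopifnot(
    inherits(ring, "cring_config"), inherits(thermo, "thermo_params"),
    inherits(params, "kinetic_params"), inherits(light, "light_protocol")
  )
  s <- as.numeric(state)
  names(s) <- .state_names

  intensity <- light_intensity(light, t)
  qe <- s["psbs_protonated"] * s["zeaxanthin"]
  v_psii <- params$antenna_rate_per_intensity * intensity *
    (1 - params$qe_max * qe) * (1 - s["qa_reduced"])
  v_qa_pq <- params$k_qa_pq * s["qa_reduced"] * (1 - s["pq_reduced"])
  v_b6f <- b6f_rate_constant(s["lumen_ph"], params) *
    s["pq_reduced"] * s["p700_ox"]
  v_psi <- params$antenna_rate_per_intensity * intensity * (1 - s["p700_ox"])
  rec_ex <- (params$f_dist * s["delta_psi"] - params$delta_e_stab) / 0.06
  v_rec <- s["qa_reduced"] * s["s23_donor_frac"] * params$k_r *
    10^min(rec_ex, params$recomb_exp_cap)
  pmf <- s["delta_psi"] + thermo$z * (thermo$stromal_ph - s["lumen_ph"])
  v_atp_h <- params$g_atpase * (pmf - equilibrium_pmf(thermo, ring))
  ion_eq <- if (is.na(params$psi_ion_eq)) 0 else params$psi_ion_eq
  v_ion <- params$g_ion * (s["delta_psi"] - ion_eq)

  fluxes <- c(
    v_psii = v_psii, v_qa_pq = v_qa_pq, v_b6f = v_b6f, v_psi = v_psi,
    v_rec = v_rec, v_atp_h = v_atp_h, v_ion = v_ion
  )
  names(fluxes) <- c(
    "v_psii", "v_qa_pq", "v_b6f", "v_psi", "v_rec", "v_atp_h", "v_ion"
  )
  bad <- names(fluxes)[!is.finite(fluxes)]
  if (length(bad)) {
    stop_integration(paste0(
      "non-finite flux term(s) at t = ", t, ": ", paste(bad, collapse = ", ")
    ), last_time = t, last_state = s)
  }

  d <- stats::setNames(numeric(length(.state_names)), .state_names)
  d["qa_reduced"] <- v_psii - v_qa_pq - v_rec
  d["pq_reduced"] <- (v_qa_pq - v_b6f) / params$n_pq_e
  d["p700_ox"] <- v_psi - v_b6f
  d["lumen_ph"] <- -(v_psii + 2 * v_b6f - v_atp_h) / params$beta_lumen
  d["delta_psi"] <- params$c_membrane *
    (v_psii + v_b6f + v_psi - v_rec - v_atp_h - v_ion)
  d["counter_ion_moved"] <- v_ion
  d["s23_donor_frac"] <- v_psii * (params$s23_target - s["s23_donor_frac"]) -
    params$k_s_decay * s["s23_donor_frac"] - v_rec
  psbs_target <- hill_protonation(s["lumen_ph"], params$pka_psbs, params$n_psbs)
  d["psbs_protonated"] <- params$k_psbs * (psbs_target - s["psbs_protonated"])
  vde_act <- hill_protonation(s["lumen_ph"], params$pka_vde, params$n_vde)
  d["zeaxanthin"] <- params$k_vde * vde_act * (1 - s["zeaxanthin"]) -
    params$k_ep * s["zeaxanthin"]
  d["cumulative_lef"] <- v_psi
  d["cumulative_singlet_o2"] <- params$phi_1o2 * v_rec
  d["cumulative_psii"] <- v_psii
  d["cumulative_recombination"] <- v_rec
  d["cumulative_b6f"] <- v_b6f
  d["cumulative_atp_h"] <- v_atp_h
  attr(d, "fluxes") <- fluxes
  d
}
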