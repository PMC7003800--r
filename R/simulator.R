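# Dark equilibration, stiff integration over a light protocol, trajectory
# assembly and serialization.

# parameter packing order shared with src/model.cpp
.pack_params <- function(params, thermo, ring, psi_ion_eq) {
  c(
    params$antenna_rate_per_intensity, params$k_qa_pq, params$n_pq_e,
    params$k_b6f_max, params$n_hill_b6f, params$pka_reg, params$k_r,
    params$delta_e_stab, params$f_dist, params$phi_1o2, params$g_atpase,
    params$c_membrane, params$beta_lumen, params$g_ion, psi_ion_eq,
    params$pka_psbs, params$n_psbs, params$k_psbs, params$pka_vde,
    params$n_vde, params$k_vde, params$k_ep, params$qe_max,
    params$s23_target, params$k_s_decay, thermo$stromal_ph, thermo$z,
    equilibrium_pmf(thermo, ring), params$recomb_exp_cap
  )
}

.default_atol <- function() {
  a <- stats::setNames(rep(1e-9, length(.state_names)), .state_names)
  a["delta_psi"] <- 1e-11
  a[c(
    "cumulative_lef", "cumulative_singlet_o2", "cumulative_psii",
    "cumulative_recombination", "cumulative_b6f", "cumulative_atp_h"
  )] <- 1e-7
  a
}

#' Dark-equilibrated model state
#'
#' Constructs the state in which every net flux vanishes in darkness: the
#' pmf sits exactly at the ATP synthase equilibrium ([equilibrium_pmf()]),
#' partitioned between delta-psi and delta-pH according to `fraction_psi`;
#' all photochemical pools are relaxed (QA oxidized, P700 reduced, PQ at
#' its dark poise, no S2/S3 centers); PsbS protonation and zeaxanthin sit
#' at their steady states for the resulting lumen pH.  Physiologically this
#' is a chloroplast in darkness whose ATP synthase regulatory thiols are
#' still reduced: the minimum pmf needed to sustain dG_ATP.
#'
#' The residual of [derivatives()] at the returned state (with the
#' counter-ion Nernst potential set to the dark delta-psi, as
#' [simulate_run()] does) is verified to be below `tol`; a failure raises
#' an equilibration error carrying the residuals.
#'
#' @param ring A [cring_config()].
#' @param thermo A [thermo_params()].
#' @param params A [kinetic_params()].
#' @param fraction_psi Fraction of the dark pmf stored as delta-psi
#'   (default 0.5, the equal-partition assumption).
#' @param tol Residual tolerance for the fixed-point check (default 1e-6).
#' @return A [model_state()] with attribute `"pmf_dark"` (the `pmf_state`).
#' @examples
#' st <- dark_equilibrate(cring_config(14), thermo_params(), kinetic_params())
#' st["lumen_ph"] # ~7.05
#' @export
dark_equilibrate <- function(ring, thermo, params, fraction_psi = 0.5,
                             tol = 1e-6) {
  stopifnot(
    inherits(ring, "cring_config"), inherits(thermo, "thermo_params"),
    inherits(params, "kinetic_params")
  )
  pmf_eq <- equilibrium_pmf(thermo, ring)
  part <- partition_pmf(pmf_eq, fraction_psi, thermo)
  ph <- lumen_ph(thermo$stromal_ph, part$delta_ph)
  psbs <- hill_protonation(ph, params$pka_psbs, params$n_psbs)
  vde_act <- hill_protonation(ph, params$pka_vde, params$n_vde)
  denom <- params$k_vde * vde_act + params$k_ep
  zx <- if (denom > 0) params$k_vde * vde_act / denom else 0
  st <- model_state(
    qa_reduced = 0, pq_reduced = params$pq_dark, p700_ox = 0,
    lumen_ph = ph, delta_psi = part$delta_psi, counter_ion_moved = 0,
    s23_donor_frac = 0, psbs_protonated = psbs, zeaxanthin = zx
  )
  par2 <- params
  par2$psi_ion_eq <- part$delta_psi
  dd <- derivatives(
    0, st, ring, thermo, par2,
    light_static(0, 1)
  )
  scale <- pmax(abs(as.numeric(st)), 1)
  resid <- max(abs(as.numeric(dd)) / scale)
  if (resid > tol) {
    stop(errorCondition(
      sprintf("dark equilibration residual %.3g exceeds %.3g", resid, tol),
      residuals = dd, class = c("cringpmf_equilibration_error", "error")
    ))
  }
  attr(st, "pmf_dark") <- part
  st
}

#' Integrate the light-reaction model over an illumination protocol
#'
#' Starts from [dark_equilibrate()], integrates the stiff ODE system with an
#' adaptive L-stable Rosenbrock(2,3) method (restarting at every protocol
#' breakpoint so square-wave transitions are never stepped over), and
#' returns the trajectory sampled on a fixed reporting grid together with
#' all derived observables.  The run is fully deterministic; `seed` is
#' recorded in the metadata for provenance only.
#'
#' @param ring A [cring_config()].
#' @param thermo A [thermo_params()].
#' @param params A [kinetic_params()].  `psi_ion_eq = NA` (the default) is
#'   resolved to the dark-equilibrium delta-psi so that darkness is a fixed
#'   point of the full system.
#' @param protocol A `light_protocol`.
#' @param fraction_psi Dark pmf partition fraction (default 0.5).
#' @param grid_dt Reporting interval, s (default 0.5).
#' @param rtol Relative tolerance (default 1e-8).
#' @param atol Named per-state absolute tolerances; default
#'   1e-9 for pools/pH, 1e-11 V for delta-psi, 1e-7 for running integrals.
#' @param seed Optional integer recorded in the metadata (the core model is
#'   deterministic and does not consume it).
#' @param init_state Optional [model_state()] to start from instead of the
#'   dark equilibrium (the dark state is still computed to resolve
#'   `psi_ion_eq` and to anchor the light-induced deltas' t = 0 row).
#' @return An object of class `trajectory`: a data.frame with one row per
#'   reporting time and columns `time`, the state variables, derived
#'   observables (`pmf_total`, `delta_ph`, `delta_ph_v`, `b6f_relative_rate`,
#'   `b6f_rate_constant`, `qe_extent`, `lef_rate`, `singlet_o2_rate`,
#'   `recombination_rate`, `light`) and light-induced deltas
#'   (`d_pmf_total`, `d_delta_psi`, `d_delta_ph_v` relative to the dark
#'   values at t = 0).  Metadata (ring, protocol, params, solver
#'   diagnostics, dark state, seed) is attached as attribute `"meta"`.
#' @examples
#' \donttest{
#' tr <- simulate_run(cring_config(14), thermo_params(), kinetic_params(),
#'   light_static(100, 60), grid_dt = 1)
#' utils::tail(tr$lumen_ph, 1)
#' }
#' @export
simulate_run <- function(ring, thermo, params, protocol, fraction_psi = 0.5,
                         grid_dt = 0.5, rtol = 1e-8, atol = .default_atol(),
                         seed = NULL, init_state = NULL) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (!is.numeric(grid_dt) || grid_dt <= 0) {
    stop_invalid("grid_dt must be a positive number of seconds")
  }
  dark <- dark_equilibrate(ring, thermo, params, fraction_psi)
  psi_ion_eq <- if (is.na(params$psi_ion_eq)) {
    attr(dark, "pmf_dark")$delta_psi
  } else {
    params$psi_ion_eq
  }
  par_vec <- .pack_params(params, thermo, ring, psi_ion_eq)
  y0 <- if (is.null(init_state)) dark else validate_model_state(init_state)

  dur <- protocol$duration
  breaks <- light_breakpoints(protocol)
  grid <- sort(unique(c(seq(0, dur, by = grid_dt), breaks, dur)))
  # drop near-duplicates from floating-point grid construction
  keep <- c(TRUE, diff(grid) > 1e-9)
  grid <- grid[keep]
  is_break <- grid %in% c(0, breaks)
  seg_bounds <- c(breaks, dur)
  seg_end <- vapply(
    grid[-length(grid)],
    function(t0) seg_bounds[match(TRUE, seg_bounds > t0 + 1e-12)],
    numeric(1)
  )
  seg_end[is.na(seg_end)] <- dur

  if (!is.null(atol)) {
    if (is.null(names(atol))) {
      atol <- stats::setNames(rep_len(atol, length(.state_names)), .state_names)
    }
    atol <- atol[.state_names]
    if (anyNA(atol)) stop_invalid("atol must cover every state component")
  }

  res <- tryCatch(
    cpp_integrate(
      as.numeric(y0), par_vec, pack_light(protocol), grid, is_break,
      seg_end, rtol, as.numeric(atol),
      h_init = min(1e-3, grid_dt), max_steps = 5e6
    ),
    error = function(e) {
      stop_integration(paste0("integration failed: ", conditionMessage(e)))
    }
  )

  states <- res$states
  colnames(states) <- .state_names
  df <- data.frame(time = grid, states)

  z <- thermo$z
  df$delta_ph <- thermo$stromal_ph - df$lumen_ph
  df$delta_ph_v <- z * df$delta_ph
  df$pmf_total <- df$delta_psi + df$delta_ph_v
  df$b6f_rate_constant <- b6f_rate_constant(df$lumen_ph, params)
  df$b6f_relative_rate <- df$b6f_rate_constant / params$k_b6f_max
  df$qe_extent <- df$psbs_protonated * df$zeaxanthin
  df$light <- light_intensity(protocol, df$time)
  expfac <- 10^pmin(
    (params$f_dist * df$delta_psi - params$delta_e_stab) / 0.06,
    params$recomb_exp_cap
  )
  df$recombination_rate <- df$qa_reduced * df$s23_donor_frac * params$k_r * expfac
  df$singlet_o2_rate <- params$phi_1o2 * df$recombination_rate
  df$lef_rate <- params$antenna_rate_per_intensity * df$light * (1 - df$p700_ox)
  df$d_pmf_total <- df$pmf_total - df$pmf_total[1]
  df$d_delta_psi <- df$delta_psi - df$delta_psi[1]
  df$d_delta_ph_v <- df$delta_ph_v - df$delta_ph_v[1]

  structure(df,
    class = c("trajectory", "data.frame"),
    meta = list(
      ring = ring, thermo = thermo, params = params, protocol = protocol,
      fraction_psi = fraction_psi, psi_ion_eq = psi_ion_eq,
      grid_dt = grid_dt, rtol = rtol, atol = atol, seed = seed,
      dark_state = dark,
      solver = list(n_accept = res$n_accept, n_reject = res$n_reject)
    )
  )
}

#' @export
print.trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf(
    "trajectory: c%d ring, %s protocol, %.0f s, %d samples\n",
    meta$ring$c_subunits, meta$protocol$kind, meta$protocol$duration, nrow(x)
  ))
  s <- trajectory_summary(x)
  cat(sprintf(
    "  cumulative LEF %.4g e-/PSII, cumulative 1O2 %.4g, min lumen pH %.2f, max dpsi %.1f mV\n",
    s$cumulative_lef, s$cumulative_singlet_o2, s$min_lumen_ph,
    1000 * s$max_delta_psi
  ))
  invisible(x)
}

#' Scalar summary of a trajectory
#'
#' @param trajectory A `trajectory` from [simulate_run()].
#' @return List with ring size, protocol kind, photon dose, cumulative LEF
#'   and singlet-oxygen totals, minimum lumen pH and maximum delta-psi.
#' @export
trajectory_summary <- function(trajectory) {
  stopifnot(inherits(trajectory, "trajectory"))
  meta <- attr(trajectory, "meta")
  n <- nrow(trajectory)
  list(
    c_subunits = meta$ring$c_subunits,
    protocol = meta$protocol$kind,
    duration_s = meta$protocol$duration,
    total_dose = total_dose(meta$protocol),
    cumulative_lef = trajectory$cumulative_lef[n],
    cumulative_singlet_o2 = trajectory$cumulative_singlet_o2[n],
    min_lumen_ph = min(trajectory$lumen_ph),
    max_delta_psi = max(trajectory$delta_psi),
    pmf_dark_v = trajectory$pmf_total[1]
  )
}

#' Write a trajectory as a flat CSV
#'
#' One row per reporting time, one column per state or derived quantity,
#' full precision (15 significant digits).
#'
#' @param trajectory A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "trajectory"))
  df <- as.data.frame(trajectory)
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
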