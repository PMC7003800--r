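test_that("photosynthetic control is ten-fold between pH 7.5 and 5.5", {
  for (n in c(1, 1.5, 2)) {
    kp <- kinetic_params(n_hill_b6f = n)
    ratio <- b6f_rate_constant(7.5, kp) / b6f_rate_constant(5.5, kp)
    expect_equal(ratio, 10, tolerance = 0.02)
  }
  # n = 1 has the closed-form midpoint 6.5
  expect_equal(kp_default$pka_reg, 6.5, tolerance = 1e-9)
  # midpoint of the sigmoid is half-maximal; alkaline limit saturates
  expect_equal(
    b6f_rate_constant(kp_default$pka_reg, kp_default),
    kp_default$k_b6f_max / 2
  )
  expect_equal(b6f_rate_constant(14, kp_default), kp_default$k_b6f_max,
    tolerance = 1e-6
  )
  expect_true(all(diff(b6f_rate_constant(seq(4, 9, 0.1), kp_default)) > 0))
})

test_that("recombination rate follows the exponential delta-psi law", {
  kp <- kp_default
  st0 <- model_state(qa_reduced = 0, s23_donor_frac = 0.5, delta_psi = 0.1)
  expect_equal(recombination_rate(st0, kp), 0)

  st <- model_state(qa_reduced = 0.6, s23_donor_frac = 0.5, delta_psi = 0)
  expect_equal(recombination_rate(st, kp), 0.3 * kp$k_r)

  # a 0.06/f_dist volt increase multiplies the rate by 10
  st_hi <- st
  st_hi["delta_psi"] <- 0.06 / kp$f_dist
  expect_equal(recombination_rate(st_hi, kp) / recombination_rate(st, kp), 10,
    tolerance = 1e-9
  )

  # strictly increasing in delta-psi
  rates <- vapply(seq(-0.05, 0.25, by = 0.01), function(v) {
    s <- st
    s["delta_psi"] <- v
    recombination_rate(s, kp)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))

  expect_equal(singlet_o2_rate(st, kp), kp$phi_1o2 * recombination_rate(st, kp))
})

test_that("ATP synthase flux is ohmic around the equilibrium pmf", {
  th <- th_default
  ring <- cring_config(14)
  kp <- kp_default
  pmf_eq <- equilibrium_pmf(th, ring)
  expect_equal(atp_synthase_flux(pmf_eq, ring, th, kp), 0)
  expect_equal(
    atp_synthase_flux(pmf_eq + 0.01, ring, th, kp),
    kp$g_atpase * 0.01
  )
  expect_lt(atp_synthase_flux(pmf_eq - 0.02, ring, th, kp), 0)
  kp0 <- kinetic_params(g_atpase = 0)
  expect_equal(atp_synthase_flux(0.3, ring, th, kp0), 0)
})

test_that("qE extent is off near pH 7 and engages by pH 6.5", {
  kp <- kp_default
  expect_lt(qe_extent(7.8, NULL, kp), 1e-3)
  expect_lt(qe_extent(7.05, NULL, kp), 0.01)
  expect_gt(qe_extent(6.5, NULL, kp), 0.05)
  expect_gt(qe_extent(6.5, NULL, kp), qe_extent(7.0, NULL, kp))
  # sigmoid midpoint: pKa at the lumen pH with Hill n = 1 gives 0.5 protonation
  kp_mid <- kinetic_params(pka_psbs = 6.8, n_psbs = 1, pka_vde = 6.8, n_vde = 1)
  act <- qe_extent(6.8, NULL, kp_mid)
  zx_ss <- kp_mid$k_vde * 0.5 / (kp_mid$k_vde * 0.5 + kp_mid$k_ep)
  expect_equal(act, 0.5 * zx_ss, tolerance = 1e-12)
  # instantaneous form reads the state
  st <- model_state(psbs_protonated = 0.4, zeaxanthin = 0.5)
  expect_equal(qe_extent(7.0, st, kp), 0.2)
})

test_that("counter-ion flux is ohmic in delta-psi", {
  kp <- kp_default
  st <- model_state(delta_psi = 0.1)
  expect_equal(counter_ion_flux(st, kp), kp$g_ion * 0.1)
  st_eq <- model_state(delta_psi = 0)
  expect_equal(counter_ion_flux(st_eq, kp), 0)
  expect_equal(counter_ion_flux(st, kinetic_params(g_ion = 0)), 0)
})

test_that("kinetic_params validates ranges and rejects unknown keys", {
  expect_error(kinetic_params(nope = 1), class = "cringpmf_config_error")
  expect_error(kinetic_params(f_dist = 1.5), class = "cringpmf_invalid_parameter")
  expect_error(kinetic_params(k_r = -1), class = "cringpmf_invalid_parameter")
  expect_error(kinetic_params(pka_psbs = 9), class = "cringpmf_invalid_parameter")
})

test_that("dark equilibrium is a fixed point of the derivatives", {
  for (cc in c(8, 14)) {
    ring <- cring_config(cc)
    st <- dark_equilibrate(ring, th_default, kp_default)
    kp2 <- kinetic_params(psi_ion_eq = attr(st, "pmf_dark")$delta_psi)
    d <- derivatives(0, st, ring, th_default, kp2, light_static(0, 1))
    expect_lt(max(abs(as.numeric(d)) / pmax(abs(as.numeric(st)), 1)), 1e-6)
  }
})

test_that("proton bookkeeping identity holds in the derivatives", {
  set.seed(7)
  ring <- cring_config(11)
  for (i in 1:20) {
    st <- model_state(
      qa_reduced = stats::runif(1), pq_reduced = stats::runif(1),
      p700_ox = stats::runif(1), lumen_ph = stats::runif(1, 5, 8),
      delta_psi = stats::runif(1, -0.05, 0.2),
      s23_donor_frac = stats::runif(1), psbs_protonated = stats::runif(1),
      zeaxanthin = stats::runif(1)
    )
    d <- derivatives(1, st, ring, th_default, kp_default, light_static(300, 10))
    fl <- attr(d, "fluxes")
    influx <- fl[["v_psii"]] + 2 * fl[["v_b6f"]] - fl[["v_atp_h"]]
    expect_equal(
      unname(d["lumen_ph"]) * kp_default$beta_lumen, -influx,
      tolerance = 1e-12
    )
    expect_equal(unname(d["cumulative_lef"]), fl[["v_psi"]])
    expect_equal(
      unname(d["cumulative_singlet_o2"]),
      kp_default$phi_1o2 * fl[["v_rec"]]
    )
  }
})

test_that("a light step from darkness charges the membrane and acidifies", {
  ring <- cring_config(14)
  st <- dark_equilibrate(ring, th_default, kp_default)
  kp2 <- kinetic_params(psi_ion_eq = attr(st, "pmf_dark")$delta_psi)
  d <- derivatives(0, st, ring, th_default, kp2, light_static(1000, 10))
  expect_gt(unname(d["delta_psi"]), 0)
  expect_lt(unname(d["lumen_ph"]), 0)
})

test_that("R and C++ right-hand sides agree to machine precision", {
  set.seed(123)
  ring <- cring_config(9)
  protos <- list(
    light_static(137, 100),
    light_sinusoidal(90, 60, 45, 100),
    light_square_wave(0, 200, 40, 0.5, 100)
  )
  kp <- kinetic_params(psi_ion_eq = 0.03)
  pv <- cringpmf:::.pack_params(kp, th_default, ring, 0.03)
  for (i in 1:30) {
    st <- model_state(
      qa_reduced = stats::runif(1), pq_reduced = stats::runif(1),
      p700_ox = stats::runif(1), lumen_ph = stats::runif(1, 5, 8),
      delta_psi = stats::runif(1, -0.05, 0.25),
      counter_ion_moved = stats::rnorm(1),
      s23_donor_frac = stats::runif(1), psbs_protonated = stats::runif(1),
      zeaxanthin = stats::runif(1)
    )
    tt <- stats::runif(1, 0, 99)
    proto <- protos[[1 + i %% 3]]
    d_r <- derivatives(tt, st, ring, th_default, kp, proto)
    d_c <- cringpmf:::cpp_rhs(
      tt, as.numeric(st), pv, cringpmf:::pack_light(proto)
    )
    expect_equal(as.numeric(d_r), d_c, tolerance = 1e-12)
  }
})

test_that("non-finite fluxes raise an integration error naming the term", {
  ring <- cring_config(14)
  st <- model_state(
    qa_reduced = 0.5, s23_donor_frac = 0.5, delta_psi = NaN, lumen_ph = 7
  )
  err <- expect_error(
    derivatives(0, st, ring, th_default, kp_default, light_static(100, 10)),
    class = "cringpmf_integration_error"
  )
  expect_match(conditionMessage(err), "v_rec")
})
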