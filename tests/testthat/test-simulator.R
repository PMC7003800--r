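test_that("dark_equilibrate reproduces the printed dark pmf and lumen pH", {
  st14 <- dark_equilibrate(cring_config(14), th_default, kp_default)
  p14 <- attr(st14, "pmf_dark")
  expect_equal(p14$pmf_total, 0.0888, tolerance = 1e-3)
  expect_equal(unname(st14["lumen_ph"]), 7.05, tolerance = 0.01)

  st8 <- dark_equilibrate(cring_config(8), th_default, kp_default)
  p8 <- attr(st8, "pmf_dark")
  expect_equal(p8$pmf_total, 0.1555, tolerance = 1e-3)
  expect_equal(unname(st8["lumen_ph"]), 6.49, tolerance = 0.01)

  # partition respected, redox pools relaxed
  expect_equal(p8$delta_psi, 0.5 * p8$pmf_total)
  expect_equal(unname(st8["qa_reduced"]), 0)
  expect_equal(unname(st8["pq_reduced"]), kp_default$pq_dark)
})

test_that("an all-dark run keeps every observable at its dark value", {
  tr <- run_short(14, light_static(0, 120))
  expect_lt(max(abs(tr$d_pmf_total)), 1e-6)
  expect_lt(max(abs(tr$d_delta_psi)), 1e-6)
  expect_lt(max(abs(tr$d_delta_ph_v)), 1e-6)
  expect_lt(max(abs(tr$lumen_ph - tr$lumen_ph[1])), 1e-6)
  expect_lt(tr$cumulative_singlet_o2[nrow(tr)], 1e-9)
})

test_that("trajectories satisfy Eq.-1 composition and the conservation identities", {
  kp <- kp_default
  tr <- run_short(12, light_square_wave(0, 400, 20, 0.5, 60))
  # pmf recomposed from delta-psi and pH at every sample
  expect_equal(
    tr$pmf_total, tr$delta_psi + th_default$z * (7.8 - tr$lumen_ph),
    tolerance = 1e-12
  )
  # charge: delta-psi tracks the integrated electrogenic flux
  q <- kp$c_membrane * (tr$cumulative_psii + tr$cumulative_b6f +
    tr$cumulative_lef - tr$cumulative_recombination - tr$cumulative_atp_h -
    tr$counter_ion_moved)
  expect_lt(max(abs(tr$delta_psi - tr$delta_psi[1] - q)), 1e-8)
  # electrons: LEF = stable separations - recombination - pool storage
  stored <- tr$qa_reduced + kp$n_pq_e * (tr$pq_reduced - tr$pq_reduced[1]) -
    tr$p700_ox
  expect_lt(
    max(abs(tr$cumulative_lef -
      (tr$cumulative_psii - tr$cumulative_recombination - stored))),
    1e-7
  )
  # protons: buffered pH change equals net deposited protons
  expect_lt(
    max(abs((tr$lumen_ph[1] - tr$lumen_ph) * kp$beta_lumen -
      (tr$cumulative_psii + 2 * tr$cumulative_b6f - tr$cumulative_atp_h))),
    1e-6
  )
  # cumulative quantities are non-decreasing
  for (col in c(
    "cumulative_lef", "cumulative_singlet_o2", "cumulative_psii",
    "cumulative_recombination", "cumulative_b6f"
  )) {
    expect_true(all(diff(tr[[col]]) > -1e-9), label = col)
  }
  # recombination-competent pool never exceeds the closed-center fraction
  expect_true(all(tr$s23_donor_frac * tr$qa_reduced <= tr$qa_reduced + 1e-12))
})

test_that("membrane charging matches the frozen-capacitor closed form", {
  # both photosystems charge the capacitor with rate a*I*exp(-a*I*t);
  # closed form: dpsi(t) = dpsi0 + 2 c (1 - exp(-a I t))
  tr <- simulate_run(
    cring_config(14), th_default, kp_frozen, light_static(1000, 0.05),
    grid_dt = 0.001
  )
  a_i <- kp_frozen$antenna_rate_per_intensity * 1000
  pred <- tr$delta_psi[1] +
    kp_frozen$c_membrane * 2 * (1 - exp(-a_i * tr$time))
  growth_err <- abs(tr$delta_psi - pred) /
    pmax(pred - tr$delta_psi[1], 1e-12)
  expect_lt(max(growth_err[-1]), 0.01)
})

test_that("counter-ion relaxation follows the linear-ODE closed form", {
  kp <- kinetic_params(
    g_atpase = 0, k_qa_pq = 0, k_b6f_max = 0, k_r = 0, qe_max = 0,
    psi_ion_eq = 0
  )
  st <- dark_equilibrate(cring_config(14), th_default, kp)
  st["delta_psi"] <- 0.1
  tr <- simulate_run(
    cring_config(14), th_default, kp, light_static(0, 20),
    grid_dt = 0.25, init_state = st
  )
  tau <- 1 / (kp$g_ion * kp$c_membrane)
  expect_lt(max(abs(tr$delta_psi - 0.1 * exp(-tr$time / tau))), 1e-6)
  # initial flux is g_ion * 0.1
  expect_equal(
    (tr$counter_ion_moved[2] - tr$counter_ion_moved[1]) / 0.25,
    kp$g_ion * 0.1,
    tolerance = 0.05
  )
})

test_that("runs are deterministic and converged in tolerance", {
  t1 <- run_short(14, light_static(100, 60))
  t2 <- run_short(14, light_static(100, 60))
  expect_identical(as.data.frame(t1), as.data.frame(t2))

  t3 <- simulate_run(cring_config(14), th_default, kp_default,
    light_static(100, 60),
    grid_dt = 0.5, rtol = 5e-9, atol = cringpmf:::.default_atol() / 2
  )
  n <- nrow(t1)
  expect_lt(
    abs(t1$cumulative_lef[n] / t3$cumulative_lef[n] - 1), 1e-3
  )
})

test_that("photosynthetic control shuts down electron flow without ATP synthase", {
  # with proton efflux essentially off, pmf shoots up, the lumen acidifies,
  # and pH control must throttle the b6f complex until linear flow stalls:
  # the electron-flux runaway is self-limiting even though the capacitor
  # briefly stores every translocated charge
  kp <- kinetic_params(g_atpase = 0)
  tr <- simulate_run(
    cring_config(14), th_default, kp, light_static(500, 600),
    grid_dt = 1
  )
  expect_true(all(is.finite(tr$pmf_total)))
  expect_gt(tr$pmf_total[61], tr$pmf_total[1]) # light builds pmf
  n <- nrow(tr)
  expect_lt(tr$b6f_relative_rate[n], 0.01 * tr$b6f_relative_rate[1])
  early_lef <- (tr$cumulative_lef[61] - tr$cumulative_lef[1]) / 60
  late_lef <- (tr$cumulative_lef[n] - tr$cumulative_lef[n - 60]) / 60
  expect_lt(late_lef, 0.05 * early_lef)
})

test_that("square-wave transitions appear in the trajectory grid", {
  tr <- run_short(14, light_square_wave(0, 200, 7, 0.5, 21))
  expect_true(all(c(3.5, 7, 10.5, 14) %in% tr$time))
  expect_true(all(diff(tr$time) > 0))
  # light column matches the protocol evaluator
  expect_equal(
    tr$light,
    light_intensity(light_square_wave(0, 200, 7, 0.5, 21), tr$time)
  )
})

test_that("trajectory CSV round-trips numerically", {
  tr <- run_short(14, light_static(50, 10))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_equal(back$cumulative_lef, tr$cumulative_lef, tolerance = 1e-12)
  expect_equal(back$delta_psi, tr$delta_psi, tolerance = 1e-12)
  unlink(path)
})
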