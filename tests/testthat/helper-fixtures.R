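# shared fixtures: default parameter sets and a short-run helper
th_default <- thermo_params()
kp_default <- kinetic_params()

run_short <- function(c_subunits = 14, protocol = light_static(200, 30),
                      params = kp_default, ...) {
  simulate_run(cring_config(c_subunits), th_default, params, protocol,
    grid_dt = 0.5, ...)
}

# frozen linear "capacitor" parameter set: both photosystems charge the
# membrane, every other flux switched off
kp_frozen <- kinetic_params(
  g_atpase = 0, g_ion = 0, k_r = 0, k_qa_pq = 0, k_b6f_max = 0, qe_max = 0
)
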