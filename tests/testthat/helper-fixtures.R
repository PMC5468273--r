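# Shared fixture builders; everything is generated in code, no stored data.

# Default assay geometry and its analytic initial slope for Pf = 2e-2 cm/s,
# 200 -> 70 mOsm: Pf*S*Vw*dOsm/V0 = 2e-2 * 0.045 * 18 * 1.3e-4 / 9e-4.
SLOPE_REF <- 2.34e-3

# a noise-free single-oocyte tidy data frame from the forward model
noise_free_cohort <- function(pf = 2e-2, n = 1, duration = 60, dt = 1,
                              seed = 1) {
  sim_swelling_cohort(swelling_sim_params(
    pf_true = pf, n_oocytes = n, pf_cv = 0, area_noise_cv = 0,
    duration = duration, dt = dt, seed = seed))
}

# hand-built wide bug table with exact arithmetic
anchor_bug <- function() {
  data.frame(bug_id = "b1", group = "g", w_prefeed = 4.0, w_fed = 16.0,
             wt_12 = 12.0, wt_24 = 10.0, stringsAsFactors = FALSE)
}
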