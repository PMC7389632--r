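# Shared fixtures. The staged adult calibration takes ~25 s, so it is run
# once per session and cached, together with the standard adult protocol
# simulations derived from it.

.fixture_env <- function() {
  if (!exists(".pedpbpk_test_cache", envir = globalenv())) {
    assign(".pedpbpk_test_cache", new.env(parent = emptyenv()),
           envir = globalenv())
  }
  get(".pedpbpk_test_cache", envir = globalenv())
}

cached <- function(name, expr) {
  env <- .fixture_env()
  if (!exists(name, envir = env)) assign(name, force(expr), envir = env)
  get(name, envir = env)
}

reference_adult <- function() cached("adult", build_individual(29, "male"))

calibrated <- function() {
  cached("calibration", calibrate_workflow(reference_adult()))
}

calibrated_model <- function() {
  cached("model", build_model(reference_adult(), calibrated()$drug))
}

adult_sim <- function(which) {
  m <- calibrated_model()
  switch(which,
    iv = cached("sim_iv",
                simulate_regimen(m, regimen("iv_bolus", 2.97), 480,
                                 dt_out_h = 0.01)),
    oral = cached("sim_oral", simulate_regimen(m, regimen("oral", 20), 120)),
    fed = cached("sim_fed",
                 simulate_regimen(m, regimen("oral", 20, fed = TRUE), 120)),
    multi = cached("sim_multi",
                   simulate_regimen(m, regimen("oral", 20, n_doses = 10),
                                    240)),
    stop("unknown fixture: ", which))
}

obs_noise_free <- function() {
  cached("obs_noise_free",
         gen_reference_observation_set(calibrated()$drug, noise_cv = 0,
                                       n_subjects = 3, seed = 7,
                                       height_sd_fraction = 0))
}

obs_noisy <- function() {
  cached("obs_noisy",
         gen_reference_observation_set(calibrated()$drug, noise_cv = 0.15,
                                       n_subjects = 12, seed = 7))
}

recovery_noise_free <- function() {
  cached("recovery_noise_free",
         calibrate_workflow(reference_adult(), observations = obs_noise_free()))
}

recovery_noisy <- function() {
  cached("recovery_noisy",
         calibrate_workflow(reference_adult(), observations = obs_noisy()))
}

# quick mid-sized drug set for engine property tests (no calibration needed)
test_drug <- function(...) {
  adult <- reference_adult()
  args <- utils::modifyList(
    list(cl_renal_adult_l_h = 4.35,
         kp_scalar = solve_kp_scalar(0.89, adult, 0.2, 0.02)),
    list(...))
  do.call(lisinopril, args)
}
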