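# Shared fixtures, built in code.

# Canonical secretion/model parameters of the synthetic validation protocol
# (glucose in mg/L).
val_secretion <- function() secretion_params(Km = 0.6, C0 = 1000, alpha = 0.01)

val_model <- function(tau_p = 15) {
  model_params("single", val_secretion(), tau_p = tau_p)
}

# A small deterministic clinical-style record (glucose mg/dl).
toy_record <- function() {
  ogtt_record(times = c(-10, 0, 20, 30, 60, 90, 120, 150, 180),
              glucose = c(92, 90, 120, 150, 140, 120, 110, 100, 95),
              insulin = c(5, 5.2, 9, 14, 16, 12, 9, 7, 6),
              cpeptide = c(1.1, 1.0, 1.6, 2.3, 2.6, 2.2, 1.8, 1.5, 1.3),
              subject_id = "toy", glucose_unit = "mg/dl")
}

# Noise-free synthetic subject under the validation conditions.
noiseless_subject <- function(seed = 1, tau_p = 15) {
  spec <- synthetic_spec(noise_fraction = 0,
                         theta_insulin = val_model(tau_p))
  generate_subject(spec, seed = seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * abs(expected)),
              label = sprintf("max rel err %.3g vs tol %.3g",
                              max(abs(actual - expected) / abs(expected)), tol))
}
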