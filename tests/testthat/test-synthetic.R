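# Ground-truth generator: glucose pulse, model-consistent truth, noise,
# corruption, and the generate-then-refit closure.

test_that("the glucose pulse hits its landmarks", {
  spec <- synthetic_spec(noise_fraction = 0)
  # flat baseline before ingestion, peak value g_b + A at t_peak
  expect_equal(generate_glucose_profile(spec, c(-10, -1, 0)), rep(900, 3))
  expect_equal(generate_glucose_profile(spec, spec$t_peak), 1800)
  # zero amplitude leaves a constant baseline
  flat <- synthetic_spec(g_amplitude = 0, noise_fraction = 0)
  expect_equal(generate_glucose_profile(flat, seq(-10, 180, 10)), rep(900, 20))
  # a normal-range pulse stays within its band and settles back down
  nr <- synthetic_spec(g_baseline = 90, g_amplitude = 90, t_peak = 45,
                       shape = 1, glucose_unit = "mg/dl", noise_fraction = 0,
                       theta_insulin = val_model())
  g <- generate_glucose_profile(nr, seq(-10, 300, 1))
  expect_true(all(g >= 90 & g <= 180))
  expect_lt(generate_glucose_profile(nr, 300), 100)
  expect_error(synthetic_spec(t_peak = -5), "t_peak")
})

test_that("noiseless sampling equals the truth and seeds are reproducible", {
  spec <- synthetic_spec(noise_fraction = 0)
  subj <- generate_subject(spec, seed = 1)
  idx <- match(spec$sample_times, round(subj$truth$time, 6))
  expect_equal(subj$record$glucose, subj$truth$glucose[idx])
  expect_equal(subj$record$insulin, subj$truth$insulin[idx])
  expect_equal(subj$record$cpeptide, subj$truth$cpeptide[idx])

  noisy <- synthetic_spec(noise_fraction = 0.2)
  s1 <- generate_subject(noisy, seed = 7)
  s2 <- generate_subject(noisy, seed = 7)
  expect_identical(s1$record, s2$record)
  s3 <- generate_subject(noisy, seed = 8)
  expect_false(identical(s1$record$insulin, s3$record$insulin))
})

test_that("the dense truth satisfies the discrete model recursion", {
  spec <- synthetic_spec(noise_fraction = 0)
  subj <- generate_subject(spec, seed = 1)
  tr <- subj$truth
  tau <- spec$theta_insulin$tau_p
  phi <- exp(-0.1 / tau)
  gamma <- tau * (1 - phi)
  n <- nrow(tr)
  umid <- (tr$isr[-n] + tr$isr[-1]) / 2  # step-averaged secretion input
  resid <- tr$insulin[-1] - (phi * tr$insulin[-n] + gamma * umid)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("molar coupling holds exactly in the ground truth", {
  subj <- generate_subject(synthetic_spec(noise_fraction = 0), seed = 2)
  ratio <- subj$truth$csr / subj$truth$isr
  expect_equal(range(ratio), rep(molar_csr_per_isr, 2), tolerance = 1e-12)
})

test_that("corruption multiplies the chosen sample after noise", {
  spec0 <- synthetic_spec(noise_fraction = 0.1)
  spec1 <- synthetic_spec(noise_fraction = 0.1,
                          corruption = list(time = 60, factor = 0.6))
  a <- generate_subject(spec0, seed = 5)$record
  b <- generate_subject(spec1, seed = 5)$record
  k <- which(a$times == 60)
  expect_equal(b$glucose[k], 0.6 * a$glucose[k])
  expect_equal(b$glucose[-k], a$glucose[-k])
  expect_equal(b$insulin, a$insulin)  # glucose-only corruption by default
  expect_error(synthetic_spec(corruption = list(time = 45, factor = 0.6)),
               "sample_times")
})

test_that("subject CSVs round-trip through the standard OGTT reader", {
  subj <- generate_subject(synthetic_spec(noise_fraction = 0.2), seed = 3)
  stem <- file.path(withr::local_tempdir(), "subj")
  paths <- write_subject(subj, stem)
  back <- read_ogtt(paste0(stem, "_record.csv"), glucose_unit = "mg/L")
  expect_equal(back$glucose, subj$record$glucose)
  truth <- utils::read.csv(paste0(stem, "_truth.csv"))
  expect_equal(nrow(truth), nrow(subj$truth))
})

test_that("the generate-then-refit loop closes at zero noise", {
  rs <- recovery_study(taus = c(15), noise_fraction = 0, n_reps = 1,
                       n_starts = 10, seed = 1)
  expect_true(all(rs$ok))
  expect_lt(rs$err_tau, 0.005)
  expect_lt(max(rs$err_Km, rs$err_C0, rs$err_alpha), 0.005)
})

test_that("recovery_study records failures without aborting and summarizes", {
  rs <- recovery_study(taus = c(15, 30), noise_fraction = 0, n_reps = 2,
                       n_starts = 6, seed = 2)
  expect_s3_class(rs, "recovery_study")
  expect_equal(nrow(rs), 4)
  s <- summary(rs)
  expect_s3_class(s, "summary.recovery_study")
  expect_true(is.finite(s$tau_max_err_pct))
  expect_lt(s$tau_max_err_pct, 0.5)
  # an all-failed table still summarizes gracefully
  rs$ok <- FALSE
  s0 <- summary(rs)
  expect_true(is.na(s0$tau_max_err_pct))
  expect_equal(s0$n_failed, 4)
})
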