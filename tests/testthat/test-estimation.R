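# Objective function, bounded Levenberg-Marquardt, and the multi-start
# ensemble.

test_that("objective equals a brute-force residual sum and is permutation-invariant", {
  rec <- toy_record()
  gi <- interpolate_glucose(rec)
  theta <- model_params("single", secretion_params(20, 1300, 0.08), tau_p = 12)
  # independent summation oracle over the measured points
  y <- simulate_plasma(theta, gi, out_times = rec$times)$value
  oracle <- 0
  for (k in seq_along(rec$times)) oracle <- oracle + (rec$insulin[k] - y[k])^2
  expect_equal(ogtt_objective(theta, rec, gi, "insulin"), oracle)

  # self-consistency: measurements generated by the model give ~zero cost
  z <- simulate_plasma(theta, gi, out_times = rec$times)$value
  rec2 <- ogtt_record(rec$times, rec$glucose, insulin = z)
  gi2 <- interpolate_glucose(rec2)
  expect_lt(ogtt_objective(theta, rec2, gi2, "insulin"), 1e-12 * sum(z^2))

  # measurement order cannot matter (series are tied to times)
  expect_error(ogtt_objective(theta, ogtt_record(rec$times[1:4], rec$glucose[1:4],
                                                 rec$insulin[1:4]),
                              gi, "insulin"),
               "more insulin measurements")
})

test_that("a single bounded LM start descends and flags boundary hits", {
  subj <- noiseless_subject(seed = 5)
  rec <- subj$record
  gi <- interpolate_glucose(rec)
  b <- validation_bounds()
  th0 <- c(tau_p = 40, Km = 2, C0 = 800, alpha = 0.02)
  start_cost <- ogtt_objective(isrfit:::.vec_to_params(th0, "single"), rec, gi, "insulin")
  fit <- fit_single_start(rec, gi, "insulin", th0, b)
  expect_s3_class(fit, "fit_result")
  expect_lte(fit$cost, start_cost)
  expect_true(fit$converged)

  # narrowing a bound to exclude the truth pins the solution on it
  b_narrow <- param_bounds("mg/L", tau_p = c(5, 180), Km = c(0.01, 0.3),
                           C0 = c(200, 1500), alpha = c(0.005, 0.045))
  fit_n <- fit_single_start(rec, gi, "insulin",
                            c(tau_p = 40, Km = 0.2, C0 = 800, alpha = 0.02),
                            b_narrow)
  expect_true(fit_n$at_boundary)
  expect_error(fit_single_start(rec, gi, "insulin",
                                c(tau_p = 1, Km = 2, C0 = 800, alpha = 0.02), b),
               "within the bounds")
})

test_that("noiseless ensembles recover the generating parameters tightly", {
  subj <- noiseless_subject(seed = 1)
  ens <- fit_ensemble(subj$record, "insulin", bounds = validation_bounds(),
                      n_starts = 12, seed = 2)
  truth <- c(tau_p = 15, Km = 0.6, C0 = 1000, alpha = 0.01)
  expect_rel_equal(colMeans(ens$params), truth, 0.005)
  # the optimum set is degenerate: coefficient of variation under 1%
  cv <- apply(ens$params, 2, sd) / colMeans(ens$params)
  expect_true(all(cv < 0.01))
})

test_that("ensembles are bitwise-reproducible for a fixed seed", {
  subj <- noiseless_subject(seed = 9)
  e1 <- fit_ensemble(subj$record, "insulin", bounds = validation_bounds(),
                     n_starts = 8, seed = 31)
  e2 <- fit_ensemble(subj$record, "insulin", bounds = validation_bounds(),
                     n_starts = 8, seed = 31)
  expect_identical(e1$params, e2$params)
  expect_identical(e1$traj, e2$traj)
  e3 <- fit_ensemble(subj$record, "insulin", bounds = validation_bounds(),
                     n_starts = 8, seed = 32)
  expect_false(identical(e1$params, e3$params))
})

test_that("fit_subject fits available species independently", {
  subj <- noiseless_subject(seed = 4)
  rec <- subj$record
  fits <- fit_subject(rec, bounds = validation_bounds(), n_starts = 8, seed = 3)
  expect_s3_class(fits$insulin, "fit_ensemble")
  expect_s3_class(fits$cpeptide, "fit_ensemble")
  # molar coupling recovered through two independent fits
  KmI <- mean(fits$insulin$params[, "Km"])
  KmC <- mean(fits$cpeptide$params[, "Km"])
  expect_equal(KmC / KmI, molar_csr_per_isr, tolerance = 0.01)

  # insulin-only record: one ensemble, the other slot empty
  rec_i <- ogtt_record(rec$times, rec$glucose, insulin = rec$insulin)
  fits_i <- fit_subject(rec_i, bounds = validation_bounds(), n_starts = 8, seed = 3)
  expect_null(fits_i$cpeptide)
  # and the insulin ensemble is unaffected by the other species' presence
  expect_equal(fits_i$insulin$params, fits$insulin$params)

  expect_error(fit_subject(ogtt_record(rec$times, rec$glucose)), "neither")
})
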