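settings <- estimation_settings()

test_that("the squared sweat error is symmetric and zero at equality", {
  expect_equal(sweat_error(10, 7), 9)
  expect_equal(sweat_error(3.2, 3.2), 0)
  expect_equal(sweat_error(2, 5), sweat_error(5, 2))
  expect_error(sweat_error(NA, 1), "finite")
})

test_that("forward-then-inverse round trip recovers blood cortisol", {
  for (Cb in c(50, 355, 1000)) {
    sw <- surface_nmoll(Cb)
    m <- sweat_measurement("s", "pre_surgery", sw, 1)
    est <- estimate_blood(m, default_p, settings, default_d)
    expect_true(est$converged)
    expect_lte(est$n_iter, 50)
    expect_lte(est$error_trace[length(est$error_trace)], 0.01)
    expect_lt(abs(est$C_blood_hat - Cb) / Cb, 1e-3)
  }
})

test_that("zero sweat cortisol maps to exactly zero blood cortisol", {
  m <- sweat_measurement("s", "pre_surgery", 0, 1)
  est <- estimate_blood(m, default_p, settings, default_d)
  expect_identical(est$C_blood_hat, 0)
  expect_true(est$converged)
})

test_that("the estimate scales linearly with the measured sweat value", {
  m1 <- sweat_measurement("s", "pre_surgery", 0.6, 1)
  m2 <- sweat_measurement("s", "pre_surgery", 1.2, 1)
  e1 <- estimate_blood(m1, default_p, settings, default_d)
  e2 <- estimate_blood(m2, default_p, settings, default_d)
  expect_equal(e2$C_blood_hat, 2 * e1$C_blood_hat, tolerance = 1e-6)
})

test_that("the error trace starts at the initialization's error", {
  sw_init <- surface_nmoll(settings$C_blood_init)
  m <- sweat_measurement("s", "pre_surgery", 1.5, 1)
  est <- estimate_blood(m, default_p, settings, default_d)
  expect_equal(est$error_trace[1], (1.5 - sw_init)^2, tolerance = 1e-9)
})

test_that("the outer loop converges across the measurement range", {
  for (sw in c(0, 0.01, 0.4, 1.7, 55, 500)) {
    m <- sweat_measurement("s", "post_no_dexa", sw, 1)
    est <- estimate_blood(m, default_p, settings, default_d)
    expect_true(est$converged)
    expect_lte(est$n_iter, 50)
  }
})

test_that("personalization recovers the generating free-cortisol fraction", {
  for (a in c(0.113, 0.05)) {
    truth <- update_parameters(default_p, alpha = a)
    sw <- surface_nmoll(420, 1.3, truth)
    m <- sweat_measurement("s", "post_no_dexa", sw, 1.3, 420)
    fit <- personalize_params(m, default_p, settings, default_d)
    expect_lt(abs(fit$alpha - a) / a, 0.01)
    expect_lt(fit$sse, 1e-10)
  }
})

test_that("personalization is a fixed point on default-consistent data", {
  sw <- surface_nmoll(355, 1)
  m <- sweat_measurement("s", "pre_surgery", sw, 1, 355)
  fit <- personalize_params(m, default_p, settings, default_d)
  expect_lt(abs(fit$alpha - default_p$alpha) / default_p$alpha, 1e-3)
})

test_that("noisy two-record groups still bracket the true fraction", {
  set.seed(7)
  a_true <- 0.09
  truth <- update_parameters(default_p, alpha = a_true)
  noise <- exp(rnorm(2, 0, sqrt(log(1 + 0.1^2))))
  rows <- rbind(
    sweat_measurement("s", "post_no_dexa",
                      surface_nmoll(300, 1, truth) * noise[1], 1, 300),
    sweat_measurement("s", "post_no_dexa",
                      surface_nmoll(520, 0.8, truth) * noise[2], 0.8, 520)
  )
  fit <- personalize_params(rows, default_p, settings, default_d)
  expect_lt(abs(fit$alpha - a_true) / a_true, 0.25)
})

test_that("over-parameterized personalization fails loudly", {
  s2 <- estimation_settings(personalized_params = c("alpha", "S_enzyme"))
  m <- sweat_measurement("s", "pre_surgery", 0.7, 1, 355)
  expect_error(personalize_params(m, default_p, s2, default_d),
               "unidentifiable")
})

test_that("calibration records must carry a blood reference", {
  m <- sweat_measurement("s", "pre_surgery", 0.7, 1)
  expect_error(personalize_params(m, default_p, settings, default_d),
               "C_blood_ref")
})

test_that("double loop without personalization reduces to plain inversion", {
  s0 <- estimation_settings(personalized_params = character(0))
  m <- sweat_measurement("s", "pre_surgery", 0.9, 1)
  res <- double_loop(m, default_p, s0, default_d)
  est <- estimate_blood(m, default_p, s0, default_d)
  expect_equal(res$C_blood_hat, est$C_blood_hat)
  expect_equal(res$n_iter, est$n_iter)
})

test_that("double loop on a noise-free cohort is exact", {
  coh <- generate_cohort(cohort_spec(n_subjects = 6, noise_cv = 0, seed = 11),
                         default_p, default_d)
  res <- double_loop(coh$measurements, default_p, settings, default_d)
  expect_true(all(res$converged))
  expect_gt(cor(res$C_blood_hat, coh$truth$C_blood), 0.999)
  expect_lt(sqrt(mean((res$C_blood_hat - coh$truth$C_blood)^2)), 1)
  # with noise-free calibration the personalized fraction is the truth
  expect_equal(res$alpha_hat, coh$truth$alpha, tolerance = 1e-4)
})

test_that("scaling all sweat measurements scales all estimates", {
  coh <- generate_cohort(cohort_spec(n_subjects = 4, noise_cv = 0, seed = 3),
                         default_p, default_d)
  s0 <- estimation_settings(personalized_params = character(0))
  m1 <- coh$measurements
  m2 <- m1
  m2$C_sweat <- 3 * m2$C_sweat
  r1 <- double_loop(m1, default_p, s0, default_d)
  r2 <- double_loop(m2, default_p, s0, default_d)
  expect_equal(r2$C_blood_hat, 3 * r1$C_blood_hat, tolerance = 1e-6)
})

test_that("measurement CSV round trip preserves records", {
  coh <- generate_cohort(cohort_spec(n_subjects = 3, seed = 5),
                         default_p, default_d)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_sweat_measurements(coh$measurements, tf)
  back <- read_sweat_measurements(tf)
  expect_equal(back$C_sweat, coh$measurements$C_sweat, tolerance = 1e-12)
  expect_identical(back$subject_id, coh$measurements$subject_id)
  expect_identical(back$condition, coh$measurements$condition)
})

test_that("measurement CSV validation rejects malformed input", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,condition,sweat_cortisol_nmol_l",
               "s1,pre_surgery,0.5"), tf)
  expect_error(read_sweat_measurements(tf), "missing column")
  writeLines(c(paste("subject_id,condition,sweat_cortisol_nmol_l,",
                     "sweat_velocity_norm", sep = ""),
               "s1,mid_surgery,0.5,1"), tf)
  expect_error(read_sweat_measurements(tf), "condition")
})
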