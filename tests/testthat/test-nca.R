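test_that("trapezoidal AUC matches hand-computed piecewise-linear areas", {
  expect_equal(auc_linear_trapezoid(c(0, 240), c(2, 2)), 480)
  expect_equal(auc_linear_trapezoid(c(0, 60, 120), c(10, 5, 0)), 600)
  # sub-window with interpolation at both bounds
  expect_equal(auc_linear_trapezoid(c(0, 60, 120), c(10, 5, 0), 30, 90),
               (7.5 + 5) / 2 * 30 + (5 + 2.5) / 2 * 30)
})

test_that("dense trapezoid AUC agrees with the analytic exponential integral", {
  k <- 0.01
  t <- seq(0, 240, by = 1)
  analytic <- (10 / k) * (1 - exp(-k * 240))
  est <- auc_linear_trapezoid(t, 10 * exp(-k * t))
  expect_lt(abs(est - analytic) / analytic, 1e-4)
})

test_that("AUC is additive at an interior sample time and scale-equivariant", {
  set.seed(5)
  for (rep in 1:10) {
    t <- sort(sample(0:300, 8))
    cc <- runif(8, 0.5, 12)
    a <- t[3]
    expect_equal(auc_linear_trapezoid(t, cc, t[1], a) +
                   auc_linear_trapezoid(t, cc, a, t[8]),
                 auc_linear_trapezoid(t, cc, t[1], t[8]))
    kf <- runif(1, 0.1, 10)
    expect_equal(auc_linear_trapezoid(t, kf * cc),
                 kf * auc_linear_trapezoid(t, cc))
  }
})

test_that("AUC window handling: anchoring rules and range errors", {
  t <- c(5, 15, 30, 60)
  cc <- c(8, 6, 4, 2)
  # carry-back anchor uses the first observed value at the window start
  expect_equal(auc_linear_trapezoid(t, cc, 0, 5), 8 * 5)
  expect_error(auc_linear_trapezoid(t, cc, 0, 5, anchor = "none"),
               class = "renalpk_out_of_range")
  expect_error(auc_linear_trapezoid(t, cc, 0, 100),
               class = "renalpk_out_of_range")
  expect_error(auc_linear_trapezoid(c(0), c(1)),
               class = "renalpk_insufficient_data")
  # log back-extrapolation reproduces the exact exponential C0
  tt <- c(10, 20, 40, 80)
  expo <- 5 * exp(-0.03 * tt)
  got <- auc_linear_trapezoid(tt, expo, 0, 10,
                              anchor = "log_backextrapolate")
  c0 <- 5
  expect_lt(abs(got - (c0 + expo[1]) / 2 * 10) / got, 1e-10)
})

test_that("lambda-z is exact on a noiseless exponential and rejects flat profiles", {
  t <- c(10, 30, 60, 120, 180, 240)
  fit <- fit_lambda_z(t, 8 * exp(-0.02 * t))
  expect_equal(fit$lambda_z, 0.02, tolerance = 1e-10)
  expect_error(fit_lambda_z(t, rep(3, 6)), class = "renalpk_no_valid_fit")
  expect_error(fit_lambda_z(c(0, 10, 20), c(0, 0, 0)),
               class = "renalpk_no_valid_fit")
})

test_that("lambda-z window selection isolates the terminal phase of a bi-exponential", {
  t <- seq(0, 600, by = 10)
  cc <- 5 * exp(-0.1 * t) + 1 * exp(-0.01 * t)
  fit <- fit_lambda_z(t, cc)
  # oracle: fit only beyond 5 half-lives of the fast phase (t > 34.7 min)
  keep <- t > 5 * log(2) / 0.1
  oracle <- -coef(lm(log(cc[keep]) ~ t[keep]))[[2]]
  expect_gt(fit$t_first, 5 * log(2) / 0.1)
  expect_lt(abs(fit$lambda_z - 0.01) / 0.01, 0.02)
  expect_lt(abs(fit$lambda_z - oracle) / oracle, 0.02)
  expect_named(tidy(fit),
               c("lambda_z", "intercept", "n_points", "adj_r2",
                 "t_first", "t_last"))
})

test_that("AUC extrapolation to infinity follows C_last / lambda_z", {
  t <- c(10, 30, 60, 120, 180, 240)
  fit <- fit_lambda_z(t, 8 * exp(-0.02 * t))
  expect_equal(auc_extrapolate_inf(100, 0, fit), 100)
  expect_equal(auc_extrapolate_inf(100, 1, fit), 100 + 1 / 0.02)
  # dense mono-exponential: AUC_inf within 0.1% of C0/k
  td <- seq(0, 400, by = 1)
  cd <- 12 * exp(-0.015 * td)
  auc_last <- auc_linear_trapezoid(td, cd)
  fit2 <- fit_lambda_z(td, cd)
  est <- auc_extrapolate_inf(auc_last, cd[length(cd)], fit2)
  expect_lt(abs(est - 12 / 0.015) / (12 / 0.015), 1e-3)
})

test_that("clearance formulas reproduce hand arithmetic and published desk checks", {
  expect_equal(cl_total(3, 300, 1000), 10) # 10 µmol/kg dose, AUC 1000
  expect_equal(cl_total(0, 300, 1000), 0)
  expect_error(cl_total(10, 300, 0), class = "renalpk_division_error")
  # cephalexin 10 mg/kg against the published AUC_inf group mean:
  # ratio-of-means lands within 3% of the printed per-animal mean 10.6
  expect_lt(abs(cl_total(10, 347.39, 2770) - 10.6) / 10.6, 0.03)

  expect_equal(cl_renal(10000, 1000), 10)
  expect_equal(cl_renal(0, 1000), 0)
  expect_error(cl_renal(10, 0), class = "renalpk_division_error")

  expect_equal(urinary_recovery(28787.9, 10, 347.39), 100, tolerance = 1e-4)
  expect_equal(urinary_recovery(0, 10, 347.39), 0)
  expect_error(urinary_recovery(10, 0, 347.39),
               class = "renalpk_undefined_recovery")

  expect_equal(kp_kidney(90, 10), 9)
  expect_equal(kp_kidney(5, 5), 1)
  expect_error(kp_kidney(5, 0), class = "renalpk_undefined_ratio")

  # clearances scale-invariance: conc in different units cancels
  expect_equal(cl_renal(3 * 10000, 3 * 1000), cl_renal(10000, 1000))
})

test_that("urine coverage gaps are detected and reported", {
  ur <- tibble::tibble(t_start_min = c(0, 60, 180), t_end_min = c(60, 120, 240),
                       amount_nmol_per_kg = c(5, 4, 3))
  expect_error(cumulative_urine(ur, c(0, 240)), "120.*180",
               class = "renalpk_coverage_error")
  expect_equal(cumulative_urine(ur, c(0, 120)), 9)
})

test_that("clearance ratio classifies net secretion vs reabsorption as published", {
  # published group means: CL_R, fu, inulin clearance -> printed ratios
  r <- clearance_ratio(c(7.96, 2.87, 1.88), c(0.82, 0.82, 0.82),
                       c(6.72, 5.36, 6.72))
  expect_equal(round(r$ratio, 2), c(1.44, 0.65, 0.34))
  expect_equal(r$classification,
               c("net-secretion", "net-reabsorption", "net-reabsorption"))
  expect_equal(clearance_ratio(5, 1, 5)$classification, "indeterminate")
  expect_equal(clearance_ratio(5.2, 1, 5, epsilon = 0)$classification,
               "net-secretion")
  expect_error(clearance_ratio(5, 0.82, 0), class = "renalpk_validation_error")
  expect_error(clearance_ratio(5, 1.2, 5), class = "renalpk_validation_error")
})

test_that("fold change reproduces the published fold-change rows", {
  expect_equal(round(fold_change(90.3, 16.6), 2), 5.44)
  expect_equal(round(fold_change(9807, 5373), 2), 1.83)
  expect_equal(fold_change(3.7, 3.7), 1)
  expect_error(fold_change(1, 0), class = "renalpk_validation_error")
})

test_that("run_nca_study recovers the simulator's noiseless ground truth", {
  ph <- phys_cephalexin()
  design <- study_design(10, sample_times = c(2, seq(10, 240, by = 10)))
  sim <- simulate_subject(ph, drug_cephalexin(), profile_control(), design,
                          subject_id = "s1")
  plasma <- dplyr::mutate(sim$plasma, group = "control")
  urine <- dplyr::mutate(sim$urine, group = "control")
  tissue <- dplyr::mutate(sim$tissue, group = "control")
  doses <- tibble::tibble(subject_id = "s1", analyte = "cephalexin",
                          dose_mg_per_kg = 10, mw_g_per_mol = 347.39)
  res <- run_nca_study(plasma, urine, tissue, doses,
                       fu = tibble::tibble(analyte = "cephalexin", fu = 0.82),
                       gfr = reference_inulin_clearance())
  s <- res$subjects
  expect_equal(s$auc_0_t, sim$truth$auc_window, tolerance = 0.02)
  expect_equal(s$cl_r, sim$truth$cl_r, tolerance = 0.02)
  expect_equal(s$cl_tot, sim$truth$cl_tot, tolerance = 0.05)
  expect_equal(s$kp_kidney, sim$truth$kp_kidney, tolerance = 1e-6)
  expect_equal(s$classification, "net-secretion")
})

test_that("run_nca_study honours partial inputs and equal groups", {
  ph <- phys_cephalexin()
  sim <- simulate_subject(ph, drug_cephalexin(), profile_control(),
                          study_design(10), subject_id = "s1")
  plasma <- dplyr::mutate(sim$plasma, group = "control")
  doses <- tibble::tibble(subject_id = "s1", analyte = "cephalexin",
                          dose_mg_per_kg = 10, mw_g_per_mol = 347.39)
  fu <- tibble::tibble(analyte = "cephalexin", fu = 0.82)
  gfr <- reference_inulin_clearance()
  # no urine: AUC-based parameters still produced, CL_R absent
  res <- run_nca_study(plasma, urine = NULL, doses = doses, fu = fu, gfr = gfr)
  expect_true(is.finite(res$subjects$auc_0_t))
  expect_true(is.finite(res$subjects$cl_tot))
  expect_true(is.na(res$subjects$cl_r))
  # missing fu configuration errors out
  expect_error(run_nca_study(plasma, fu = tibble::tibble(analyte = "x", fu = 1),
                             gfr = gfr),
               class = "renalpk_configuration_error")
  # two identical groups: every fold change is 1
  pl2 <- dplyr::bind_rows(plasma,
                          dplyr::mutate(plasma, group = "hyperuricemia",
                                        subject_id = "s2"))
  d2 <- dplyr::bind_rows(doses, dplyr::mutate(doses, subject_id = "s2"))
  res2 <- run_nca_study(pl2, doses = d2, fu = fu, gfr = gfr)
  fc <- res2$fold_changes$fold_hyperuricemia
  expect_equal(fc[is.finite(fc)], rep(1, sum(is.finite(fc))))
  expect_s3_class(tidy(res2), "tbl_df")
  expect_true("fold_hyperuricemia" %in% names(glance(res2)))
})
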