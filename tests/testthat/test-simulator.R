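test_that("parameter constructors validate their invariants", {
  expect_error(physiology_params(gfr = 30, q_renal = 23),
               class = "renalpk_validation_error")
  expect_error(physiology_params(v_central = -1),
               class = "renalpk_validation_error")
  expect_error(drug_params(mw = 300, fu = 0), class = "renalpk_validation_error")
  expect_error(drug_params(mw = 300, fu = 0.5, vmax_uptake = 10, km_uptake = 0),
               class = "renalpk_validation_error")
  expect_error(transporter_profile(uptake = -0.1),
               class = "renalpk_validation_error")
  expect_error(study_design(10, sample_times = c(10, 5)),
               class = "renalpk_validation_error")
  expect_error(study_design(10, urine_intervals = list(c(0, 120), c(60, 240))),
               class = "renalpk_validation_error")
  expect_error(study_design(10, n_per_group = 0),
               class = "renalpk_validation_error")
})

test_that("closed-form peritubular balance agrees with bisection on random regimes", {
  set.seed(42)
  ph <- physiology_params()
  for (i in 1:25) {
    dr <- drug_params(mw = 300, fu = runif(1, 0.1, 1),
                      ps_passive = runif(1, 0, 2),
                      vmax_uptake = runif(1, 0, 5e4),
                      km_uptake = runif(1, 10, 5000))
    cp <- runif(1, 0, 300)
    ccell <- runif(1, 0, 5000)
    a <- renalpk:::solve_c_local(cp, ccell, ph, dr, 1)
    b <- renalpk:::solve_c_local_bisect(cp, ccell, ph, dr, 1, tol = 1e-12)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("an empty system stays empty", {
  s <- simulate_subject(physiology_params(), drug_params(mw = 300, fu = 0.5),
                        profile_control(), study_design(0))
  expect_true(all(abs(as.matrix(s$trajectory[, -1])) < 1e-12))
  expect_true(all(s$plasma$conc_uM == 0))
})

test_that("filtration-only subject has CL_R = fu * GFR (inulin-like limit)", {
  # no carriers, no passive exchange, no non-renal elimination; elimination
  # completes well inside the window so the luminal washout lag is negligible
  ph <- physiology_params(v_central = 300)
  dr <- drug_params(name = "marker", mw = 5000, fu = 0.7)
  s <- simulate_subject(ph, dr, profile_control(), study_design(50))
  expect_lt(abs(s$truth$cl_r - 0.7 * ph$gfr) / (0.7 * ph$gfr), 0.02)
  # clearance ratio = 1 within 2%
  expect_lt(abs((s$truth$cl_r / 0.7) / ph$gfr - 1), 0.02)
})

test_that("linear secretion matches the well-stirred closed form and its flow cap", {
  ph <- physiology_params(v_central = 300)
  # fast apical efflux, linear uptake regime (Km >> local concentrations)
  clints <- c(5, 50, 500, 5000)
  for (clint in clints) {
    dr <- drug_params(mw = 300, fu = 0.8, vmax_uptake = clint * 1e4,
                      km_uptake = 1e4, vmax_efflux = 1e6, km_efflux = 100)
    s <- simulate_subject(ph, dr, profile_control(), study_design(5))
    tr <- s$trajectory
    long <- renalpk:::integrate_model(
      c(s$dose_nmol_per_kg, rep(0, 6)), seq(0, 20000, by = 100),
      ph, dr, profile_control())
    cl_inf <- long$a_urine[nrow(long)] / long$auc_plasma[nrow(long)]
    expect_lt(abs(cl_inf - oracle_well_stirred_cl(23, 0.8, clint, ph$gfr)) /
                oracle_well_stirred_cl(23, 0.8, clint, ph$gfr), 0.01)
  }
  # huge intrinsic clearance: renal clearance approaches, never exceeds,
  # the unbound perfusion limit fu * Q
  dr <- drug_params(mw = 300, fu = 0.8, vmax_uptake = 5e7, km_uptake = 1e4,
                    vmax_efflux = 1e6, km_efflux = 100)
  s <- simulate_subject(ph, dr, profile_control(), study_design(5))
  expect_lte(s$truth$cl_r, 0.8 * 23 * (1 + 1e-6))
  expect_gt(s$truth$cl_r, 0.9 * 0.8 * 23)
})

test_that("mass balance closes to 1e-6 across a parameter grid", {
  grid <- list(
    list(ph = phys_metformin(), dr = drug_metformin()),
    list(ph = phys_cephalexin(), dr = drug_cephalexin()),
    list(ph = phys_creatinine(), dr = drug_creatinine()))
  thetas <- list(profile_control(), profile_hyperuricemic(),
                 transporter_profile(0.5, 0.5, 1),
                 transporter_profile(1, 0.3, 1),
                 transporter_profile(0.3, 1, 0.6),
                 transporter_profile(0.8, 1, 0.2),
                 transporter_profile(1, 1, 0))
  n_checked <- 0
  for (cfg in grid) {
    dose <- if (cfg$dr$synthesis_rate > 0) 0 else 10
    for (th in thetas) {
      s <- simulate_subject(cfg$ph, cfg$dr, th, study_design(dose))
      expect_lt(max(abs(mass_balance_error(s))), 1e-6)
      # study-condition flow cap: CL_R below the unbound perfusion limit
      if (is.finite(s$truth$cl_r)) {
        expect_lte(s$truth$cl_r, cfg$dr$fu * cfg$ph$q_renal * (1 + 1e-6))
      }
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})

test_that("CL_R falls and Kp rises monotonically as apical efflux is lost", {
  ph <- phys_metformin()
  thetas <- c(1, 0.8, 0.6, 0.4)
  res <- t(vapply(thetas, function(te) {
    s <- simulate_subject(ph, drug_metformin(),
                          transporter_profile(efflux = te), study_design(30))
    c(s$truth$cl_r, s$truth$kp_kidney)
  }, c(0, 0)))
  expect_true(all(diff(res[, 1]) <= 0)) # CL_R non-increasing
  expect_true(all(diff(res[, 2]) >= 0)) # Kp non-decreasing
})

test_that("saturable reabsorption makes the clearance ratio rise with dose and cross 1", {
  ph <- phys_cephalexin()
  doses <- c(0.3, 1, 3, 10)
  ratios <- vapply(doses, function(d) {
    s <- simulate_subject(ph, drug_cephalexin(), profile_control(),
                          study_design(d))
    (s$truth$cl_r / drug_cephalexin()$fu) / ph$gfr
  }, 0)
  expect_true(all(diff(ratios) > 0))
  expect_lt(ratios[doses == 1], 1)
  expect_gt(ratios[doses == 10], 1)
})

test_that("an endogenous analyte starts at steady state and stays there", {
  s <- simulate_subject(phys_creatinine(), drug_creatinine(),
                        profile_control(), study_design(0))
  cp <- s$trajectory$a_central / phys_creatinine()$v_central
  expect_lt(diff(range(cp)) / mean(cp), 0.001) # invariant over 240 min
  expect_true(is.na(s$truth$cl_tot)) # no dose: no AUC_inf-based clearance
  expect_gt(s$truth$cl_r, 0)
})

test_that("simulate_study is reproducible, respects noise-off, and keeps subjects stable", {
  ph <- phys_cephalexin()
  d <- study_design(10, n_per_group = 2, seed = 99)
  a <- simulate_study(ph, drug_cephalexin(), design = d)
  b <- simulate_study(ph, drug_cephalexin(), design = d)
  expect_identical(a, b)

  # noise off: every subject equals the noiseless single-subject run
  d0 <- study_design(10, n_per_group = 2, bsv_cv = 0, residual_cv = 0, seed = 1)
  st <- simulate_study(ph, drug_cephalexin(), design = d0)
  ref <- simulate_subject(ph, drug_cephalexin(), profile_control(), d0)
  for (sid in unique(st$plasma$subject_id[st$plasma$group == "control"])) {
    expect_equal(st$plasma$conc_uM[st$plasma$subject_id == sid],
                 ref$plasma$conc_uM)
  }

  # enlarging the cohort preserves the earlier subjects' records
  d3 <- study_design(10, n_per_group = 3, seed = 99)
  big <- simulate_study(ph, drug_cephalexin(), design = d3)
  small_ids <- unique(a$plasma$subject_id[a$plasma$group == "control"])
  expect_equal(dplyr::filter(big$plasma, .data$subject_id %in% small_ids,
                             .data$group == "control"),
               dplyr::filter(a$plasma, .data$group == "control"))
  expect_error(simulate_study(ph, drug_cephalexin(),
                              design = study_design(10, n_per_group = 0)),
               class = "renalpk_validation_error")
})

test_that("urine amounts are non-negative so cumulative excretion is monotone", {
  st <- simulate_study(phys_cephalexin(), drug_cephalexin(),
                       design = study_design(10, n_per_group = 3, seed = 5))
  expect_true(all(st$urine$amount_nmol_per_kg >= 0))
  cum <- st$urine |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = !is.unsorted(cumsum(.data$amount_nmol_per_kg)))
  expect_true(all(cum$ok))
})
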