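# Mechanistic kidney model.
#
# Compartments (amounts, nmol/kg): central plasma, tubular cell, tubular
# lumen, urine; two bookkeeping integrals (non-renal elimination, cumulative
# synthesis) close the mass balance, and a third accumulates the plasma
# concentration integral (exact AUC for ground truth).
#
# Glomerular filtration acts on systemic plasma (fu GFR C_p): the
# glomerulus sits upstream of the peritubular capillary bed, which is why a
# freely filtered marker (inulin) has renal clearance exactly equal to GFR.
# Tubular secretion draws on the post-glomerular plasma flow Q' = Q - GFR
# (the filtration fraction has already left) and, with restrictive protein
# binding, only on the unbound drug it carries. The peritubular site is not
# a compartment: its local unbound concentration u is eliminated
# algebraically at every step from the flow balance
#   Q' (fu C_p - u) = J_up(u) - PS C_cell,
#   J_up(u) = theta Vmax u / (Km + u) + PS u
# so secretory extraction is capped at Q' fu C_p and total renal clearance
# at fu GFR + fu Q' = fu Q, for any carrier capacity. With a single
# Michaelis-Menten uptake term the balance is a quadratic in u solved in
# closed form (stable root), so the ODE right-hand side is iteration-free.

# Closed-form solution of the peritubular flow balance. Returns the local
# unbound concentration u >= 0.
solve_c_local <- function(cp, ccell, phys, drug, theta_uptake) {
  q_eff <- phys$q_renal - phys$gfr
  ps <- drug$ps_passive
  vmax <- theta_uptake * drug$vmax_uptake
  km <- drug$km_uptake
  a <- q_eff + ps
  b <- q_eff * drug$fu * cp + ps * ccell
  if (b <= 0 || a <= 0) return(0)
  if (vmax <= 0) return(b / a)
  # a*u^2 + (a*km + vmax - b)*u - b*km = 0; roots have opposite signs
  # (product -b*km/a < 0); take the positive one stably.
  qb <- a * km + vmax - b
  qc <- -b * km
  disc <- sqrt(qb * qb - 4 * a * qc)
  if (qb >= 0) 2 * qc / (-qb - disc) else (-qb + disc) / (2 * a)
}

# Same balance solved by bisection; used in tests to validate the algebra.
solve_c_local_bisect <- function(cp, ccell, phys, drug, theta_uptake,
                                 tol = 1e-10) {
  q_eff <- phys$q_renal - phys$gfr
  ps <- drug$ps_passive
  f <- function(u) {
    j_up <- theta_uptake * drug$vmax_uptake * u / (drug$km_uptake + u) +
      ps * u
    q_eff * (drug$fu * cp - u) - j_up + ps * ccell
  }
  lo <- 0
  hi <- drug$fu * cp + ps * ccell / max(q_eff, 1e-12) + 1e-12
  if (f(lo) <= 0) return(0)
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Instantaneous fluxes at a state. Amounts may carry tiny negative
# integrator noise; concentrations are clamped at zero for flux evaluation.
model_fluxes <- function(y, phys, drug, theta) {
  cp <- max(y[[1]], 0) / phys$v_central
  ccell <- max(y[[2]], 0) / phys$v_kidney
  clum <- max(y[[3]], 0) / phys$v_lumen
  u <- solve_c_local(cp, ccell, phys, drug, theta$uptake)
  list(
    cp = cp, ccell = ccell, clum = clum, u_local = u,
    j_filt = drug$fu * phys$gfr * cp,
    j_up = theta$uptake * drug$vmax_uptake * u / (drug$km_uptake + u) +
      drug$ps_passive * u,
    j_back = drug$ps_passive * ccell,
    j_eff = theta$efflux * drug$vmax_efflux * ccell / (drug$km_efflux + ccell),
    j_reab = theta$reab * drug$vmax_reab * clum / (drug$km_reab + clum),
    j_urine = phys$urine_flow_k * max(y[[3]], 0),
    # secretory (peritubular) extraction; filtration is accounted separately
    extraction_sec = (phys$q_renal - phys$gfr) * (drug$fu * cp - u)
  )
}

model_rhs <- function(t, y, parms) {
  phys <- parms$phys
  drug <- parms$drug
  fl <- model_fluxes(y, phys, drug, parms$theta)
  d_central <- drug$synthesis_rate - drug$cl_nonrenal * fl$cp -
    fl$j_filt - fl$extraction_sec + fl$j_reab
  d_cell <- fl$j_up - fl$j_back - fl$j_eff
  d_lumen <- fl$j_filt + fl$j_eff - fl$j_reab - fl$j_urine
  d_urine <- fl$j_urine
  d_nonrenal <- drug$cl_nonrenal * fl$cp
  d_synth <- drug$synthesis_rate
  d_aucp <- fl$cp
  list(c(d_central, d_cell, d_lumen, d_urine, d_nonrenal, d_synth, d_aucp))
}

state_names <- c("a_central", "a_cell", "a_lumen", "a_urine",
                 "a_nonrenal", "a_synth", "auc_plasma")

integrate_model <- function(y0, times, phys, drug, theta,
                            rtol = 1e-8, atol = 1e-10) {
  names(y0) <- state_names
  out <- deSolve::ode(y = y0, times = times, func = model_rhs,
                      parms = list(phys = phys, drug = drug, theta = theta),
                      method = "vode", rtol = rtol, atol = atol)
  m <- unclass(out)
  if (anyNA(m) || any(!is.finite(m))) {
    abort(paste0("integration produced non-finite states for drug '",
                 drug$name, "'; check the Vmax/Km parameter regime."),
          class = "renalpk_integration_error")
  }
  neg_tol <- -1e-6 * max(abs(m[, -1L]), 1)
  if (any(m[, -1L] < neg_tol)) {
    abort(paste0("integration produced negative amounts for drug '",
                 drug$name, "'; check the parameter regime."),
          class = "renalpk_integration_error")
  }
  tibble::as_tibble(as.data.frame(m))
}

# Steady state of an endogenous analyte: integrate the synthesis-driven
# system from empty until the plasma concentration is stationary. The
# approach is exponential with the system's slowest washout time, so a long
# horizon with a stiff solver is cheap and robust.
endogenous_steady_state <- function(phys, drug, theta, t_equil = 30000) {
  traj <- integrate_model(rep(0, 7), c(0, t_equil * 0.9, t_equil),
                          phys, drug, theta)
  last <- as.numeric(traj[nrow(traj), paste0("a_", c("central", "cell", "lumen"))])
  prev <- as.numeric(traj[nrow(traj) - 1L, "a_central"])
  if (abs(last[1] - prev) > 1e-6 * max(last[1], 1)) {
    warn("endogenous pre-equilibration may not have fully converged; consider a larger `t_equil`.")
  }
  c(last, 0, 0, 0, 0)
}

#' Simulate one subject of a renal transport study (noiseless)
#'
#' Integrates the plasma / tubular-cell / lumen / urine model for one animal
#' and samples it according to the study design: plasma concentrations at
#' `design$sample_times`, urinary amounts per collection interval, and the
#' kidney tissue concentration at `design$tissue_time`. No between-subject
#' or residual variability is applied; see [simulate_study()] for the noisy
#' two-arm wrapper.
#'
#' For a dosed drug the IV bolus `dose_mg_per_kg * 1000 / mw` µmol/kg is
#' placed in the central compartment at time 0. For an endogenous analyte
#' (`synthesis_rate > 0`, dose 0) the initial state is the model steady
#' state, so the sampled plasma concentration is the time-invariant baseline.
#'
#' @param phys A [physiology_params()] object.
#' @param drug A [drug_params()] object.
#' @param theta A [transporter_profile()] object.
#' @param design A [study_design()] object.
#' @param subject_id Label attached to the sampled records.
#'
#' @return A list of class `subject_sim` with elements
#'   `trajectory` (tibble of compartment amounts over a dense time grid,
#'   plus the running plasma-concentration integral `auc_plasma`),
#'   `plasma`, `urine`, `tissue` (sampled record tibbles), and
#'   `truth` (one-row tibble of noiseless reference quantities:
#'   `cl_tot`, `cl_r`, `kp_kidney`, `auc_window`, `auc_inf`, window bounds).
#'   Mass balance (dose + synthesized = stored + excreted + eliminated) holds
#'   to integrator tolerance; `mass_balance_error()` retrieves the relative
#'   defect.
#' @examples
#' s <- simulate_subject(physiology_params(), drug_cephalexin(),
#'                       profile_control(), study_design(10))
#' s$truth
#' @export
simulate_subject <- function(phys, drug, theta, design, subject_id = "s1") {
  stopifnot(inherits(phys, "physiology_params"),
            inherits(drug, "drug_params"),
            inherits(theta, "transporter_profile"),
            inherits(design, "study_design"))
  dose_nmol <- design$dose_mg_per_kg * 1e6 / drug$mw
  window <- c(0, max(vapply(design$urine_intervals, max, 0)))

  y0 <- rep(0, 7)
  if (drug$synthesis_rate > 0 && dose_nmol == 0) {
    y0 <- endogenous_steady_state(phys, drug, theta)
  }
  y0[1] <- y0[1] + dose_nmol

  t_grid <- sort(unique(c(seq(0, max(design$tissue_time, window[2]), by = 2),
                          design$sample_times, design$tissue_time,
                          unlist(design$urine_intervals))))
  traj <- integrate_model(y0, t_grid, phys, drug, theta)

  at <- function(tt, col) {
    # grid contains all sampling times exactly
    traj[[col]][match(tt, traj$time)]
  }
  plasma <- tibble::tibble(
    subject_id = subject_id, analyte = drug$name,
    time_min = design$sample_times,
    conc_uM = at(design$sample_times, "a_central") / phys$v_central)
  urine <- tibble::tibble(
    subject_id = subject_id, analyte = drug$name,
    t_start_min = vapply(design$urine_intervals, `[`, 0, 1L),
    t_end_min = vapply(design$urine_intervals, `[`, 0, 2L))
  urine$amount_nmol_per_kg <- at(urine$t_end_min, "a_urine") -
    at(urine$t_start_min, "a_urine")
  tissue <- tibble::tibble(
    subject_id = subject_id, analyte = drug$name,
    time_min = design$tissue_time,
    conc_uM = at(design$tissue_time, "a_cell") / phys$v_kidney)

  # Noiseless reference quantities. AUC_inf and total urinary output come
  # from a long-horizon integration (exact plasma AUC as a state).
  auc_window <- at(window[2], "auc_plasma") - at(window[1], "auc_plasma")
  x_urine_window <- at(window[2], "a_urine") - at(window[1], "a_urine")
  cl_r_true <- if (auc_window > 0) x_urine_window / auc_window else NA_real_
  cl_tot_true <- NA_real_
  auc_inf <- NA_real_
  if (dose_nmol > 0 && drug$synthesis_rate == 0) {
    long <- integrate_model(y0, seq(0, 20000, by = 100), phys, drug, theta)
    auc_inf <- long$auc_plasma[nrow(long)]
    cl_tot_true <- dose_nmol / auc_inf
  }
  cp_tissue_time <- at(design$tissue_time, "a_central") / phys$v_central
  truth <- tibble::tibble(
    subject_id = subject_id, analyte = drug$name,
    dose_nmol_per_kg = dose_nmol,
    auc_window = auc_window, auc_inf = auc_inf,
    cl_tot = cl_tot_true, cl_r = cl_r_true,
    kp_kidney = if (cp_tissue_time > 0) tissue$conc_uM / cp_tissue_time else NA_real_,
    window_start = window[1], window_end = window[2])

  structure(list(trajectory = traj, plasma = plasma, urine = urine,
                 tissue = tissue, truth = truth,
                 dose_nmol_per_kg = dose_nmol,
                 phys = phys, drug = drug, theta = theta, design = design),
            class = "subject_sim")
}

#' Relative mass-balance defect of a simulated subject
#'
#' dose + cumulative synthesis minus everything stored, excreted or
#' eliminated, relative to total input, at every stored time point.
#'
#' @param sim A `subject_sim` from [simulate_subject()].
#' @return Numeric vector of relative defects along the trajectory.
#' @export
mass_balance_error <- function(sim) {
  stopifnot(inherits(sim, "subject_sim"))
  tr <- sim$trajectory
  input <- sim$dose_nmol_per_kg + tr$a_synth +
    (tr$a_central[1] + tr$a_cell[1] + tr$a_lumen[1] - sim$dose_nmol_per_kg)
  stored <- tr$a_central + tr$a_cell + tr$a_lumen + tr$a_urine + tr$a_nonrenal
  (stored - input) / pmax(abs(input), 1e-9)
}

# documented counter scheme for per-subject seeds: substream i of master m
# is m + 1000003 * i (mod 2^31 - 1), so adding subjects never reshuffles
# earlier ones.
subject_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * i) %% (2^31 - 1))
}

lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

perturb_drug <- function(drug, cv) {
  f <- lnorm_factor(4, cv)
  drug$vmax_uptake <- drug$vmax_uptake * f[1]
  drug$vmax_efflux <- drug$vmax_efflux * f[2]
  drug$vmax_reab <- drug$vmax_reab * f[3]
  drug$cl_nonrenal <- drug$cl_nonrenal * f[4]
  drug
}

#' Simulate a two-arm renal transport study
#'
#' Runs [simulate_subject()] for `design$n_per_group` animals per arm.
#' Between-subject variability is applied as lognormal perturbation of the
#' carrier Vmax values and non-renal clearance (volumes and flows are fixed,
#' keeping the flow cap interpretable); residual assay noise is applied
#' multiplicatively to every sampled observation. Per-subject RNG substreams
#' are derived from `design$seed` by a fixed counter scheme, so the same seed
#' reproduces the study byte for byte and enlarging `n_per_group` leaves
#' earlier subjects unchanged.
#'
#' @inheritParams simulate_subject
#' @param theta_control,theta_case [transporter_profile()] objects for the
#'   control and case arm.
#' @param groups Length-2 character vector of arm labels.
#'
#' @return A list of class `simulated_study` with tibbles `plasma`
#'   (subject_id, group, analyte, time_min, conc_uM), `urine`, `tissue`,
#'   and `true_params` (per-subject noiseless reference parameters and the
#'   perturbed Vmax values, for recovery testing).
#' @examples
#' st <- simulate_study(physiology_params(), drug_cephalexin(),
#'                      design = study_design(10, n_per_group = 2, seed = 7))
#' dplyr::count(st$plasma, group)
#' @export
simulate_study <- function(phys, drug, theta_control = profile_control(),
                           theta_case = profile_hyperuricemic(),
                           design = study_design(10),
                           groups = c("control", "hyperuricemia")) {
  stopifnot(inherits(design, "study_design"))
  if (design$n_per_group < 1L) {
    abort("`n_per_group` must be >= 1.", class = "renalpk_validation_error")
  }
  arms <- list(theta_control, theta_case)
  names(arms) <- groups
  plasma <- urine <- tissue <- truth <- list()
  counter <- 0L
  for (g in seq_along(arms)) {
    for (i in seq_len(design$n_per_group)) {
      counter <- counter + 1L
      sid <- sprintf("%s_%02d", substr(groups[g], 1, 3), i)
      seed_i <- subject_seed(design$seed, counter)
      set.seed(seed_i)
      drug_i <- perturb_drug(drug, design$bsv_cv)
      sim <- simulate_subject(phys, drug_i, arms[[g]], design, subject_id = sid)
      pl <- sim$plasma
      pl$conc_uM <- pl$conc_uM * lnorm_factor(nrow(pl), design$residual_cv)
      ur <- sim$urine
      ur$amount_nmol_per_kg <- ur$amount_nmol_per_kg *
        lnorm_factor(nrow(ur), design$residual_cv)
      ti <- sim$tissue
      ti$conc_uM <- ti$conc_uM * lnorm_factor(nrow(ti), design$residual_cv)
      tru <- sim$truth
      tru$group <- groups[g]
      tru$vmax_uptake <- drug_i$vmax_uptake
      tru$vmax_efflux <- drug_i$vmax_efflux
      tru$vmax_reab <- drug_i$vmax_reab
      tru$cl_nonrenal <- drug_i$cl_nonrenal
      pl$group <- ur$group <- ti$group <- groups[g]
      plasma[[counter]] <- pl
      urine[[counter]] <- ur
      tissue[[counter]] <- ti
      truth[[counter]] <- tru
    }
  }
  col_order <- function(df) {
    dplyr::relocate(df, "subject_id", "group", "analyte")
  }
  structure(list(plasma = col_order(dplyr::bind_rows(plasma)),
                 urine = col_order(dplyr::bind_rows(urine)),
                 tissue = col_order(dplyr::bind_rows(tissue)),
                 true_params = col_order(dplyr::bind_rows(truth)),
                 design = design, groups = groups),
            class = "simulated_study")
}

#' @export
print.subject_sim <- function(x, ...) {
  cat(sprintf("<subject_sim> %s, dose %.4g nmol/kg\n",
              x$drug$name, x$dose_nmol_per_kg))
  cat(sprintf("  truth: CL_tot %.4g, CL_R %.4g mL/min/kg, Kp %.4g\n",
              x$truth$cl_tot, x$truth$cl_r, x$truth$kp_kidney))
  invisible(x)
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %s, %d subjects/arm (%s)\n",
              x$plasma$analyte[1], x$design$n_per_group,
              paste(x$groups, collapse = " vs ")))
  invisible(x)
}
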