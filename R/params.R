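#' Renal physiology parameters
#'
#' Bundles the physiological constants of the kidney model. Volumes and flows
#' are expressed per kg body weight so that simulated amounts are in nmol/kg
#' and concentrations (amount / volume) come out in nmol/mL = µM.
#'
#' @param gfr Glomerular filtration rate, mL/min/kg. The default is the
#'   control-arm inulin clearance of an adult rat (6.72 mL/min/kg).
#' @param q_renal Effective renal plasma flow perfusing the tubular exchange
#'   site, mL/min/kg (default 23, the rat renal flow that caps a
#'   flow-limited clearance).
#' @param v_central Central (plasma + rapidly equilibrating) distribution
#'   volume, mL/kg.
#' @param v_kidney Kidney tissue volume, mL/kg (about 8 g of kidney per kg
#'   body weight, taking unit tissue density).
#' @param v_lumen Tubular luminal volume, mL/kg.
#' @param urine_flow_k First-order lumen-to-urine washout rate constant,
#'   1/min. `urine_flow_k * v_lumen` is the equivalent urine flow (mL/min/kg).
#'
#' @return An object of class `physiology_params` (a validated named list).
#' @examples
#' physiology_params()
#' physiology_params(gfr = 5.36) # reduced-filtration arm
#' @export
physiology_params <- function(gfr = 6.72, q_renal = 23, v_central = 1000,
                              v_kidney = 8, v_lumen = 2, urine_flow_k = 0.05) {
  p <- list(gfr = gfr, q_renal = q_renal, v_central = v_central,
            v_kidney = v_kidney, v_lumen = v_lumen, urine_flow_k = urine_flow_k)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single finite positive number.", nm),
            class = "renalpk_validation_error")
    }
  }
  if (gfr > q_renal) {
    abort("`gfr` cannot exceed `q_renal`: filtration is a fraction of renal plasma flow.",
          class = "renalpk_validation_error")
  }
  structure(p, class = "physiology_params")
}

#' Drug-specific parameters of the tubular transport model
#'
#' Describes one analyte: its physicochemistry (`mw`, `fu`), systemic
#' elimination outside the kidney, passive permeability across the
#' basolateral membrane, and the three saturable carriers of the model
#' (basolateral uptake, apical efflux, luminal reabsorption), each a
#' Michaelis-Menten pair. Endogenous analytes (creatinine) carry a zero-order
#' `synthesis_rate` instead of a dose.
#'
#' @param name Analyte label used in simulated records.
#' @param mw Molecular weight, g/mol.
#' @param fu Unbound fraction in plasma, in (0, 1]. Only unbound drug is
#'   filtered and presented to the uptake carrier.
#' @param cl_nonrenal Non-renal clearance, mL/min/kg.
#' @param ps_passive Bidirectional passive permeability-surface product
#'   between peritubular plasma and tubular cell, mL/min/kg.
#' @param vmax_uptake,km_uptake Basolateral uptake carrier (Oct2/Oat1-like):
#'   maximum rate nmol/min/kg and Michaelis constant µM.
#' @param vmax_efflux,km_efflux Apical efflux carrier (Mate1-like), same units.
#' @param vmax_reab,km_reab Luminal reabsorption carrier (Pept-like), same
#'   units; reabsorbed drug returns to the central compartment.
#' @param synthesis_rate Zero-order endogenous production, nmol/min/kg
#'   (0 for dosed drugs).
#'
#' @return An object of class `drug_params`.
#' @seealso [drug_metformin()], [drug_cephalexin()], [drug_creatinine()] for
#'   ready-made parameterizations.
#' @export
drug_params <- function(name = "drug", mw, fu, cl_nonrenal = 0, ps_passive = 0,
                        vmax_uptake = 0, km_uptake = 1,
                        vmax_efflux = 0, km_efflux = 1,
                        vmax_reab = 0, km_reab = 1,
                        synthesis_rate = 0) {
  p <- list(name = name, mw = mw, fu = fu, cl_nonrenal = cl_nonrenal,
            ps_passive = ps_passive,
            vmax_uptake = vmax_uptake, km_uptake = km_uptake,
            vmax_efflux = vmax_efflux, km_efflux = km_efflux,
            vmax_reab = vmax_reab, km_reab = km_reab,
            synthesis_rate = synthesis_rate)
  num <- p[setdiff(names(p), "name")]
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "renalpk_validation_error")
    }
  }
  if (mw <= 0) abort("`mw` must be positive.", class = "renalpk_validation_error")
  if (fu <= 0 || fu > 1) {
    abort("`fu` must lie in (0, 1].", class = "renalpk_validation_error")
  }
  rates <- c("cl_nonrenal", "ps_passive", "vmax_uptake", "vmax_efflux",
             "vmax_reab", "synthesis_rate")
  for (nm in rates) {
    if (p[[nm]] < 0) {
      abort(sprintf("`%s` must be non-negative.", nm),
            class = "renalpk_validation_error")
    }
  }
  for (carrier in c("uptake", "efflux", "reab")) {
    vmax <- p[[paste0("vmax_", carrier)]]
    km <- p[[paste0("km_", carrier)]]
    if (vmax > 0 && km <= 0) {
      abort(sprintf("`km_%s` must be positive when `vmax_%s` > 0.",
                    carrier, carrier),
            class = "renalpk_validation_error")
    }
  }
  structure(p, class = "drug_params")
}

#' Transporter expression scaling
#'
#' Multiplicative scaling of the three carrier Vmax values, expressing
#' altered transporter abundance relative to a control animal (1 = control).
#' A hyperuricemic arm is modelled by factors below 1, e.g. apical efflux at
#' 0.607 to mirror the measured Mate1 protein reduction.
#'
#' @param uptake,efflux,reab Non-negative scaling factors applied to
#'   `vmax_uptake`, `vmax_efflux` and `vmax_reab` respectively.
#' @return An object of class `transporter_profile`.
#' @examples
#' profile_control()
#' profile_hyperuricemic()
#' @export
transporter_profile <- function(uptake = 1, efflux = 1, reab = 1) {
  p <- list(uptake = uptake, efflux = efflux, reab = reab)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(sprintf("`%s` must be a single finite non-negative number.", nm),
            class = "renalpk_validation_error")
    }
  }
  structure(p, class = "transporter_profile")
}

#' @rdname transporter_profile
#' @export
profile_control <- function() transporter_profile(1, 1, 1)

#' @rdname transporter_profile
#' @details `profile_hyperuricemic()` encodes the measured downregulation:
#'   apical efflux (Mate1) at 0.607 of control, basolateral uptake
#'   (Oct2/Oat1) at 0.7, luminal reabsorption (Pept) at 0.8.
#' @export
profile_hyperuricemic <- function() transporter_profile(0.7, 0.607, 0.8)

#' Study design for a simulated two-arm pharmacokinetic experiment
#'
#' @param dose_mg_per_kg IV bolus dose, mg/kg (0 for endogenous analytes).
#' @param sample_times Plasma sampling times, min, strictly increasing and
#'   non-negative.
#' @param urine_intervals List of `c(start, end)` urine collection intervals
#'   in min; must be non-overlapping. The default covers 0-240 min in four
#'   intervals.
#' @param tissue_time Terminal kidney sampling time, min (default 240).
#' @param n_per_group Animals per arm (default 3, as in a typical small
#'   rodent PK study; raise it for statistical property checks).
#' @param bsv_cv Between-subject lognormal coefficient of variation applied
#'   to carrier Vmax values and non-renal clearance.
#' @param residual_cv Multiplicative lognormal assay CV applied to sampled
#'   observations.
#' @param seed Master RNG seed for [simulate_study()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(dose_mg_per_kg,
                         sample_times = c(5, 15, 30, 60, 120, 180, 240),
                         urine_intervals = list(c(0, 60), c(60, 120),
                                                c(120, 180), c(180, 240)),
                         tissue_time = 240,
                         n_per_group = 3,
                         bsv_cv = 0.2,
                         residual_cv = 0.1,
                         seed = 1L) {
  if (!is.numeric(dose_mg_per_kg) || length(dose_mg_per_kg) != 1L ||
      !is.finite(dose_mg_per_kg) || dose_mg_per_kg < 0) {
    abort("`dose_mg_per_kg` must be a single non-negative number.",
          class = "renalpk_validation_error")
  }
  if (length(sample_times) < 2L || any(sample_times < 0) ||
      any(diff(sample_times) <= 0)) {
    abort("`sample_times` must be >= 0 and strictly increasing.",
          class = "renalpk_validation_error")
  }
  iv <- do.call(rbind, lapply(urine_intervals, function(x) {
    if (length(x) != 2L || x[2] <= x[1] || x[1] < 0) {
      abort("each urine interval must be c(start, end) with 0 <= start < end.",
            class = "renalpk_validation_error")
    }
    x
  }))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2] - 1e-9)) {
    abort("urine intervals must not overlap.", class = "renalpk_validation_error")
  }
  if (n_per_group < 1) {
    abort("`n_per_group` must be >= 1.", class = "renalpk_validation_error")
  }
  if (bsv_cv < 0 || residual_cv < 0) {
    abort("coefficients of variation must be non-negative.",
          class = "renalpk_validation_error")
  }
  structure(list(dose_mg_per_kg = dose_mg_per_kg,
                 sample_times = as.numeric(sample_times),
                 urine_intervals = lapply(seq_len(nrow(iv)),
                                          function(i) as.numeric(iv[i, ])),
                 tissue_time = as.numeric(tissue_time),
                 n_per_group = as.integer(n_per_group),
                 bsv_cv = bsv_cv, residual_cv = residual_cv,
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Reference drug parameterizations
#'
#' Ready-made [drug_params()] sets that realize, in the simulator, the three
#' renal handling regimes studied in hyperuricemic rats:
#'
#' * `drug_metformin()` - an organic cation secreted by basolateral uptake
#'   (Oct2) and apical efflux (Mate1). Uptake intrinsic clearance
#'   (`vmax_uptake / km_uptake` = 150 mL/min/kg) far exceeds renal plasma
#'   flow, so its renal clearance is flow-limited; apical efflux operates
#'   near saturation, so reduced efflux expression raises kidney accumulation
#'   sharply while barely moving plasma clearance.
#' * `drug_cephalexin()` - an anionic beta-lactam secreted (Oat1/Mate1-like)
#'   and reabsorbed by a saturable luminal peptide carrier. At a 10 mg/kg
#'   dose the luminal concentration saturates reabsorption and net secretion
#'   dominates; at 1 mg/kg reabsorption dominates, so the clearance ratio
#'   crosses 1 between the two doses.
#' * `drug_creatinine()` - endogenous, fully unbound (`fu` = 1), produced at
#'   a constant rate chosen so the steady-state plasma concentration is
#'   about 12.8 µM and the clearance ratio about 1.6 (net secretion).
#'
#' The apparent central distribution volume lives in
#' [physiology_params()]; pair these presets with `v_central` of about
#' 1000 mL/kg (metformin), 250 mL/kg (cephalexin, extracellular-like) and
#' 600 mL/kg (creatinine, total body water-like).
#'
#' @return A `drug_params` object.
#' @name drug_presets
NULL

#' @rdname drug_presets
#' @export
drug_metformin <- function() {
  drug_params(name = "metformin", mw = 129.16, fu = 0.85,
              cl_nonrenal = 8, ps_passive = 0.3,
              vmax_uptake = 60000, km_uptake = 400,
              vmax_efflux = 1500, km_efflux = 1200)
}

#' @rdname drug_presets
#' @export
drug_cephalexin <- function() {
  drug_params(name = "cephalexin", mw = 347.39, fu = 0.82,
              cl_nonrenal = 2.5, ps_passive = 0.2,
              vmax_uptake = 10000, km_uptake = 300,
              vmax_efflux = 6000, km_efflux = 150,
              vmax_reab = 190, km_reab = 200)
}

#' @rdname drug_presets
#' @export
drug_creatinine <- function() {
  drug_params(name = "creatinine", mw = 113.12, fu = 1,
              cl_nonrenal = 0, ps_passive = 0.2,
              vmax_uptake = 2700, km_uptake = 500,
              vmax_efflux = 1500, km_efflux = 150,
              synthesis_rate = 140)
}

#' @export
print.physiology_params <- function(x, ...) {
  cat("<physiology_params>\n")
  cat(sprintf("  GFR %.3g, renal plasma flow %.3g mL/min/kg\n", x$gfr, x$q_renal))
  cat(sprintf("  volumes (mL/kg): central %.4g, kidney %.3g, lumen %.3g\n",
              x$v_central, x$v_kidney, x$v_lumen))
  cat(sprintf("  lumen washout %.3g /min\n", x$urine_flow_k))
  invisible(x)
}

#' @export
print.drug_params <- function(x, ...) {
  cat(sprintf("<drug_params> %s (mw %.5g, fu %.3g)\n", x$name, x$mw, x$fu))
  cat(sprintf("  uptake Vmax/Km %.4g/%.4g, efflux %.4g/%.4g, reab %.4g/%.4g\n",
              x$vmax_uptake, x$km_uptake, x$vmax_efflux, x$km_efflux,
              x$vmax_reab, x$km_reab))
  cat(sprintf("  CL_nonrenal %.3g mL/min/kg, PS %.3g, synthesis %.3g nmol/min/kg\n",
              x$cl_nonrenal, x$ps_passive, x$synthesis_rate))
  invisible(x)
}

#' @export
print.transporter_profile <- function(x, ...) {
  cat(sprintf("<transporter_profile> uptake %.3g, efflux %.3g, reab %.3g\n",
              x$uptake, x$efflux, x$reab))
  invisible(x)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> dose %.3g mg/kg, n = %d/arm, seed %d\n",
              x$dose_mg_per_kg, x$n_per_group, x$seed))
  cat(sprintf("  plasma at %s min; tissue at %.0f min\n",
              paste(x$sample_times, collapse = ", "), x$tissue_time))
  cat(sprintf("  urine: %s\n",
              paste(vapply(x$urine_intervals,
                           function(i) sprintf("%g-%g", i[1], i[2]), ""),
                    collapse = ", ")))
  cat(sprintf("  BSV CV %.3g, residual CV %.3g\n", x$bsv_cv, x$residual_cv))
  invisible(x)
}
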