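#' Published group-mean PK parameters of the hyperuricemic-rat study
#'
#' Transcribed group means (n = 3 animals per arm) for metformin
#' (30 mg/kg IV), cephalexin (10 mg/kg and, in control animals only,
#' 1 mg/kg IV) and endogenous creatinine, together with the literature
#' unbound fractions and the per-arm inulin clearance. These are the desk
#' inputs from which the derived-parameter arithmetic - clearance ratios,
#' fold changes, dose/AUC consistency - is reproducible without the raw
#' per-animal data.
#'
#' `ratio_printed` is the published `(CL_R/fu)/CL_inulin` value; recomputing
#' it from the tabulated means with [clearance_ratio()] reproduces it to
#' 2 decimals.
#'
#' @return A tibble with one row per analyte/dose/arm: `analyte`, `group`,
#'   `dose_mg_per_kg`, `mw_g_per_mol`, `auc_0_4_uM_min`, `auc_inf_uM_min`,
#'   `cl_tot_mL_min_kg`, `cl_r_mL_min_kg`, `fu`, `ratio_printed`,
#'   `urinary_recovery_pct`, `kp_kidney`.
#' @examples
#' ref <- reference_pk_means()
#' with(ref, clearance_ratio(cl_r_mL_min_kg, fu,
#'                           reference_inulin_clearance()$cl_inulin_mL_min_kg[
#'                             match(group, reference_inulin_clearance()$group)]))
#' @export
reference_pk_means <- function() {
  tibble::tribble(
    ~analyte, ~group, ~dose_mg_per_kg, ~mw_g_per_mol,
    ~auc_0_4_uM_min, ~auc_inf_uM_min, ~cl_tot_mL_min_kg, ~cl_r_mL_min_kg,
    ~fu, ~ratio_printed, ~urinary_recovery_pct, ~kp_kidney,
    "metformin", "control", 30, 129.16,
    5530, 5638, NA, 23.0, 0.85, 4.03, 74.5, 16.6,
    "metformin", "hyperuricemia", 30, 129.16,
    6100, 6223, NA, 18.3, 0.85, 4.01, 63.3, 90.3,
    "cephalexin", "control", 10, 347.39,
    2629, 2770, 10.6, 7.96, 0.82, 1.44, 71.0, 9.76,
    "cephalexin", "hyperuricemia", 10, 347.39,
    4625, 7381, NA, 2.87, 0.82, 0.65, 46.1, 15.1,
    "cephalexin_low_dose", "control", 1, 347.39,
    656, 901, 3.57, 1.88, 0.82, 0.34, 41.1, NA,
    "creatinine", "control", 0, 113.12,
    5373, NA, NA, 10.9, 1.0, 1.62, NA, 10.2,
    "creatinine", "hyperuricemia", 0, 113.12,
    9807, NA, NA, 5.84, 1.0, 1.09, NA, 13.7)
}

#' @rdname reference_pk_means
#' @details `reference_inulin_clearance()` returns the per-arm inulin
#'   clearance (GFR): 6.72 mL/min/kg in control and 5.36 in hyperuricemic
#'   animals.
#' @export
reference_inulin_clearance <- function() {
  tibble::tibble(group = c("control", "hyperuricemia"),
                 cl_inulin_mL_min_kg = c(6.72, 5.36))
}

#' @rdname reference_pk_means
#' @details `reference_uptake_percent()` returns the published
#'   percent-of-control values of the MATE1 inhibition screen (oxonic acid,
#'   adenine and uric acid at 50 and 500 µM; cimetidine as the positive
#'   control at 8.2%), used to parameterize [generate_uptake()] emulations.
#' @export
reference_uptake_percent <- function() {
  tibble::tribble(
    ~treatment, ~conc_uM, ~percent_of_control,
    "oxonic_acid", 50, 101.5,
    "oxonic_acid", 500, 98.2,
    "adenine", 50, 87.7,
    "adenine", 500, 87.0,
    "uric_acid", 50, 102.0,
    "uric_acid", 500, 100.7,
    "cimetidine", NA, 8.2)
}
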