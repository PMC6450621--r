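# Tidy CSV schemas. Units are baked into the column names so files cannot
# drift silently: times in min, concentrations in µM, amounts in nmol/kg.

pk_schemas <- list(
  plasma = list(cols = c(subject_id = "c", group = "c", analyte = "c",
                         time_min = "d", conc_uM = "d"),
                nonneg = c("time_min", "conc_uM")),
  urine = list(cols = c(subject_id = "c", group = "c", analyte = "c",
                        t_start_min = "d", t_end_min = "d",
                        amount_nmol_per_kg = "d"),
               nonneg = c("t_start_min", "t_end_min", "amount_nmol_per_kg")),
  tissue = list(cols = c(subject_id = "c", group = "c", analyte = "c",
                         time_min = "d", conc_uM = "d"),
                nonneg = c("time_min", "conc_uM")),
  doses = list(cols = c(subject_id = "c", analyte = "c",
                        dose_mg_per_kg = "d", mw_g_per_mol = "d"),
               nonneg = c("dose_mg_per_kg", "mw_g_per_mol")),
  fu = list(cols = c(analyte = "c", fu = "d"), nonneg = "fu"),
  gfr = list(cols = c(group = "c", cl_inulin_mL_min_kg = "d"),
             nonneg = "cl_inulin_mL_min_kg"),
  ct = list(cols = c(sample_id = "c", group = "c", gene = "c", ct = "d"),
            nonneg = character()),
  uptake = list(cols = c(cell_line = "c", treatment = "c", replicate = "c",
                         amount_pmol_per_mg = "d",
                         medium_conc_pmol_per_uL = "d"),
                nonneg = c("amount_pmol_per_mg", "medium_conc_pmol_per_uL")))

#' Names of the tidy CSV schemas
#' @return Character vector of schema names accepted by [read_validate()]
#'   and [write_pk_csv()].
#' @export
pk_schema_names <- function() names(pk_schemas)

#' Read and validate a tidy study CSV
#'
#' Reads one of the package's tidy CSV schemas, checks that the declared
#' columns are present and numeric where required, rejects negative values
#' in quantity columns with row-addressed messages, and warns (but
#' proceeds) on unknown extra columns.
#'
#' @param path CSV file path.
#' @param schema_name One of [pk_schema_names()].
#' @return A validated tibble with the schema's columns first.
#' @export
read_validate <- function(path, schema_name) {
  if (!schema_name %in% names(pk_schemas)) {
    abort(sprintf("unknown schema '%s'; see pk_schema_names().", schema_name),
          class = "renalpk_validation_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
          class = "renalpk_validation_error")
  }
  sch <- pk_schemas[[schema_name]]
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing column(s) %s for schema '%s'.",
                  path, paste(missing, collapse = ", "), schema_name),
          class = "renalpk_validation_error")
  }
  extra <- setdiff(names(df), names(sch$cols))
  if (length(extra) > 0L) {
    warn(sprintf("%s: ignoring unknown column(s) %s.",
                 path, paste(extra, collapse = ", ")))
  }
  for (col in names(sch$cols)) {
    if (sch$cols[[col]] == "d") {
      val <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(val) & !is.na(df[[col]]))
      if (length(bad) > 0L) {
        abort(sprintf("%s: non-numeric value in column '%s' at data row(s) %s.",
                      path, col, paste(head(bad, 5), collapse = ", ")),
              class = "renalpk_validation_error")
      }
      df[[col]] <- val
    }
  }
  for (col in sch$nonneg) {
    bad <- which(df[[col]] < 0)
    if (length(bad) > 0L) {
      abort(sprintf("%s: negative value in column '%s' at data row(s) %s.",
                    path, col, paste(head(bad, 5), collapse = ", ")),
            class = "renalpk_validation_error")
    }
  }
  dplyr::relocate(df, dplyr::all_of(names(sch$cols)))
}

#' Write a tidy study CSV
#'
#' Deterministic counterpart of [read_validate()]: columns are emitted in
#' the declared schema order so a write-then-read round trip returns an
#' equal table.
#'
#' @param df Data frame matching the schema.
#' @param path Output CSV path.
#' @param schema_name One of [pk_schema_names()].
#' @return `path`, invisibly.
#' @export
write_pk_csv <- function(df, path, schema_name) {
  if (!schema_name %in% names(pk_schemas)) {
    abort(sprintf("unknown schema '%s'.", schema_name),
          class = "renalpk_validation_error")
  }
  sch <- pk_schemas[[schema_name]]
  missing <- setdiff(names(sch$cols), names(df))
  if (length(missing) > 0L) {
    abort(sprintf("cannot write schema '%s': missing column(s) %s.",
                  schema_name, paste(missing, collapse = ", ")),
          class = "renalpk_validation_error")
  }
  readr::write_csv(df[, names(sch$cols)], path, progress = FALSE)
  invisible(path)
}

#' Write a formatted report table
#'
#' Renders an analysis result in one of the publication-style layouts and
#' writes it as a deterministic CSV: fixed column order, groups ordered as
#' given, ratios and fold changes rounded to 2 decimals, other quantities
#' to 3 significant digits.
#'
#' Layouts:
#' * `"pk_table"` - one row per group (plus fold-change rows) per analyte,
#'   columns AUC_0-t, AUC_inf, CL_tot, CL_R, fu, clearance ratio, urinary
#'   recovery, K_p,kidney; expects an [run_nca_study()] result.
#' * `"expression"` - per-gene relative expression (ratio to control);
#'   expects an [expression_summary()] tibble.
#' * `"uptake"` - percent-of-control per treatment; expects an
#'   [uptake_percent_of_control()] tibble.
#'
#' @param results The analysis object for the layout.
#' @param layout One of `"pk_table"`, `"expression"`, `"uptake"`.
#' @param path Output CSV path.
#' @return The formatted tibble, invisibly.
#' @export
write_report <- function(results, layout = c("pk_table", "expression",
                                             "uptake"), path) {
  layout <- match.arg(layout)
  tab <- switch(layout,
    pk_table = format_pk_table(results),
    expression = format_expression_table(results),
    uptake = format_uptake_table(results))
  readr::write_csv(tab, path, progress = FALSE, na = "NC")
  invisible(tab)
}

round_sig <- function(x, digits = 3) signif(x, digits)

format_pk_table <- function(res) {
  if (!inherits(res, "nca_study")) {
    abort("`results` for layout 'pk_table' must be an nca_study.",
          class = "renalpk_layout_error")
  }
  wide <- res$summary |>
    dplyr::select("analyte", "group", "parameter", "mean") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "mean")
  fu_tab <- dplyr::distinct(res$subjects, .data$analyte, .data$fu)
  wide <- dplyr::left_join(wide, fu_tab, by = "analyte")
  cols <- c("auc_0_t", "auc_inf", "cl_tot", "cl_r", "fu",
            "clearance_ratio", "urinary_recovery", "kp_kidney")
  for (col in setdiff(cols, names(wide))) wide[[col]] <- NA_real_
  fold <- res$fold_changes
  fold_cols <- grep("^fold_", names(fold), value = TRUE)
  out <- wide |>
    dplyr::mutate(dplyr::across(dplyr::all_of(c("auc_0_t", "auc_inf",
                                                "cl_tot", "cl_r",
                                                "urinary_recovery",
                                                "kp_kidney")),
                                ~round_sig(.x, 3)),
                  dplyr::across(dplyr::all_of(c("clearance_ratio", "fu")),
                                ~round(.x, 2))) |>
    dplyr::select("analyte", "group", dplyr::all_of(cols)) |>
    dplyr::arrange(.data$analyte)
  if (length(fold_cols) > 0L) {
    fc <- fold |>
      dplyr::filter(.data$parameter %in% cols) |>
      dplyr::select("analyte", "parameter", dplyr::all_of(fold_cols)) |>
      tidyr::pivot_longer(dplyr::all_of(fold_cols), names_to = "arm",
                          values_to = "fold") |>
      dplyr::mutate(group = sub("^fold_", "fold change: ", .data$arm),
                    fold = round(.data$fold, 2)) |>
      dplyr::select("analyte", "group", "parameter", "fold") |>
      tidyr::pivot_wider(names_from = "parameter", values_from = "fold")
    for (col in setdiff(cols, names(fc))) fc[[col]] <- NA_real_
    out <- dplyr::bind_rows(out, dplyr::select(fc, "analyte", "group",
                                               dplyr::all_of(cols))) |>
      dplyr::arrange(.data$analyte)
  }
  out
}

format_expression_table <- function(res) {
  need <- c("gene", "group", "mean_rel_expr", "sem", "ratio_to_control")
  if (!all(need %in% names(res))) {
    abort("`results` for layout 'expression' must be an expression_summary() tibble.",
          class = "renalpk_layout_error")
  }
  res |>
    dplyr::mutate(dplyr::across(c("mean_rel_expr", "sem", "ratio_to_control"),
                                ~round(.x, 3))) |>
    dplyr::arrange(.data$gene, .data$group)
}

format_uptake_table <- function(res) {
  need <- c("treatment", "percent_of_control")
  if (!all(need %in% names(res))) {
    abort("`results` for layout 'uptake' must be an uptake_percent_of_control() tibble.",
          class = "renalpk_layout_error")
  }
  res |>
    dplyr::mutate(percent_of_control = round(.data$percent_of_control, 1),
                  dplyr::across(dplyr::where(is.numeric), ~round_sig(.x, 4)))
}
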