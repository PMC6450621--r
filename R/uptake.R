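#' Cell-to-medium ratio of an uptake assay
#'
#' Cellular uptake normalized to the medium substrate concentration:
#' `amount / medium_conc`, in µL per mg protein - a distribution-volume-like
#' index of transport activity.
#'
#' @param amount Cellular amount, pmol per mg protein (vectorized).
#' @param medium_conc Medium substrate concentration, pmol/µL, > 0.
#' @return Cell-to-medium ratio, µL/mg protein.
#' @examples
#' cell_to_medium(0.05, 0.00025) # 200 µL/mg
#' @export
cell_to_medium <- function(amount, medium_conc) {
  if (any(!is.finite(medium_conc)) || any(medium_conc <= 0)) {
    abort("`medium_conc` must be positive.",
          class = "renalpk_validation_error")
  }
  if (any(amount < 0)) {
    abort("`amount` must be non-negative.",
          class = "renalpk_validation_error")
  }
  amount / medium_conc
}

#' Percent of control for transporter-mediated uptake
#'
#' The transporter-mediated component is the expressing-cell minus the
#' mock-cell (vector-only) group mean; the percent of control is that
#' component in a treated group relative to the untreated control:
#' `100 * (E_t - M_t) / (E_c - M_c)`. Mock subtraction is
#' treatment-matched.
#'
#' @param expressing_treated,mock_treated,expressing_control,mock_control
#'   Group means of cell-to-medium ratios, µL/mg protein.
#' @return Percent of control (vectorized over the treated means).
#' @examples
#' percent_of_control(28, 20, 100, 20) # 10
#' @export
percent_of_control <- function(expressing_treated, mock_treated,
                               expressing_control, mock_control) {
  denom <- expressing_control - mock_control
  if (any(!is.finite(denom)) || any(denom <= 0)) {
    abort("the control transporter-mediated component (expressing - mock) must be positive.",
          class = "renalpk_undefined_percent")
  }
  100 * (expressing_treated - mock_treated) / denom
}

#' Reduce an uptake assay table to percent-of-control per treatment
#'
#' Computes per-record cell-to-medium ratios, averages them per cell line
#' and treatment, forms the treatment-matched transporter-mediated
#' component, and expresses it relative to the untreated control. When the
#' expressing cells have at least two replicates per treatment, Dunnett
#' many-to-one adjusted p-values against the control treatment are attached.
#'
#' @param uptake Tibble with columns `cell_line` ("expressing"/"mock"),
#'   `treatment`, `replicate`, `amount_pmol_per_mg`,
#'   `medium_conc_pmol_per_uL`.
#' @param control_treatment Label of the untreated wells (default
#'   "control").
#' @param dunnett Attach Monte-Carlo Dunnett adjusted p-values (default
#'   TRUE when replication allows).
#' @param seed Seed for the Dunnett Monte-Carlo draw.
#' @return A tibble of class `uptake_pct` with one row per treatment:
#'   `treatment`, mean expressing and mock ratios, `transporter_component`,
#'   `percent_of_control`, and `p_adjusted` (NA for the control row).
#' @examples
#' up <- generate_uptake(180, 20, c(control = 0, cimetidine = 0.918),
#'                       n = 3, noise_cv = 0.05, seed = 2)
#' uptake_percent_of_control(up)
#' @export
uptake_percent_of_control <- function(uptake, control_treatment = "control",
                                      dunnett = TRUE, seed = 1L) {
  need <- c("cell_line", "treatment", "amount_pmol_per_mg",
            "medium_conc_pmol_per_uL")
  if (!all(need %in% names(uptake))) {
    abort(paste0("`uptake` must have columns ",
                 paste(need, collapse = ", "), "."),
          class = "renalpk_validation_error")
  }
  if (!control_treatment %in% uptake$treatment) {
    abort(sprintf("control treatment '%s' not found.", control_treatment),
          class = "renalpk_configuration_error")
  }
  up <- uptake |>
    dplyr::mutate(ratio = cell_to_medium(.data$amount_pmol_per_mg,
                                         .data$medium_conc_pmol_per_uL))
  means <- up |>
    dplyr::group_by(.data$treatment, .data$cell_line) |>
    dplyr::summarise(mean_ratio = mean(.data$ratio), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "cell_line",
                       values_from = c("mean_ratio", "n"))
  ctrl <- means[means$treatment == control_treatment, , drop = FALSE]
  out <- means |>
    dplyr::mutate(
      transporter_component = .data$mean_ratio_expressing -
        .data$mean_ratio_mock,
      percent_of_control = percent_of_control(
        .data$mean_ratio_expressing, .data$mean_ratio_mock,
        ctrl$mean_ratio_expressing, ctrl$mean_ratio_mock))

  out$p_adjusted <- NA_real_
  treatments <- setdiff(out$treatment, control_treatment)
  expressing <- up[up$cell_line == "expressing", , drop = FALSE]
  reps <- table(expressing$treatment)
  if (dunnett && length(treatments) > 0L && all(reps >= 2)) {
    trt_values <- lapply(treatments, function(tr) {
      expressing$ratio[expressing$treatment == tr]
    })
    names(trt_values) <- treatments
    dn <- dunnett_many_to_one(
      expressing$ratio[expressing$treatment == control_treatment],
      trt_values, seed = seed)
    out$p_adjusted[match(dn$treatment, out$treatment)] <- dn$p_adjusted
  }
  out <- dplyr::arrange(out, .data$treatment != control_treatment,
                        .data$treatment)
  class(out) <- c("uptake_pct", class(out))
  out
}

#' @export
autoplot.uptake_pct <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$treatment,
                                       y = .data$percent_of_control)) +
    ggplot2::geom_col(width = 0.6, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey55") +
    ggplot2::labs(x = NULL, y = "transporter-mediated uptake (% of control)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
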