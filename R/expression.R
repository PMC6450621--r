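#' Relative mRNA expression by the delta-delta-Ct method
#'
#' Per sample and gene: `dCt = Ct_gene - Ct_reference`;
#' `ddCt = dCt - mean(dCt of the control group)`; relative expression
#' `2^(-ddCt)` (amplification efficiency fixed at 2). The control-group
#' baseline is the group mean of dCt, so the control-arm geometric mean
#' expression is 1 by construction. Technical replicates (duplicate
#' sample-gene rows) are averaged on the Ct scale before dCt.
#'
#' @param ct Tibble with columns `sample_id`, `group`, `gene`, `ct`.
#' @param reference_gene Reference (housekeeping) gene label, default
#'   "Gapdh".
#' @param control_group Control group label, default "control".
#' @return A tibble of class `ddct_tbl` with one row per sample and target
#'   gene: `gene`, `sample_id`, `group`, `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`. Summarize per gene with [expression_summary()].
#' @examples
#' ct <- generate_qpcr(c(Mate1 = 0.5), n_per_group = 3, noise_sd_ct = 0)
#' delta_delta_ct(ct)
#' @export
delta_delta_ct <- function(ct, reference_gene = "Gapdh",
                           control_group = "control") {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(ct))) {
    abort(paste0("`ct` must have columns ", paste(need, collapse = ", "), "."),
          class = "renalpk_validation_error")
  }
  if (!control_group %in% ct$group) {
    abort(sprintf("control group '%s' not present in the Ct table.",
                  control_group),
          class = "renalpk_configuration_error")
  }
  if (any(!is.finite(ct$ct))) {
    abort("all Ct values must be finite.", class = "renalpk_validation_error")
  }
  # average technical replicates on the Ct scale
  ct <- ct |>
    dplyr::group_by(.data$sample_id, .data$group, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  ref <- ct |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample_id", ct_ref = "ct")
  missing_ref <- setdiff(unique(ct$sample_id), ref$sample_id)
  if (length(missing_ref) > 0L) {
    abort(paste0("sample(s) without a reference-gene Ct: ",
                 paste(missing_ref, collapse = ", ")),
          class = "renalpk_validation_error")
  }

  out <- ct |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ct_ref) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(delta_delta_ct = .data$delta_ct -
                    mean(.data$delta_ct[.data$group == control_group])) |>
    dplyr::ungroup() |>
    dplyr::mutate(rel_expr = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("gene", "sample_id", "group", "delta_ct",
                  "delta_delta_ct", "rel_expr") |>
    dplyr::arrange(.data$gene, .data$group, .data$sample_id)
  class(out) <- c("ddct_tbl", class(out))
  attr(out, "reference_gene") <- reference_gene
  attr(out, "control_group") <- control_group
  out
}

#' Summarize relative expression per gene and group
#'
#' Group mean with SEM of the per-sample `2^(-ddCt)` values, the
#' case-over-control ratio of group means (displayed so the control mean is
#' 1), and an unpaired t-test p-value per gene against the control group.
#'
#' @param ddct A [delta_delta_ct()] result.
#' @return A tibble with `gene`, `group`, `n`, `mean_rel_expr`, `sem`,
#'   `ratio_to_control`, `p_value` (NA for the control rows).
#' @export
expression_summary <- function(ddct) {
  if (!inherits(ddct, "ddct_tbl")) {
    abort("`ddct` must come from delta_delta_ct().",
          class = "renalpk_validation_error")
  }
  control_group <- attr(ddct, "control_group")
  smry <- ddct |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_rel_expr = mean(.data$rel_expr),
                     sem = sd(.data$rel_expr) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(ratio_to_control = .data$mean_rel_expr /
                    .data$mean_rel_expr[.data$group == control_group]) |>
    dplyr::ungroup()
  pvals <- ddct |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(d, key) {
      ctrl <- d$rel_expr[d$group == control_group]
      cases <- setdiff(unique(d$group), control_group)
      purrr::map_dfr(cases, function(g) {
        p <- if (length(ctrl) >= 2 && sum(d$group == g) >= 2) {
          # degenerate (zero-variance) gene: no test rather than an error
          tryCatch(students_t_unpaired(d$rel_expr[d$group == g], ctrl)$p,
                   renalpk_degenerate_variance = function(e) NA_real_)
        } else {
          NA_real_
        }
        tibble::tibble(group = g, p_value = p)
      })
    }) |>
    dplyr::ungroup()
  dplyr::left_join(smry, pvals, by = c("gene", "group"))
}

#' @export
autoplot.ddct_tbl <- function(object, ...) {
  smry <- expression_summary(object)
  ggplot2::ggplot(smry, ggplot2::aes(x = .data$gene,
                                     y = .data$ratio_to_control,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "relative mRNA (ratio to control)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
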