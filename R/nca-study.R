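#' Non-compartmental analysis of a whole study
#'
#' Runs the full NCA pipeline per animal and analyte - windowed trapezoidal
#' AUC, terminal-slope extrapolation, total and renal clearance, urinary
#' recovery, kidney partition coefficient, and the GFR-normalized clearance
#' ratio with its secretion/reabsorption classification - then summarizes
#' each arm as mean with SEM and reports case-over-control fold changes.
#'
#' Endogenous analytes (no dose record, or dose 0) get `NA` for
#' `auc_inf`, `cl_tot` and recovery, mirroring the usual "NC"/"NA" entries
#' of a PK parameter table: extrapolation to infinity is meaningless for a
#' steady-state endogenous profile. A missing or failed terminal fit
#' likewise yields `NA` extrapolated quantities rather than an error.
#'
#' @param plasma Tibble with columns `subject_id`, `group`, `analyte`,
#'   `time_min`, `conc_uM`.
#' @param urine Optional tibble with `subject_id`, `group`, `analyte`,
#'   `t_start_min`, `t_end_min`, `amount_nmol_per_kg`. Without it, CL_R,
#'   recovery and the clearance ratio are left `NA`.
#' @param tissue Optional tibble with `subject_id`, `group`, `analyte`,
#'   `time_min`, `conc_uM` (terminal kidney samples).
#' @param doses Optional tibble with `subject_id` (or one row per analyte),
#'   `analyte`, `dose_mg_per_kg`, `mw_g_per_mol`.
#' @param fu Tibble with `analyte`, `fu`: unbound plasma fractions.
#' @param gfr Tibble with `group`, `cl_inulin_mL_min_kg`: per-arm inulin
#'   clearance used to normalize the clearance ratio.
#' @param window AUC / urine window, min (default `c(0, 240)`).
#' @param control_group Label of the control arm (denominator of fold
#'   changes).
#' @param epsilon Indeterminate band half-width for [clearance_ratio()].
#' @param anchor Window-start anchoring rule, see [auc_linear_trapezoid()].
#'
#' @return An object of class `nca_study`: a list with
#'   `subjects` (per-animal parameter tibble), `summary` (group mean, SEM
#'   and n per parameter), `fold_changes` (case over control group means),
#'   and the call settings. [tidy()] returns the per-animal table,
#'   [glance()] the fold changes, [autoplot()] a parameter dot plot.
#' @examples
#' st <- simulate_study(physiology_params(), drug_cephalexin(),
#'                      design = study_design(10, n_per_group = 2, seed = 1))
#' res <- run_nca_study(
#'   st$plasma, st$urine, st$tissue,
#'   doses = dplyr::distinct(st$plasma[, c("subject_id", "analyte")]) |>
#'     dplyr::mutate(dose_mg_per_kg = 10, mw_g_per_mol = 347.39),
#'   fu = tibble::tibble(analyte = "cephalexin", fu = 0.82),
#'   gfr = tibble::tibble(group = c("control", "hyperuricemia"),
#'                        cl_inulin_mL_min_kg = c(6.72, 5.36)))
#' res$summary
#' @export
run_nca_study <- function(plasma, urine = NULL, tissue = NULL, doses = NULL,
                          fu, gfr, window = c(0, 240),
                          control_group = "control", epsilon = 0.05,
                          anchor = "first_observed") {
  need <- c("subject_id", "group", "analyte", "time_min", "conc_uM")
  if (!all(need %in% names(plasma))) {
    abort(paste0("`plasma` must have columns ",
                 paste(need, collapse = ", "), "."),
          class = "renalpk_validation_error")
  }
  if (!all(c("analyte", "fu") %in% names(fu))) {
    abort("`fu` must have columns analyte, fu.",
          class = "renalpk_validation_error")
  }
  if (!all(c("group", "cl_inulin_mL_min_kg") %in% names(gfr))) {
    abort("`gfr` must have columns group, cl_inulin_mL_min_kg.",
          class = "renalpk_validation_error")
  }
  missing_fu <- setdiff(unique(plasma$analyte), fu$analyte)
  if (length(missing_fu) > 0L) {
    abort(paste0("no unbound fraction configured for analyte(s): ",
                 paste(missing_fu, collapse = ", ")),
          class = "renalpk_configuration_error")
  }

  keys <- dplyr::distinct(plasma, .data$subject_id, .data$group, .data$analyte)
  res <- purrr::pmap(keys, function(subject_id, group, analyte) {
    pl <- dplyr::arrange(
      dplyr::filter(plasma, .data$subject_id == !!subject_id,
                    .data$analyte == !!analyte),
      .data$time_min)
    fu_i <- fu$fu[match(analyte, fu$analyte)]
    gfr_i <- gfr$cl_inulin_mL_min_kg[match(group, gfr$group)]

    dose_i <- mw_i <- NA_real_
    if (!is.null(doses)) {
      d <- doses[doses$analyte == analyte, , drop = FALSE]
      if ("subject_id" %in% names(d) && subject_id %in% d$subject_id) {
        d <- d[d$subject_id == subject_id, , drop = FALSE]
      }
      if (nrow(d) > 0L) {
        dose_i <- d$dose_mg_per_kg[1]
        mw_i <- d$mw_g_per_mol[1]
      }
    }
    dosed <- is.finite(dose_i) && dose_i > 0

    auc_w <- auc_linear_trapezoid(pl$time_min, pl$conc_uM,
                                  t_start = window[1], t_end = window[2],
                                  anchor = anchor)
    lam <- tryCatch(fit_lambda_z(pl$time_min, pl$conc_uM),
                    renalpk_no_valid_fit = function(e) NULL)
    auc_inf <- cl_tot <- lambda_z <- NA_real_
    if (dosed && !is.null(lam)) {
      lambda_z <- lam$lambda_z
      c_last <- tail(pl$conc_uM[pl$conc_uM > 0], 1)
      auc_last <- auc_linear_trapezoid(pl$time_min, pl$conc_uM,
                                       t_start = window[1],
                                       t_end = max(pl$time_min),
                                       anchor = anchor)
      auc_inf <- auc_extrapolate_inf(auc_last, c_last, lam)
      cl_tot <- cl_total(dose_i, mw_i, auc_inf)
    }

    clr <- recov <- x_ur <- NA_real_
    if (!is.null(urine)) {
      ur <- urine[urine$subject_id == subject_id & urine$analyte == analyte, ,
                  drop = FALSE]
      if (nrow(ur) > 0L) {
        x_ur <- cumulative_urine(ur, window)
        clr <- cl_renal(x_ur, auc_w)
        if (dosed) recov <- urinary_recovery(x_ur, dose_i, mw_i)
      }
    }

    kp <- NA_real_
    if (!is.null(tissue)) {
      ti <- tissue[tissue$subject_id == subject_id &
                     tissue$analyte == analyte, , drop = FALSE]
      if (nrow(ti) > 0L) {
        i_cp <- which.min(abs(pl$time_min - ti$time_min[1]))
        if (pl$conc_uM[i_cp] > 0) kp <- ti$conc_uM[1] / pl$conc_uM[i_cp]
      }
    }

    cr <- if (is.finite(clr) && is.finite(gfr_i)) {
      clearance_ratio(clr, fu_i, gfr_i, epsilon)
    } else {
      tibble::tibble(ratio = NA_real_, classification = NA_character_)
    }

    tibble::tibble(
      subject_id = subject_id, group = group, analyte = analyte,
      dose_mg_per_kg = dose_i, auc_0_t = auc_w, lambda_z = lambda_z,
      auc_inf = auc_inf, cl_tot = cl_tot, cl_r = clr,
      urinary_recovery = recov, kp_kidney = kp, fu = fu_i,
      clearance_ratio = cr$ratio, classification = cr$classification)
  })
  subjects <- dplyr::bind_rows(res)

  params <- c("auc_0_t", "auc_inf", "cl_tot", "cl_r", "urinary_recovery",
              "kp_kidney", "clearance_ratio")
  long <- tidyr::pivot_longer(subjects, dplyr::all_of(params),
                              names_to = "parameter", values_to = "value")
  summary <- long |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$analyte, .data$group, .data$parameter) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = params)) |>
    dplyr::arrange(.data$analyte, .data$parameter, .data$group) |>
    dplyr::mutate(parameter = as.character(.data$parameter))

  fold_changes <- summary |>
    dplyr::select("analyte", "group", "parameter", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  case_groups <- setdiff(unique(subjects$group), control_group)
  if (control_group %in% names(fold_changes) && length(case_groups) > 0L) {
    for (cg in case_groups) {
      fold_changes[[paste0("fold_", cg)]] <-
        fold_changes[[cg]] / fold_changes[[control_group]]
    }
  }

  structure(list(subjects = subjects, summary = summary,
                 fold_changes = fold_changes, window = window,
                 control_group = control_group, epsilon = epsilon),
            class = "nca_study")
}

#' @export
print.nca_study <- function(x, ...) {
  cat(sprintf("<nca_study> %d animals, %d analyte(s), window %g-%g min\n",
              length(unique(x$subjects$subject_id)),
              length(unique(x$subjects$analyte)),
              x$window[1], x$window[2]))
  print(x$summary, n = 20)
  invisible(x)
}

#' @rdname run_nca_study
#' @param x An `nca_study` object.
#' @param ... Unused.
#' @export
tidy.nca_study <- function(x, ...) x$subjects

#' @rdname run_nca_study
#' @export
glance.nca_study <- function(x, ...) x$fold_changes

#' @rdname run_nca_study
#' @param object An `nca_study` object.
#' @export
autoplot.nca_study <- function(object, ...) {
  params <- c("auc_0_t", "cl_r", "kp_kidney", "clearance_ratio")
  df <- object$summary |>
    dplyr::filter(.data$parameter %in% params)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.2) +
    ggplot2::facet_grid(parameter ~ analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "group mean ± SEM") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Plot plasma concentration-time profiles
#'
#' @param plasma Tibble with `subject_id`, `group`, `analyte`, `time_min`,
#'   `conc_uM`.
#' @param log_y Log-scale the concentration axis (default TRUE).
#' @return A ggplot object: group mean profiles with per-animal traces.
#' @export
plot_concentration_time <- function(plasma, log_y = TRUE) {
  p <- ggplot2::ggplot(plasma,
                       ggplot2::aes(x = .data$time_min, y = .data$conc_uM,
                                    colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.35) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1) +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "plasma concentration (µM)") +
    ggplot2::theme_bw()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
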