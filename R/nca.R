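# Non-compartmental analysis kernels.

check_profile <- function(time, conc) {
  if (length(time) != length(conc)) {
    abort("`time` and `conc` must have equal length.",
          class = "renalpk_validation_error")
  }
  if (length(time) < 2L) {
    abort("at least 2 concentration-time points are required.",
          class = "renalpk_insufficient_data")
  }
  if (any(!is.finite(time)) || any(!is.finite(conc))) {
    abort("non-finite values in the concentration-time profile.",
          class = "renalpk_validation_error")
  }
  if (time[1] < 0 || any(diff(time) <= 0)) {
    abort("`time` must be non-negative and strictly increasing.",
          class = "renalpk_validation_error")
  }
  if (any(conc < 0)) {
    abort("negative concentrations in the profile.",
          class = "renalpk_validation_error")
  }
  invisible(TRUE)
}

#' Linear-trapezoid area under the concentration-time curve
#'
#' Integrates a plasma concentration-time profile over `[t_start, t_end]`
#' with the linear trapezoidal rule, interpolating linearly at window
#' bounds that fall between samples.
#'
#' For an IV bolus no concentration is measurable at t = 0; when the window
#' starts before the first sample, `anchor` controls the value used there:
#' `"first_observed"` (default) carries the first observed concentration
#' back, `"log_backextrapolate"` extrapolates C(0) log-linearly from the
#' first two positive samples, and `"none"` raises an out-of-range error.
#'
#' @param time,conc Numeric vectors: sampling times (min, strictly
#'   increasing, >= 0) and concentrations (µM, >= 0).
#' @param t_start,t_end Integration window, min. Defaults to the sampled
#'   range.
#' @param anchor Handling of a window start before the first sample (see
#'   Details).
#' @return AUC over the window, µM·min.
#' @examples
#' auc_linear_trapezoid(c(0, 240), c(2, 2))           # 480
#' auc_linear_trapezoid(c(0, 60, 120), c(10, 5, 0))   # 600
#' @export
auc_linear_trapezoid <- function(time, conc, t_start = min(time),
                                 t_end = max(time),
                                 anchor = c("first_observed",
                                            "log_backextrapolate", "none")) {
  anchor <- match.arg(anchor)
  check_profile(time, conc)
  if (t_end <= t_start) {
    abort("`t_end` must exceed `t_start`.", class = "renalpk_validation_error")
  }
  if (t_end > max(time) + 1e-9) {
    abort(sprintf("window end %g is beyond the last sample time %g.",
                  t_end, max(time)),
          class = "renalpk_out_of_range")
  }
  if (t_start < time[1] - 1e-9) {
    if (anchor == "none") {
      abort(sprintf("window start %g precedes the first sample time %g.",
                    t_start, time[1]),
            class = "renalpk_out_of_range")
    }
    c0 <- if (anchor == "first_observed") {
      conc[1]
    } else {
      pos <- which(conc > 0)
      if (length(pos) < 2L) {
        abort("log back-extrapolation needs two positive leading samples.",
              class = "renalpk_insufficient_data")
      }
      i <- pos[1:2]
      slope <- (log(conc[i[2]]) - log(conc[i[1]])) / (time[i[2]] - time[i[1]])
      exp(log(conc[i[1]]) + slope * (t_start - time[i[1]]))
    }
    time <- c(t_start, time)
    conc <- c(c0, conc)
  }
  f <- stats::approxfun(time, conc)
  knots <- c(t_start, time[time > t_start & time < t_end], t_end)
  y <- f(knots)
  sum(diff(knots) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Terminal slope (lambda-z) by log-linear regression
#'
#' Fits ordinary least squares to log concentration against time over
#' candidate terminal windows (the last 3, 4, ... points after the peak)
#' and keeps the window with the highest adjusted R-squared, preferring
#' fewer points on ties. The terminal rate constant is minus the slope.
#'
#' @inheritParams auc_linear_trapezoid
#' @param min_points Minimum number of points in a candidate window
#'   (>= 3).
#' @return An object of class `lambda_z_fit`: a list with `lambda_z`
#'   (1/min), `intercept` (log µM at t = 0 of the fitted line), `n_points`,
#'   `adj_r2`, `t_first`, `t_last`. Use [tidy()] for a one-row tibble.
#' @examples
#' t <- c(10, 30, 60, 120, 180, 240)
#' fit <- fit_lambda_z(t, 8 * exp(-0.02 * t))
#' fit$lambda_z
#' @export
fit_lambda_z <- function(time, conc, min_points = 3L) {
  check_profile(time, conc)
  if (min_points < 3L) {
    abort("`min_points` must be >= 3.", class = "renalpk_validation_error")
  }
  i_peak <- which.max(conc)
  idx <- seq(i_peak, length(conc))
  idx <- idx[conc[idx] > 0]
  if (length(idx) < min_points) {
    abort("too few positive post-peak concentrations for a terminal fit.",
          class = "renalpk_no_valid_fit")
  }
  best <- NULL
  for (k in seq(min_points, length(idx))) {
    w <- tail(idx, k)
    fit <- lm(log(conc[w]) ~ time[w])
    slope <- coef(fit)[[2]]
    # numerically flat profiles are not a decline
    if (!is.finite(slope) || slope >= -1e-12) next
    # noiseless profiles fit exactly; summary.lm warns about that
    r2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || r2 > best$adj_r2) {
      best <- list(lambda_z = -slope, intercept = coef(fit)[[1]],
                   n_points = k, adj_r2 = r2,
                   t_first = time[w[1]], t_last = time[w[length(w)]])
    }
  }
  if (is.null(best)) {
    abort("no candidate terminal window has a negative slope; lambda-z is not estimable.",
          class = "renalpk_no_valid_fit")
  }
  structure(best, class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  cat(sprintf("<lambda_z_fit> lambda_z %.5g /min (t1/2 %.4g min), %d points on [%g, %g], adj R2 %.4f\n",
              x$lambda_z, log(2) / x$lambda_z, x$n_points,
              x$t_first, x$t_last, x$adj_r2))
  invisible(x)
}

#' @export
tidy.lambda_z_fit <- function(x, ...) {
  tibble::tibble(lambda_z = x$lambda_z, intercept = x$intercept,
                 n_points = x$n_points, adj_r2 = x$adj_r2,
                 t_first = x$t_first, t_last = x$t_last)
}

#' Extrapolate an AUC to infinity
#'
#' `AUC_inf = AUC_0-tlast + C_last / lambda_z`.
#'
#' @param auc_0_tlast AUC up to the last quantifiable sample, µM·min.
#' @param c_last Last quantifiable concentration, µM.
#' @param fit A [fit_lambda_z()] result.
#' @return AUC from 0 to infinity, µM·min.
#' @export
auc_extrapolate_inf <- function(auc_0_tlast, c_last, fit) {
  if (!inherits(fit, "lambda_z_fit")) {
    abort("`fit` must be a `lambda_z_fit`.", class = "renalpk_validation_error")
  }
  auc_0_tlast + c_last / fit$lambda_z
}

#' Total body clearance from dose and AUC to infinity
#'
#' `CL_tot = D / AUC_inf` with the dose converted to nmol/kg
#' (`dose_mg_per_kg * 1e6 / mw`), so nmol/kg over nmol·mL^-1·min gives
#' mL/min/kg.
#'
#' @param dose_mg_per_kg IV bolus dose, mg/kg.
#' @param mw Molecular weight, g/mol.
#' @param auc_inf AUC extrapolated to infinity, µM·min.
#' @return Total clearance, mL/min/kg. A zero dose returns 0.
#' @examples
#' cl_total(10, 347.39, 2770) # cephalexin 10 mg/kg
#' @export
cl_total <- function(dose_mg_per_kg, mw, auc_inf) {
  if (dose_mg_per_kg == 0) return(0)
  if (mw <= 0) abort("`mw` must be positive.", class = "renalpk_validation_error")
  if (!is.finite(auc_inf) || auc_inf <= 0) {
    abort("`auc_inf` must be positive to compute a clearance.",
          class = "renalpk_division_error")
  }
  (dose_mg_per_kg * 1e6 / mw) / auc_inf
}

#' Cumulative urinary amount over a window, with coverage check
#'
#' Sums interval urinary amounts over `[window[1], window[2]]` and errors if
#' the collection intervals leave a gap inside the window.
#'
#' @param urine A data frame with columns `t_start_min`, `t_end_min`,
#'   `amount_nmol_per_kg` for one subject and analyte.
#' @param window Length-2 numeric window, min.
#' @return Cumulative amount, nmol/kg.
#' @export
cumulative_urine <- function(urine, window = c(0, 240)) {
  need <- c("t_start_min", "t_end_min", "amount_nmol_per_kg")
  if (!all(need %in% names(urine))) {
    abort(paste0("`urine` must have columns ", paste(need, collapse = ", "), "."),
          class = "renalpk_validation_error")
  }
  u <- urine[order(urine$t_start_min), , drop = FALSE]
  sel <- u$t_start_min >= window[1] - 1e-9 & u$t_end_min <= window[2] + 1e-9
  u <- u[sel, , drop = FALSE]
  bounds <- c(window[1], u$t_end_min)
  starts <- c(u$t_start_min, window[2])
  gaps <- which(starts - bounds > 1e-9)
  if (length(gaps) > 0L) {
    gap_txt <- paste(sprintf("[%g, %g]", bounds[gaps], starts[gaps]),
                     collapse = ", ")
    abort(paste0("urine collections do not cover the window; missing span(s): ",
                 gap_txt),
          class = "renalpk_coverage_error")
  }
  sum(u$amount_nmol_per_kg)
}

#' Renal clearance from urinary excretion and AUC
#'
#' `CL_R = X_urine / AUC` over the same window: nmol/kg over
#' nmol·mL^-1·min gives mL/min/kg.
#'
#' @param x_urine_nmol_per_kg Cumulative urinary amount over the window
#'   (see [cumulative_urine()]).
#' @param auc_window AUC over the same window, µM·min.
#' @return Renal clearance, mL/min/kg.
#' @examples
#' cl_renal(10000, 1000) # 10 mL/min/kg
#' @export
cl_renal <- function(x_urine_nmol_per_kg, auc_window) {
  if (!is.finite(auc_window) || auc_window <= 0) {
    abort("`auc_window` must be positive to compute a renal clearance.",
          class = "renalpk_division_error")
  }
  if (x_urine_nmol_per_kg < 0) {
    abort("urinary amount must be non-negative.",
          class = "renalpk_validation_error")
  }
  x_urine_nmol_per_kg / auc_window
}

#' Urinary recovery as percent of dose
#'
#' @inheritParams cl_renal
#' @inheritParams cl_total
#' @return Percent of the administered dose recovered in urine.
#' @export
urinary_recovery <- function(x_urine_nmol_per_kg, dose_mg_per_kg, mw) {
  if (dose_mg_per_kg <= 0) {
    abort("urinary recovery is undefined without a dose (endogenous analyte).",
          class = "renalpk_undefined_recovery")
  }
  100 * x_urine_nmol_per_kg / (dose_mg_per_kg * 1e6 / mw)
}

#' Kidney-to-plasma partition coefficient
#'
#' `K_p,kidney = C_kidney / C_plasma` at the terminal sampling time.
#'
#' @param c_kidney Kidney tissue concentration, µM (per mL tissue).
#' @param c_plasma Plasma concentration at the same time, µM.
#' @return Dimensionless ratio.
#' @export
kp_kidney <- function(c_kidney, c_plasma) {
  if (any(!is.finite(c_plasma)) || any(c_plasma <= 0)) {
    abort("`c_plasma` must be positive: the tissue-to-plasma ratio is undefined otherwise.",
          class = "renalpk_undefined_ratio")
  }
  c_kidney / c_plasma
}

#' Renal clearance ratio and secretion/reabsorption classification
#'
#' Computes `(CL_R / fu) / CL_inulin`, the renal clearance of unbound drug
#' normalized to the glomerular filtration rate (inulin clearance). A ratio
#' above 1 indicates net tubular secretion, below 1 net reabsorption.
#' Classification uses a band of half-width `epsilon` around 1
#' (`epsilon = 0` restores the strict > 1 / < 1 rule).
#'
#' @param cl_r Renal clearance, mL/min/kg (vectorized).
#' @param fu Unbound plasma fraction, in (0, 1].
#' @param cl_inulin Inulin clearance (GFR), mL/min/kg, > 0.
#' @param epsilon Half-width of the indeterminate band around 1.
#' @return A tibble with columns `ratio` and `classification`
#'   (`"net-secretion"`, `"net-reabsorption"` or `"indeterminate"`).
#' @examples
#' clearance_ratio(7.96, 0.82, 6.72) # 1.44, net-secretion
#' clearance_ratio(2.87, 0.82, 5.36) # 0.65, net-reabsorption
#' @export
clearance_ratio <- function(cl_r, fu, cl_inulin, epsilon = 0.05) {
  if (any(!is.finite(fu)) || any(fu <= 0) || any(fu > 1)) {
    abort("`fu` must lie in (0, 1].", class = "renalpk_validation_error")
  }
  if (any(!is.finite(cl_inulin)) || any(cl_inulin <= 0)) {
    abort("`cl_inulin` must be positive.", class = "renalpk_validation_error")
  }
  if (epsilon < 0) {
    abort("`epsilon` must be non-negative.", class = "renalpk_validation_error")
  }
  ratio <- (cl_r / fu) / cl_inulin
  classification <- dplyr::case_when(
    ratio > 1 + epsilon ~ "net-secretion",
    ratio < 1 - epsilon ~ "net-reabsorption",
    .default = "indeterminate")
  tibble::tibble(ratio = ratio, classification = classification)
}

#' Fold change of a case-group mean over the control mean
#'
#' @param mean_case,mean_control Group means of any PK parameter.
#' @return `mean_case / mean_control` (unrounded; reports round to 2
#'   decimals).
#' @examples
#' fold_change(90.3, 16.6) # 5.44 after rounding
#' @export
fold_change <- function(mean_case, mean_control) {
  if (any(!is.finite(mean_control)) || any(mean_control == 0)) {
    abort("`mean_control` must be non-zero.",
          class = "renalpk_validation_error")
  }
  mean_case / mean_control
}
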