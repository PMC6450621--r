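#' Group mean with standard error
#'
#' @param values Numeric vector, n >= 1.
#' @return One-row tibble: `n`, `mean`, `sem` (sd with n-1 denominator over
#'   sqrt(n); 0 with a warning when n = 1).
#' @examples
#' mean_sem(c(1, 2, 3))
#' @export
mean_sem <- function(values) {
  if (length(values) < 1L || any(!is.finite(values))) {
    abort("`values` must be a non-empty finite numeric vector.",
          class = "renalpk_validation_error")
  }
  n <- length(values)
  sem <- if (n == 1L) {
    warn("n = 1: SEM reported as 0.")
    0
  } else {
    sd(values) / sqrt(n)
  }
  tibble::tibble(n = n, mean = mean(values), sem = sem)
}

#' Unpaired two-sample t-test
#'
#' Classic pooled-variance (Student) two-sided test by default,
#' `df = n_a + n_b - 2`; set `var_equal = FALSE` for the Welch variant.
#' Degenerate inputs (zero pooled variance) return p = 1 with a warning if
#' the means agree, and raise an error otherwise.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @param var_equal Pool the variances (default TRUE).
#' @return One-row tibble: `t`, `df`, `p`.
#' @examples
#' students_t_unpaired(c(1, 2, 3), c(4, 5, 6))
#' @export
students_t_unpaired <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("both groups need at least 2 observations.",
          class = "renalpk_validation_error")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      warn("zero variance in both groups with equal means: p = 1.")
      return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    abort("zero variance in both groups with unequal means: t is degenerate.",
          class = "renalpk_degenerate_variance")
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment group with a shared control, controlling the
#' familywise error rate under the Dunnett multivariate-t null. Test
#' statistics use the variance pooled across all groups
#' (`df = N - k - 1` for k treatments); the null distribution of
#' `max_j |T_j|` is evaluated by seeded Monte Carlo simulation of the group
#' means and the pooled variance, and each adjusted p-value is the null
#' exceedance probability of the observed |t|. With `n_draws = 1e5` the
#' Monte-Carlo standard error of a p-value near 0.05 is about 0.0007.
#'
#' @param control Numeric vector of control observations.
#' @param treatments Named list of numeric vectors, one per treatment
#'   group. Balanced and unbalanced designs are both supported.
#' @param alpha Nominal familywise level (only reported alongside the
#'   decision column).
#' @param n_draws Monte-Carlo draws for the null max-|t| distribution.
#' @param seed RNG seed of the draw.
#' @return A tibble with one row per treatment: `treatment`, `n`,
#'   `mean_diff`, `t`, `p_unadjusted` (two-sided pooled-df t),
#'   `p_adjusted`, `significant` (at `alpha`).
#' @examples
#' set.seed(1)
#' dunnett_many_to_one(rnorm(5), list(a = rnorm(5), b = rnorm(5, 2)))
#' @export
dunnett_many_to_one <- function(control, treatments, alpha = 0.05,
                                n_draws = 1e5, seed = 1L) {
  if (!is.list(treatments) || length(treatments) < 1L) {
    abort("`treatments` must be a non-empty list of numeric vectors.",
          class = "renalpk_validation_error")
  }
  if (is.null(names(treatments)) || any(!nzchar(names(treatments)))) {
    names(treatments) <- paste0("treatment_", seq_along(treatments))
  }
  groups <- c(list(control = control), treatments)
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    abort("every group needs at least 2 observations for a pooled variance.",
          class = "renalpk_validation_error")
  }
  k <- length(treatments)
  n0 <- ns[1]
  nt <- ns[-1]
  df_err <- sum(ns) - (k + 1L)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  s2 <- ss / df_err
  if (s2 <= 0) {
    abort("zero pooled variance across all groups.",
          class = "renalpk_degenerate_variance")
  }
  mean_diff <- vapply(treatments, mean, 0) - mean(control)
  se <- sqrt(s2 * (1 / nt + 1 / n0))
  t_obs <- mean_diff / se

  max_t <- dunnett_null_max_t(n0, nt, df_err, n_draws, seed)
  p_adj <- vapply(abs(t_obs), function(tt) mean(max_t >= tt), 0)
  p_un <- 2 * pt(-abs(t_obs), df_err)

  tibble::tibble(treatment = names(treatments), n = as.integer(nt),
                 mean_diff = unname(mean_diff), t = unname(t_obs),
                 p_unadjusted = unname(p_un),
                 p_adjusted = unname(pmax(p_adj, p_un)),
                 significant = unname(pmax(p_adj, p_un) < alpha))
}

# Null draw of max_j |T_j| under the Dunnett many-to-one setting:
# independent group means, shared chi-squared pooled variance.
dunnett_null_max_t <- function(n0, nt, df_err, n_draws = 1e5, seed = 1L) {
  set.seed(as.integer(seed))
  z0 <- rnorm(n_draws, 0, 1 / sqrt(n0))
  s_draw <- sqrt(rchisq(n_draws, df_err) / df_err)
  max_t <- rep(0, n_draws)
  for (j in seq_along(nt)) {
    zj <- rnorm(n_draws, 0, 1 / sqrt(nt[j]))
    tj <- abs(zj - z0) / (s_draw * sqrt(1 / nt[j] + 1 / n0))
    max_t <- pmax(max_t, tj)
  }
  max_t
}
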