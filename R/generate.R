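#' Generate a synthetic qPCR Ct table
#'
#' Builds a sample-by-gene Ct table for a two-group design such that the
#' delta-delta-Ct estimator ([delta_delta_ct()]) recovers the supplied
#' case/control expression ratios (amplification efficiency fixed at 2, i.e.
#' one cycle per two-fold change). Per-well Gaussian noise on the Ct scale
#' emulates technical and biological scatter. The reference gene is
#' generated with ratio 1 by construction.
#'
#' @param true_ratios Named numeric vector of case/control expression ratios
#'   per gene (all > 0). Names are gene labels.
#' @param n_per_group Samples per group.
#' @param noise_sd_ct Standard deviation of per-well Ct noise, cycles.
#' @param seed RNG seed.
#' @param reference_gene Reference gene label (default "Gapdh").
#' @param groups Length-2 character vector: control label first.
#' @param base_ct Mean control-group Ct of every target gene (the estimator
#'   is invariant to it); `base_ct_ref` likewise for the reference gene.
#' @param base_ct_ref Mean reference-gene Ct.
#'
#' @return A tibble with columns `sample_id`, `group`, `gene`, `ct`.
#' @examples
#' ct <- generate_qpcr(c(Mate1 = 0.6, Oct2 = 0.7), n_per_group = 4,
#'                     noise_sd_ct = 0, seed = 1)
#' delta_delta_ct(ct)
#' @export
generate_qpcr <- function(true_ratios, n_per_group, noise_sd_ct = 0.2,
                          seed = 1L, reference_gene = "Gapdh",
                          groups = c("control", "hyperuricemia"),
                          base_ct = 24, base_ct_ref = 18) {
  if (is.null(names(true_ratios)) || any(!nzchar(names(true_ratios)))) {
    abort("`true_ratios` must be a named vector of per-gene ratios.",
          class = "renalpk_validation_error")
  }
  if (any(!is.finite(true_ratios)) || any(true_ratios <= 0)) {
    abort("all `true_ratios` must be finite and > 0.",
          class = "renalpk_validation_error")
  }
  if (reference_gene %in% names(true_ratios)) {
    abort("the reference gene is generated with ratio 1 by construction; do not list it in `true_ratios`.",
          class = "renalpk_validation_error")
  }
  set.seed(as.integer(seed))
  genes <- c(names(true_ratios), reference_gene)
  log2_shift <- c(log2(true_ratios), 0)
  names(log2_shift) <- genes
  rows <- list()
  k <- 0L
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", substr(groups[g], 1, 3), i)
      base <- ifelse(genes == reference_gene, base_ct_ref, base_ct)
      shift <- if (g == 2L) -log2_shift else 0 # lower Ct = higher expression
      rows[[k]] <- tibble::tibble(
        sample_id = sid, group = groups[g], gene = genes,
        ct = base + shift + rnorm(length(genes), 0, noise_sd_ct))
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate synthetic transporter-uptake assay records
#'
#' Emulates an inhibition experiment on transporter-expressing versus mock
#' (vector-only) cells. Mock cells carry only the background (passive)
#' cell-to-medium ratio; expressing cells additionally carry the
#' transporter-mediated component, scaled down by a per-treatment inhibition
#' fraction. Noise is multiplicative lognormal.
#'
#' @param mate1_component Transporter-mediated cell-to-medium ratio in the
#'   untreated expressing cells, µL/mg protein.
#' @param background Background cell-to-medium ratio common to both cell
#'   lines, µL/mg protein.
#' @param inhibition_fraction Named numeric vector in `[0, 1]` per treatment;
#'   include a `control = 0` entry for the untreated wells.
#' @param n Replicates per cell line and treatment.
#' @param noise_cv Multiplicative lognormal CV of the measured ratios.
#' @param seed RNG seed.
#' @param medium_conc_pmol_per_uL Substrate concentration in the transport
#'   medium (default 0.00025 pmol/µL, i.e. 0.25 nM).
#'
#' @return A tibble with columns `cell_line` ("expressing"/"mock"),
#'   `treatment`, `replicate`, `amount_pmol_per_mg`,
#'   `medium_conc_pmol_per_uL`.
#' @examples
#' up <- generate_uptake(180, 20, c(control = 0, cimetidine = 0.918),
#'                       n = 3, noise_cv = 0, seed = 1)
#' uptake_percent_of_control(up)
#' @export
generate_uptake <- function(mate1_component, background,
                            inhibition_fraction, n, noise_cv = 0.1,
                            seed = 1L,
                            medium_conc_pmol_per_uL = 0.00025) {
  if (mate1_component < 0 || background < 0) {
    abort("`mate1_component` and `background` must be non-negative.",
          class = "renalpk_validation_error")
  }
  if (is.null(names(inhibition_fraction))) {
    abort("`inhibition_fraction` must be named by treatment.",
          class = "renalpk_validation_error")
  }
  if (any(inhibition_fraction < 0 | inhibition_fraction > 1)) {
    abort("`inhibition_fraction` entries must lie in [0, 1].",
          class = "renalpk_validation_error")
  }
  set.seed(as.integer(seed))
  grid <- tidyr::expand_grid(
    cell_line = c("expressing", "mock"),
    treatment = names(inhibition_fraction),
    replicate = seq_len(n))
  inh <- inhibition_fraction[grid$treatment]
  true_ratio <- ifelse(grid$cell_line == "mock", background,
                       background + (1 - inh) * mate1_component)
  ratio <- true_ratio * lnorm_factor(nrow(grid), noise_cv)
  tibble::tibble(
    cell_line = grid$cell_line, treatment = grid$treatment,
    replicate = grid$replicate,
    amount_pmol_per_mg = ratio * medium_conc_pmol_per_uL,
    medium_conc_pmol_per_uL = medium_conc_pmol_per_uL)
}
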