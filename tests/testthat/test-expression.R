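test_that("identical Ct tables give relative expression 1 everywhere", {
  ct <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                           gene = c("Mate1", "Gapdh")) |>
    dplyr::mutate(group = rep(c("control", "hyperuricemia"), each = 6),
                  ct = 22)
  out <- delta_delta_ct(ct)
  expect_equal(out$rel_expr, rep(1, nrow(out)))
})

test_that("a one-cycle Ct shift halves the relative expression", {
  ct <- tibble::tibble(
    sample_id = c("c1", "c2", "h1", "h2"),
    group = rep(c("control", "hyperuricemia"), each = 2),
    gene = "Mate1",
    ct = c(24, 24, 25, 25)) |>
    dplyr::bind_rows(tibble::tibble(
      sample_id = c("c1", "c2", "h1", "h2"),
      group = rep(c("control", "hyperuricemia"), each = 2),
      gene = "Gapdh", ct = 18))
  out <- delta_delta_ct(ct)
  expect_equal(out$rel_expr[out$group == "hyperuricemia"], c(0.5, 0.5))
  expect_equal(out$rel_expr[out$group == "control"], c(1, 1))
})

test_that("delta-delta-Ct matches the brute-force oracle on random tables", {
  set.seed(7)
  for (rep in 1:5) {
    ct <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                             gene = c("Mate1", "Oct2", "Oat1", "Gapdh")) |>
      dplyr::mutate(group = ifelse(.data$sample_id %in% paste0("s", 1:3),
                                   "control", "hyperuricemia"),
                    ct = runif(dplyr::n(), 15, 32))
    out <- delta_delta_ct(ct)
    oracle <- oracle_ddct(ct, "Gapdh", "control")
    j <- dplyr::inner_join(out, oracle, by = c("gene", "sample_id"),
                           suffix = c("", "_o"))
    expect_equal(nrow(j), nrow(out))
    expect_equal(j$rel_expr, j$rel_expr_o, tolerance = 1e-12)
  }
})

test_that("relative expression is invariant to per-sample Ct shifts and fixes the reference at 1", {
  set.seed(8)
  ct <- tidyr::expand_grid(sample_id = paste0("s", 1:6),
                           gene = c("Mate1", "Gapdh")) |>
    dplyr::mutate(group = ifelse(.data$sample_id %in% paste0("s", 1:3),
                                 "control", "hyperuricemia"),
                  ct = runif(dplyr::n(), 18, 30))
  out <- delta_delta_ct(ct)
  shifts <- setNames(runif(6, -3, 3), paste0("s", 1:6))
  ct2 <- dplyr::mutate(ct, ct = ct + shifts[.data$sample_id])
  out2 <- delta_delta_ct(ct2)
  expect_equal(out2$rel_expr, out$rel_expr, tolerance = 1e-12)

  # the reference gene, analyzed as a target, sits at 1 for every sample
  ct3 <- dplyr::bind_rows(ct, dplyr::mutate(
    dplyr::filter(ct, .data$gene == "Gapdh"), gene = "Gapdh_as_target"))
  ct3$ct[ct3$gene == "Gapdh_as_target"] <-
    ct3$ct[ct3$gene == "Gapdh"] # identical replicate of the reference
  out3 <- delta_delta_ct(ct3)
  expect_equal(out3$rel_expr[out3$gene == "Gapdh_as_target"], rep(1, 6))
})

test_that("missing reference gene or unknown control label raise addressed errors", {
  ct <- tibble::tibble(sample_id = c("a", "a", "b"),
                       group = c("control", "control", "hyperuricemia"),
                       gene = c("Mate1", "Gapdh", "Mate1"),
                       ct = c(24, 18, 25))
  expect_error(delta_delta_ct(ct), "b", class = "renalpk_validation_error")
  ct_ok <- dplyr::bind_rows(ct, tibble::tibble(
    sample_id = "b", group = "hyperuricemia", gene = "Gapdh", ct = 18))
  expect_error(delta_delta_ct(ct_ok, control_group = "nope"),
               class = "renalpk_configuration_error")
})

test_that("technical replicates average on the Ct scale before dCt", {
  ct <- tibble::tibble(
    sample_id = c("c1", "c1", "c1", "h1", "h1"),
    group = c("control", "control", "control",
              "hyperuricemia", "hyperuricemia"),
    gene = c("Mate1", "Mate1", "Gapdh", "Mate1", "Gapdh"),
    ct = c(23, 25, 18, 25, 18)) # replicate mean 24 in control
  out <- delta_delta_ct(ct)
  expect_equal(out$rel_expr[out$group == "hyperuricemia"], 0.5)
})

test_that("generated Ct tables recover the configured expression ratios", {
  # noiseless: exact recovery
  ct0 <- generate_qpcr(c(Mate1 = 0.5, Oct2 = 1), n_per_group = 3,
                       noise_sd_ct = 0, seed = 1)
  # noiseless ratio-1 gene triggers the degenerate equal-means warning
  s0 <- suppressWarnings(expression_summary(delta_delta_ct(ct0)))
  expect_equal(
    s0$ratio_to_control[s0$gene == "Mate1" & s0$group == "hyperuricemia"],
    0.5, tolerance = 1e-12)
  # Monte-Carlo consistency at n = 200
  ct <- generate_qpcr(c(Mate1 = 0.6), n_per_group = 200,
                      noise_sd_ct = 0.2, seed = 20)
  s <- expression_summary(delta_delta_ct(ct))
  ratio <- s$ratio_to_control[s$gene == "Mate1" & s$group == "hyperuricemia"]
  expect_lt(abs(ratio - 0.6) / 0.6, 0.05)
  expect_error(generate_qpcr(c(Mate1 = -1), 3),
               class = "renalpk_validation_error")
})
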