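# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Well-stirred organ clearance of the secretory pathway in the linear
# carrier regime, referred to the post-glomerular plasma flow Q' = Q - GFR
# and unbound drug: CL_sec = fu Q' CLint / (Q' + CLint). Filtration adds
# fu * GFR on top (it acts on systemic plasma, upstream of the peritubular
# exchange), so the total caps at fu * Q for any carrier capacity.
oracle_well_stirred_cl <- function(q, fu, clint_sec, gfr) {
  qp <- q - gfr
  fu * gfr + fu * qp * clint_sec / (qp + clint_sec)
}

# Brute-force relative expression: per sample, 2^-(dCt - mean dCt of the
# control group), computed with explicit loops.
oracle_ddct <- function(ct_tbl, reference_gene, control_group) {
  samples <- unique(ct_tbl$sample_id)
  genes <- setdiff(unique(ct_tbl$gene), reference_gene)
  dct <- function(s, g) {
    ct_g <- mean(ct_tbl$ct[ct_tbl$sample_id == s & ct_tbl$gene == g])
    ct_r <- mean(ct_tbl$ct[ct_tbl$sample_id == s &
                             ct_tbl$gene == reference_gene])
    ct_g - ct_r
  }
  out <- list()
  for (g in genes) {
    ctrl_samples <- unique(ct_tbl$sample_id[ct_tbl$group == control_group])
    base <- mean(vapply(ctrl_samples, dct, 0, g = g))
    for (s in samples) {
      grp <- ct_tbl$group[ct_tbl$sample_id == s][1]
      out[[paste(g, s)]] <- data.frame(
        gene = g, sample_id = s, group = grp,
        rel_expr = 2^-(dct(s, g) - base))
    }
  }
  do.call(rbind, out)
}

# Pooled-variance two-sample t statistic, written out longhand.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, df = na + nb - 2, p = 2 * pt(-abs(tt), na + nb - 2))
}

# Default physiology pairings for the preset drugs (documented volumes).
phys_metformin <- function() physiology_params(v_central = 1000)
phys_cephalexin <- function() physiology_params(v_central = 250)
phys_creatinine <- function() physiology_params(v_central = 600)
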