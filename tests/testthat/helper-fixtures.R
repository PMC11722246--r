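# In-code fixtures shared across test files.

# A small valid summary-statistics data.frame. Betas/SEs give exactly
# consistent two-sided normal p-values.
toy_sumstats_df <- function(n = 5, chrom = "1", start_pos = 1e6,
                            beta = NULL, se = NULL,
                            effect_allele = NULL, other_allele = NULL,
                            eaf = NULL, rsid = NULL, n_samples = 10000) {
  beta <- beta %||% seq(-0.1, 0.1, length.out = n)
  se <- se %||% rep(0.02, n)
  data.frame(
    rsid = rsid %||% sprintf("rs%d", seq_len(n)),
    chrom = chrom,
    pos = start_pos + (seq_len(n) - 1L) * 1000,
    effect_allele = effect_allele %||% rep("A", n),
    other_allele = other_allele %||% rep("G", n),
    eaf = eaf %||% rep(0.3, n),
    beta = beta,
    se = se,
    p = 2 * pnorm(-abs(beta / se)),
    n = n_samples,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

pp_vector <- function(res) {
  c(res$pph0, res$pph1, res$pph2, res$pph3, res$pph4)
}

# Rebuild the b-side of a harmonised pair as a sumstats table (used for
# involution checks).
harmonised_b_as_sumstats <- function(pair) {
  d <- pair$data
  sumstats(
    data.frame(
      rsid = d$rsid, chrom = d$chrom, pos = d$pos,
      effect_allele = d$effect_allele, other_allele = d$other_allele,
      eaf = d$eaf_b, beta = d$beta_b, se = d$se_b, p = d$p_b, n = d$n_b,
      stringsAsFactors = FALSE
    ),
    trait = pair$meta_b$trait %||% "b", ancestry = "EUR",
    type = pair$meta_b$type %||% "gwas"
  )
}

# Swap every allele pair of a table, negating betas and complementing
# frequencies (an equivalent representation of the same associations).
flip_all_alleles <- function(x) {
  d <- x$data
  tmp <- d$effect_allele
  d$effect_allele <- d$other_allele
  d$other_allele <- tmp
  d$beta <- -d$beta
  d$eaf <- 1 - d$eaf
  x$data <- d
  x
}
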