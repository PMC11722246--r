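test_that("make_ld builds the AR(1) correlation family", {
  # independence case
  ld0 <- make_ld(3, rho = 0)
  expect_equal(ld0$correlation, diag(3))
  # adjacent correlation is rho by definition
  ld2 <- make_ld(2, rho = 0.9)
  expect_equal(ld2$correlation[1, 2], 0.9)
  expect_equal(ld2$correlation[2, 1], 0.9)
  # positive semi-definiteness (eigendecomposition oracle)
  ld5 <- make_ld(5, rho = 0.5)
  expect_true(min(eigen(ld5$correlation, symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-10)
  expect_equal(ld5$correlation, t(ld5$correlation))
  expect_equal(diag(ld5$correlation), rep(1, 5))
  # positions strictly increasing, rsids unique
  expect_true(all(diff(ld5$positions) > 0))
  expect_false(anyDuplicated(ld5$rsids) > 0)
  # domain errors
  expect_error(make_ld(3, rho = 1), "rho")
  expect_error(make_ld(3, rho = -0.1), "rho")
  expect_error(make_ld(0, rho = 0.5))
})

test_that("scenario_spec enforces hypothesis/causal-index consistency", {
  expect_error(scenario_spec("H0", causal_index_trait1 = 3), "H0")
  expect_error(scenario_spec("H3", causal_index_trait1 = 3,
                             causal_index_trait2 = 3), "distinct")
  expect_error(scenario_spec("H4", causal_index_trait1 = 3,
                             causal_index_trait2 = 4), "equal")
  # H4 shorthand: one shared index
  sc <- scenario_spec("H4", causal_index_trait1 = 3)
  expect_equal(sc$causal_index_trait2, 3)
  expect_error(scenario_spec("H1", causal_index_trait1 = 3,
                             variance_explained_trait1 = 1.2), "\\[0, 1\\)")
})

test_that("simulated null z-scores are centred on zero", {
  ld <- make_ld(100, rho = 0.9, seed = 5)
  sc <- scenario_spec("H0")
  reps <- 400
  zbar <- rowMeans(vapply(seq_len(reps), function(i) {
    p <- simulate_locus_pair(ld, sc, seed = 1000 + i)
    p$trait1$data$beta / p$trait1$data$se
  }, numeric(ld$n_snps)))
  # each z has unit variance, so the replicate mean has SE 1/sqrt(reps);
  # at least 99% of per-SNP means must sit inside the 3-SE band, and the
  # overall mean must too
  expect_gte(mean(abs(zbar) < 3 / sqrt(reps)), 0.99)
  expect_lt(abs(mean(zbar)), 3 / sqrt(reps))
})

test_that("H4 causal z matches the closed-form simulating mean", {
  ld <- make_ld(50, rho = 0.9, seed = 6)
  sc <- scenario_spec("H4", causal_index_trait1 = 25,
                      variance_explained_trait1 = 0.005,
                      variance_explained_trait2 = 0.005,
                      n_trait1 = 10000, n_trait2 = 10000)
  expected <- sqrt(10000 * 0.005 / 0.995)  # ~ 7.09
  reps <- 500
  z_causal <- vapply(seq_len(reps), function(i) {
    p <- simulate_locus_pair(ld, sc, seed = 2000 + i)
    (p$trait1$data$beta / p$trait1$data$se)[25]
  }, numeric(1))
  expect_lt(abs(mean(z_causal) - expected), 3 / sqrt(reps))
})

test_that("locus-pair simulation is deterministic and on the stated scale", {
  ld <- make_ld(40, rho = 0.5, seed = 2)
  sc <- scenario_spec("H4", causal_index_trait1 = 20)
  a <- simulate_locus_pair(ld, sc, seed = 99)
  b <- simulate_locus_pair(ld, sc, seed = 99)
  expect_identical(a$trait1$data, b$trait1$data)
  expect_identical(a$trait2$data, b$trait2$data)
  # SE = 1/sqrt(n) exactly; beta/se reproduces z via p
  expect_identical(a$trait1$data$se, rep(1 / sqrt(sc$n_trait1), 40))
  z <- a$trait1$data$beta / a$trait1$data$se
  expect_equal(a$trait1$data$p, 2 * pnorm(-abs(z)))
  # shared rsids/positions and shared frequencies by default
  expect_identical(a$trait1$data$rsid, a$trait2$data$rsid)
  expect_identical(a$trait1$data$eaf, a$trait2$data$eaf)
  # cross-ancestry flag re-draws trait-2 frequencies
  cx <- simulate_locus_pair(ld, sc, seed = 99, shared_eaf = FALSE)
  expect_false(identical(cx$trait1$data$eaf, cx$trait2$data$eaf))
})

test_that("shared-sign controls the cross-trait z correlation", {
  ld <- make_ld(60, rho = 0.9, seed = 7)
  corr_for <- function(sign, seed) {
    sc <- scenario_spec("H4", causal_index_trait1 = 30, shared_sign = sign)
    p <- simulate_locus_pair(ld, sc, seed = seed)
    cor(p$trait1$data$beta, p$trait2$data$beta)
  }
  pos <- vapply(1:100, function(i) corr_for(1, 3000 + i), numeric(1))
  neg <- vapply(1:100, function(i) corr_for(-1, 4000 + i), numeric(1))
  expect_gt(mean(pos > 0), 0.95)
  expect_gt(mean(neg < 0), 0.95)
})

test_that("Dirichlet concentration controls realised specificity", {
  # very small concentration: near one-hot rows, tau ~ 1
  tau_small <- vapply(1:200, function(i) {
    em <- simulate_expression(1, concentration = 0.01, seed = i)
    tau(em$tpm[1, ])
  }, numeric(1))
  expect_gte(mean(tau_small >= 0.9), 0.95)
  # very large concentration: near uniform rows, tau ~ 0
  tau_large <- vapply(1:200, function(i) {
    em <- simulate_expression(1, concentration = 1e4, seed = i)
    tau(em$tpm[1, ])
  }, numeric(1))
  expect_gte(mean(tau_large <= 0.1), 0.95)
  # mean tau is monotone decreasing over a concentration grid
  grid <- c(0.05, 0.5, 5, 50)
  mean_tau <- vapply(grid, function(conc) {
    mean(vapply(1:60, function(i) {
      tau(simulate_expression(1, concentration = conc, seed = 500 + i)$tpm[1, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_tau) < 0))
  # degenerate inputs
  expect_error(simulate_expression(0), "positive")
  expect_error(simulate_expression(2, concentration = 0), "positive")
  # determinism and shape
  a <- simulate_expression(5, seed = 3)
  b <- simulate_expression(5, seed = 3)
  expect_identical(a$tpm, b$tpm)
  expect_equal(dim(a$tpm), c(5L, 66L))
})

test_that("phenotype-QTL simulation matches its Bernoulli law", {
  genes <- sprintf("G%02d", 1:39)
  full <- simulate_phenoqtl_table(genes, hit_probability = 1,
                                  ancestries = "EUR", seed = 1)
  expect_equal(nrow(full), 39 * 4)
  none <- simulate_phenoqtl_table(genes, hit_probability = 0,
                                  ancestries = "EUR", seed = 1)
  expect_equal(nrow(none), 0)
  # binomial oracle: per-metric overlap proportion averages to 0.5
  reps <- 400
  props <- vapply(seq_len(reps), function(i) {
    tab <- simulate_phenoqtl_table(genes, hit_probability = 0.5,
                                   ancestries = "EUR", seed = 5000 + i)
    ov <- phenoqtl_overlap(genes, tab)
    ov$proportion[ov$metric == "monocyte"]
  }, numeric(1))
  se <- sqrt(0.25 / (39 * reps))
  expect_lt(abs(mean(props) - 0.5), 3 * se)
  # unknown gene labels rejected against a catalog
  cat <- load_gene_catalog()
  expect_error(
    simulate_phenoqtl_table(c("BIN1", "NOT_A_GENE"), catalog = cat),
    "NOT_A_GENE")
  # determinism
  expect_identical(
    simulate_phenoqtl_table(genes, seed = 7),
    simulate_phenoqtl_table(genes, seed = 7))
})
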