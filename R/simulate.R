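#' Specify a ground-truth colocalisation scenario
#'
#' Describes the causal configuration of a simulated locus pair under one
#' of the five colocalisation hypotheses: H0 (neither trait associated),
#' H1/H2 (only trait 1 / only trait 2), H3 (two distinct causal variants),
#' H4 (one shared causal variant).
#'
#' @param hypothesis One of \code{"H0"}, \code{"H1"}, \code{"H2"},
#'   \code{"H3"}, \code{"H4"}.
#' @param causal_index_trait1,causal_index_trait2 1-based SNP indices of
#'   the causal variants, or \code{NA} where the hypothesis has none. For
#'   H4 a single shared index may be given as \code{causal_index_trait1}.
#' @param variance_explained_trait1,variance_explained_trait2 Fraction of
#'   trait variance explained by the causal variant, in \code{[0, 1)}.
#' @param n_trait1,n_trait2 Study sample sizes.
#' @param shared_sign Direction (+1/-1) of the trait-2 effect relative to
#'   trait 1 at a shared (H4) causal variant.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(hypothesis,
                          causal_index_trait1 = NA_integer_,
                          causal_index_trait2 = NA_integer_,
                          variance_explained_trait1 = 0.01,
                          variance_explained_trait2 = 0.01,
                          n_trait1 = 10000, n_trait2 = 10000,
                          shared_sign = 1) {
  hypothesis <- match.arg(hypothesis, c("H0", "H1", "H2", "H3", "H4"))
  if (!shared_sign %in% c(-1, 1)) stop("`shared_sign` must be +1 or -1")
  for (v in c(variance_explained_trait1, variance_explained_trait2)) {
    if (!is.na(v) && (v < 0 || v >= 1)) {
      stop("variance explained must lie in [0, 1)")
    }
  }
  c1 <- causal_index_trait1
  c2 <- causal_index_trait2
  switch(hypothesis,
    H0 = {
      if (!is.na(c1) || !is.na(c2)) stop("H0 admits no causal variants")
    },
    H1 = {
      if (is.na(c1) || !is.na(c2)) stop("H1 needs a trait-1 causal index only")
    },
    H2 = {
      if (!is.na(c1) || is.na(c2)) stop("H2 needs a trait-2 causal index only")
    },
    H3 = {
      if (is.na(c1) || is.na(c2) || c1 == c2) {
        stop("H3 needs two distinct causal indices")
      }
    },
    H4 = {
      if (is.na(c1)) stop("H4 needs a causal index")
      if (is.na(c2)) c2 <- c1
      if (c1 != c2) stop("H4 requires equal causal indices")
    }
  )
  structure(
    list(hypothesis = hypothesis,
         causal_index_trait1 = c1, causal_index_trait2 = c2,
         variance_explained_trait1 = variance_explained_trait1,
         variance_explained_trait2 = variance_explained_trait2,
         n_trait1 = n_trait1, n_trait2 = n_trait2,
         shared_sign = shared_sign),
    class = "scenario_spec"
  )
}

## Marginal mean of z-scores: R %*% lambda with a single spike at the
## causal SNP of height sqrt(n v / (1 - v)).
causal_lambda <- function(ld, index, n, v, sign = 1) {
  lambda <- numeric(ld$n_snps)
  if (!is.na(index)) {
    if (index < 1 || index > ld$n_snps) {
      stop("causal index out of range (1..", ld$n_snps, ")")
    }
    lambda[index] <- sign * sqrt(n * v / (1 - v))
  }
  lambda
}

## Assemble a sumstats object from simulated z-scores on the standardized
## scale (per-SNP SE = 1/sqrt(n), beta = z * SE).
zscores_to_sumstats <- function(z, n, ld, eaf, alleles, ...) {
  se <- rep(1 / sqrt(n), ld$n_snps)
  beta <- z * se
  sumstats(
    data.frame(
      rsid = ld$rsids, chrom = ld$chrom, pos = ld$positions,
      effect_allele = alleles$effect, other_allele = alleles$other,
      eaf = eaf, beta = beta, se = se,
      p = 2 * stats::pnorm(-abs(z)), n = n,
      stringsAsFactors = FALSE
    ),
    ...
  )
}

#' Simulate a pair of LD-structured summary-statistics tables
#'
#' Draws marginal z-scores for two traits at one locus directly on the
#' summary-statistic scale: for each trait,
#' \code{z ~ MVN(R lambda, R)} where \code{R} is the LD correlation matrix
#' and \code{lambda} is zero except for a single causal entry of height
#' \code{sqrt(n v / (1 - v))} (times \code{shared_sign} for trait 2 at an
#' H4 variant). Standard errors are \code{1/sqrt(n)} on the standardized
#' scale and \code{beta = z * se}. Effect-allele frequencies are drawn
#' uniform on \code{[0.05, 0.95]} and, by default, shared between the two
#' traits (one underlying population); \code{shared_eaf = FALSE} re-draws
#' trait 2's frequencies to emulate a cross-ancestry pairing.
#'
#' @param ld An \code{ld_structure} from [make_ld()].
#' @param spec A \code{scenario_spec}.
#' @param seed Integer seed; fully determines the output.
#' @param shared_eaf Share allele frequencies between traits (default TRUE).
#' @param trait2_meta Named list of metadata for trait 2 (an eQTL by
#'   default): \code{trait}, \code{type}, \code{gene}, \code{cell_type},
#'   \code{state}, \code{ancestry}.
#' @return An object of class \code{locus_pair}: list with \code{trait1}
#'   and \code{trait2} (\code{sumstats}), \code{truth} (the scenario) and
#'   \code{seed}.
#' @examples
#' ld <- make_ld(100, rho = 0.9, seed = 1)
#' sc <- scenario_spec("H4", causal_index_trait1 = 50)
#' pair <- simulate_locus_pair(ld, sc, seed = 7)
#' @export
simulate_locus_pair <- function(ld, spec, seed, shared_eaf = TRUE,
                                trait2_meta = list()) {
  stopifnot(inherits(ld, "ld_structure"), inherits(spec, "scenario_spec"))
  L <- ld_chol(ld)
  mu1 <- drop(ld$correlation %*% causal_lambda(
    ld, spec$causal_index_trait1, spec$n_trait1,
    spec$variance_explained_trait1))
  mu2 <- drop(ld$correlation %*% causal_lambda(
    ld, spec$causal_index_trait2, spec$n_trait2,
    spec$variance_explained_trait2,
    sign = if (spec$hypothesis == "H4") spec$shared_sign else 1))

  with_seed(seed, function() {
    z1 <- rmvn_chol(mu1, L)
    z2 <- rmvn_chol(mu2, L)
    eaf1 <- stats::runif(ld$n_snps, 0.05, 0.95)
    eaf2 <- if (shared_eaf) eaf1 else stats::runif(ld$n_snps, 0.05, 0.95)
    ## one shared biallelic SNV allele pair per variant
    ea <- sample(DNA_BASES, ld$n_snps, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(DNA_BASES, a), 1L), "")
    alleles <- list(effect = ea, other = unname(oa))

    t2m <- utils::modifyList(
      list(trait = "expression", type = "eqtl", gene = "GENE1",
           cell_type = "CD14_monocyte", state = "unstimulated",
           ancestry = "EUR"),
      trait2_meta)

    structure(
      list(
        trait1 = zscores_to_sumstats(z1, spec$n_trait1, ld, eaf1, alleles,
                                     trait = "disease", type = "gwas",
                                     ancestry = "EUR"),
        trait2 = do.call(zscores_to_sumstats,
                         c(list(z2, spec$n_trait2, ld, eaf2, alleles), t2m)),
        truth = spec,
        seed = seed
      ),
      class = "locus_pair"
    )
  })
}

IMMUNE_CELL_TYPES <- c(
  "B_memory", "B_naive", "Basophil", "CD14_monocyte", "CD16_monocyte",
  "CD4_memory_T", "CD4_naive_T", "CD8_memory_T", "CD8_naive_T", "HSC",
  "ILC", "MAIT", "NK_bright", "NK_dim", "NKT", "Neutrophil", "Plasmablast",
  "Treg", "cDC", "gdT", "pDC", "Eosinophil"
)
ACTIVATION_STATES <- c("unstimulated", "influenza", "SARS-CoV-2")

#' Simulate a multi-cell-type expression matrix with tunable specificity
#'
#' Generates per-gene TPM vectors across cell type x activation state
#' columns from a symmetric Dirichlet distribution scaled by
#' \code{base_tpm}. The Dirichlet concentration controls specificity
#' monotonically: small values pile expression onto few columns (tau near
#' 1), large values spread it evenly (tau near 0), giving a ground truth
#' for specificity statistics. Defaults emulate a design of 22 peripheral
#' immune cell types measured unstimulated and after influenza A or
#' SARS-CoV-2 stimulation.
#'
#' @param n_genes Number of genes (>= 1).
#' @param cell_types Character vector of cell-type labels.
#' @param states Character vector of activation-state labels.
#' @param concentration Positive Dirichlet concentration, scalar or one
#'   value per gene.
#' @param base_tpm Positive total TPM per gene.
#' @param genes Optional gene identifiers (default \code{gene0001} ...).
#' @param ancestry Ancestry label attached to the matrix.
#' @param seed Integer seed.
#' @return An \code{expr_matrix} (see [expr_matrix()]) whose
#'   \code{intended_max} attribute records each gene's generated maximal
#'   column index.
#' @export
simulate_expression <- function(n_genes, cell_types = IMMUNE_CELL_TYPES,
                                states = ACTIVATION_STATES,
                                concentration = 0.5, base_tpm = 1000,
                                genes = NULL, ancestry = "multi", seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1) {
    stop("`n_genes` must be a positive integer")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("`concentration` must be positive")
  }
  if (base_tpm <= 0) stop("`base_tpm` must be positive")
  n_genes <- as.integer(n_genes)
  conc <- rep_len(concentration, n_genes)
  K <- length(cell_types) * length(states)
  genes <- genes %||% sprintf("gene%04d", seq_len(n_genes))

  tpm <- with_seed(seed, function() {
    t(vapply(seq_len(n_genes), function(g) {
      w <- stats::rgamma(K, shape = conc[g], rate = 1)
      if (all(w == 0)) w[1L] <- 1  # guard against underflow at tiny shape
      base_tpm * w / sum(w)
    }, numeric(K)))
  })
  em <- expr_matrix(tpm,
                    genes = genes,
                    cell_type = rep(cell_types, each = length(states)),
                    state = rep(states, times = length(cell_types)),
                    ancestry = ancestry)
  attr(em, "intended_max") <- apply(tpm, 1L, which.max)
  em
}

#' Simulate a phenotype-QTL gene--blood-count association table
#'
#' Emulates a table of significant associations between genes and blood
#' cell-count metrics by independent Bernoulli inclusion of each
#' (gene, metric, ancestry) cell.
#'
#' @param genes Character vector of gene symbols (e.g. a catalog subset).
#' @param metrics Blood-count metric labels.
#' @param hit_probability Inclusion probability, scalar or one per metric.
#' @param ancestries Ancestry labels to draw for.
#' @param catalog Optional gene catalog (see [load_gene_catalog()]); when
#'   given, every entry of \code{genes} must appear in it.
#' @param seed Integer seed.
#' @return data.frame with columns \code{gene}, \code{metric},
#'   \code{ancestry}, \code{significant} (all TRUE; absent rows are the
#'   non-associations).
#' @export
simulate_phenoqtl_table <- function(genes,
                                    metrics = c("lymphocyte", "monocyte",
                                                "neutrophil",
                                                "total_white_cell"),
                                    hit_probability = 0.5,
                                    ancestries = c("AFR", "EAS", "EUR"),
                                    catalog = NULL, seed = 1L) {
  if (length(genes) == 0 || anyNA(genes) || any(genes == "")) {
    stop("`genes` must be non-empty gene symbols")
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(genes, catalog$gene)
    if (length(unknown) > 0) {
      stop("gene(s) not in catalog: ", paste(unknown, collapse = ", "))
    }
  }
  p <- rep_len(hit_probability, length(metrics))
  if (any(p < 0 | p > 1)) stop("`hit_probability` must lie in [0, 1]")
  grid <- expand.grid(gene = genes, metric = metrics, ancestry = ancestries,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pr <- p[match(grid$metric, metrics)]
  hit <- with_seed(seed, function() stats::runif(nrow(grid)) < pr)
  out <- grid[hit, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
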