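# Synthetic end-to-end demo: one shared-variant locus, one distinct-variant
# locus, one null locus, a 39-gene expression matrix and a phenotype-QTL
# table. Thresholds are the package defaults, spelled out for visibility.
seed: 42
priors:
  p1: 1.0e-4
  p2: 1.0e-4
  p12: 1.0e-5
threshold: 0.75
window: 1000000
sig_threshold: 5.0e-8
min_snps: 50
direction_alpha: 0.05
expression_threshold: 1
expression:
  n_genes: 39
  concentration: 0.5
  base_tpm: 1000
  ancestry: multi
loci:
  - name: shared_locus
    hypothesis: H4
    n_snps: 300
    rho: 0.9
    chrom: "2"
    causal_index_trait1: 150
    variance_explained_trait1: 0.01
    variance_explained_trait2: 0.01
    n_trait1: 10000
    n_trait2: 10000
    shared_sign: 1
    gene: BIN1
    cell_type: CD14_monocyte
    state: unstimulated
    gwas_ancestry: EUR
    eqtl_ancestry: multi
  - name: distinct_locus
    hypothesis: H3
    n_snps: 300
    rho: 0.9
    chrom: "12"
    causal_index_trait1: 75
    causal_index_trait2: 225
    n_trait1: 10000
    n_trait2: 10000
    gene: LRRK2
    cell_type: CD14_monocyte
    state: SARS-CoV-2
    gwas_ancestry: EAS
    eqtl_ancestry: EAS
  - name: null_locus
    hypothesis: H0
    n_snps: 300
    rho: 0.9
    chrom: "4"
    gene: SNCA
    cell_type: CD16_monocyte
    state: unstimulated
    gwas_ancestry: EUR
    eqtl_ancestry: multi
phenoqtl:
  hit_probability: 0.5
  by_ancestry: false
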