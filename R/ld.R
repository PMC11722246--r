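#' Construct an AR(1) linkage-disequilibrium structure
#'
#' Builds the minimal LD model used by the summary-statistics simulator: a
#' first-order autoregressive genotype correlation matrix in which the
#' correlation between SNPs \code{i} and \code{j} is \code{rho^|i-j|}, plus
#' strictly increasing base-pair positions and unique variant identifiers.
#'
#' @param n_snps Number of variants (>= 1).
#' @param rho Adjacent-SNP correlation, in \code{[0, 1)}. \code{rho = 0}
#'   gives independent variants.
#' @param start_pos Base-pair coordinate of the first variant (1-based).
#' @param chrom Chromosome label attached to the structure.
#' @param seed Integer seed controlling the (jittered) inter-SNP spacing;
#'   the correlation matrix itself is fully determined by \code{n_snps} and
#'   \code{rho}.
#'
#' @return An object of class \code{ld_structure}: a list with elements
#'   \code{n_snps}, \code{correlation}, \code{positions}, \code{rsids},
#'   \code{chrom} and \code{rho}.
#' @examples
#' ld <- make_ld(5, rho = 0.5, seed = 1)
#' ld$correlation[1, 2]
#' @export
make_ld <- function(n_snps, rho, start_pos = 1e6, chrom = "1", seed = 1L) {
  stopifnot(is.numeric(n_snps), length(n_snps) == 1L, n_snps >= 1,
            n_snps == as.integer(n_snps))
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1) {
    stop("`rho` must be a single value in [0, 1)")
  }
  n_snps <- as.integer(n_snps)
  idx <- seq_len(n_snps)
  correlation <- rho^abs(outer(idx, idx, "-"))
  spacing <- with_seed(seed, function() sample(100:2500, n_snps, replace = TRUE))
  positions <- as.integer(start_pos) + c(0L, cumsum(spacing[-1L]))
  out <- structure(
    list(
      n_snps = n_snps,
      correlation = correlation,
      positions = positions,
      ## position-derived so distinct loci get distinct identifiers
      rsids = sprintf("rs%d", positions),
      chrom = as.character(chrom),
      rho = rho
    ),
    class = "ld_structure"
  )
  ## cache the Cholesky factor so replicate draws share one factorisation
  out$chol_upper <- ld_chol(out)
  out
}

## Cholesky factor of an LD correlation matrix, with a clear error for
## non-positive-definite input. Computed once per structure and reused
## across replicate multivariate-normal draws.
ld_chol <- function(ld) {
  if (!is.null(ld$chol_upper)) return(ld$chol_upper)
  tryCatch(chol(ld$correlation), error = function(e) {
    stop("LD correlation matrix is not positive definite: ",
         conditionMessage(e))
  })
}

## One draw z ~ MVN(mean, R) given the upper-triangular chol factor of R.
rmvn_chol <- function(mean, chol_upper) {
  drop(mean + crossprod(chol_upper, stats::rnorm(length(mean))))
}
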