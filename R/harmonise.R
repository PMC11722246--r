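#' Harmonise two summary-statistics tables to a common effect allele
#'
#' Intersects two tables on rsID and aligns table \code{b}'s effect sizes to
#' table \code{a}'s effect allele. Per variant: identical allele pairs are
#' kept as-is; swapped pairs (b's effect allele is a's other allele) have
#' \code{beta_b} negated and \code{eaf_b} complemented; strand-complement
#' pairs are complemented first and then aligned; anything else is dropped
#' as irreconcilable. Palindromic variants (A/T or C/G), whose strand cannot
#' be resolved from alleles alone, are dropped when their minor-allele
#' frequency exceeds \code{drop_palindromic_above_maf} (frequency too close
#' to 0.5 to resolve strand by frequency either).
#'
#' @param a,b \code{sumstats} objects on the same genome build; \code{a}
#'   fixes the reference effect allele (conventionally the GWAS).
#' @param drop_palindromic_above_maf MAF cutoff above which palindromic
#'   variants are removed (default 0.42).
#' @return An object of class \code{harmonised_pair}: a list with
#'   \code{data} (per-SNP rows carrying both traits' beta/se/p on the same
#'   effect allele), \code{counts} (kept, flipped, dropped by reason) and
#'   the two tables' metadata.
#' @examples
#' # see vignette("ndcoloc-methods") for a worked example
#' @export
harmonise <- function(a, b, drop_palindromic_above_maf = 0.42) {
  stopifnot(inherits(a, "sumstats"), inherits(b, "sumstats"))
  common <- intersect(a$data$rsid, b$data$rsid)
  if (length(common) == 0L) {
    stop("no overlapping variants between the two tables")
  }
  da <- a$data[match(common, a$data$rsid), , drop = FALSE]
  db <- b$data[match(common, b$data$rsid), , drop = FALSE]

  ea_a <- da$effect_allele; oa_a <- da$other_allele
  ea_b <- db$effect_allele; oa_b <- db$other_allele

  same <- ea_b == ea_a & oa_b == oa_a
  swap <- ea_b == oa_a & oa_b == ea_a
  cea <- complement_alleles(ea_b); coa <- complement_alleles(oa_b)
  strand_same <- !same & !swap & cea == ea_a & coa == oa_a
  strand_swap <- !same & !swap & cea == oa_a & coa == ea_a
  pal <- is_palindromic(ea_a, oa_a)

  ## note: for palindromic variants `swap` and `strand_same` coincide, so
  ## the direct interpretation (no strand change) is taken first.
  flip <- swap | strand_swap
  keepable <- same | swap | strand_same | strand_swap

  maf_a <- pmin(da$eaf, 1 - da$eaf)
  maf_b <- pmin(db$eaf, 1 - db$eaf)
  maf <- pmax(maf_a, maf_b, na.rm = TRUE)
  maf[is.na(maf_a) & is.na(maf_b)] <- NA_real_
  drop_pal <- pal & (!is.na(maf) & maf > drop_palindromic_above_maf)

  keep <- keepable & !drop_pal

  beta_b <- ifelse(flip, -db$beta, db$beta)
  eaf_b <- ifelse(flip, 1 - db$eaf, db$eaf)

  out <- data.frame(
    rsid = common,
    chrom = da$chrom,
    pos = da$pos,
    effect_allele = ea_a,
    other_allele = oa_a,
    eaf_a = da$eaf, beta_a = da$beta, se_a = da$se, p_a = da$p, n_a = da$n,
    eaf_b = eaf_b, beta_b = beta_b, se_b = db$se, p_b = db$p, n_b = db$n,
    flipped = flip,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL

  structure(
    list(
      data = out,
      counts = list(
        n_intersect = length(common),
        kept = sum(keep),
        flipped = sum(flip & keep),
        dropped = sum(!keep),
        dropped_palindromic = sum(drop_pal & keepable),
        dropped_irreconcilable = sum(!keepable)
      ),
      meta_a = a$metadata,
      meta_b = b$metadata
    ),
    class = "harmonised_pair"
  )
}

#' @export
print.harmonised_pair <- function(x, ...) {
  cat(sprintf(
    "<harmonised_pair> %s vs %s: %d kept (%d sign-flipped), %d dropped of %d shared\n",
    x$meta_a$trait, x$meta_b$trait, x$counts$kept, x$counts$flipped,
    x$counts$dropped, x$counts$n_intersect))
  invisible(x)
}

#' Extract LD-independent locus windows around significant GWAS hits
#'
#' Finds variants below the genome-wide significance threshold, draws a
#' half-open interval \code{[pos - window, pos + window)} around each, and
#' merges overlapping intervals per chromosome. Each merged interval is
#' returned as a \code{sumstats} slice annotated with its boundaries and
#' lead SNP (smallest p-value in the window).
#'
#' @param gwas A \code{sumstats} object.
#' @param sig_threshold Significance cutoff for index SNPs (default
#'   \code{5e-8}).
#' @param window Half-width in base pairs around each significant SNP
#'   (default 1 Mb, so windows span "within 1 Mb" of significant hits).
#' @return A list of \code{sumstats} objects, one per merged window, each
#'   carrying \code{window} metadata (\code{chrom}, \code{start},
#'   \code{end}, \code{lead_rsid}, \code{lead_p}). Empty list (with a
#'   message) when nothing is significant.
#' @export
extract_window <- function(gwas, sig_threshold = 5e-8, window = 1e6) {
  stopifnot(inherits(gwas, "sumstats"), window > 0)
  df <- gwas$data
  sig <- df[df$p < sig_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    message("no variants below p < ", format(sig_threshold),
            "; returning empty window list")
    return(list())
  }
  out <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, , drop = FALSE]
    start <- pmax(0, s$pos - window)
    end <- s$pos + window
    o <- order(start)
    start <- start[o]; end <- end[o]
    ## merge strictly overlapping half-open intervals
    m_start <- start[1L]; m_end <- end[1L]
    merged <- list()
    for (i in seq_along(start)[-1L]) {
      if (start[i] < m_end) {
        m_end <- max(m_end, end[i])
      } else {
        merged[[length(merged) + 1L]] <- c(m_start, m_end)
        m_start <- start[i]; m_end <- end[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(m_start, m_end)
    for (iv in merged) {
      inside <- df$chrom == chr & df$pos >= iv[1L] & df$pos < iv[2L]
      slice <- gwas
      slice$data <- df[inside, , drop = FALSE]
      rownames(slice$data) <- NULL
      lead <- which.min(slice$data$p)
      slice$metadata$window <- list(
        chrom = chr, start = iv[1L], end = iv[2L],
        lead_rsid = slice$data$rsid[lead], lead_p = slice$data$p[lead]
      )
      out[[length(out) + 1L]] <- slice
    }
  }
  out
}
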