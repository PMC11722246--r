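#' Colocalisation priors
#'
#' Per-SNP prior probabilities: \code{p1} (associated with trait 1 only),
#' \code{p2} (trait 2 only) and \code{p12} (associated with both). The
#' defaults are the field's conventional \code{1e-4}, \code{1e-4},
#' \code{1e-5}.
#'
#' @param p1,p2 Single-trait per-SNP priors.
#' @param p12 Shared-variant per-SNP prior; must not exceed
#'   \code{min(p1, p2)}.
#' @return List of class \code{coloc_priors}.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  if (p1 <= 0 || p2 <= 0 || p12 < 0) stop("priors must be positive (p12 >= 0)")
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Log approximate Bayes factor for association at one variant
#'
#' Computes the Wakefield-style approximate Bayes factor from an effect
#' estimate and its standard error under a normal effect prior with
#' standard deviation \code{prior_sd}: with \code{z = beta/se} and
#' shrinkage \code{r = prior_sd^2 / (prior_sd^2 + se^2)},
#' \code{lABF = 0.5 * (log(1 - r) + r * z^2)} (natural log). Vectorised
#' over variants.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param prior_sd Prior standard deviation of the true effect, > 0.
#' @return Named list with \code{labf}, \code{z}, \code{r} and
#'   \code{prior_sd} (an \code{abf_table} row set).
#' @examples
#' labf(0.1, 0.02, 0.2)$labf  # ~ 10.07
#' @export
labf <- function(beta, se, prior_sd) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) ||
      any(!is.finite(prior_sd))) {
    stop("`beta`, `se` and `prior_sd` must be finite")
  }
  if (any(se <= 0)) stop("`se` must be positive")
  if (any(prior_sd <= 0)) stop("`prior_sd` must be positive")
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  structure(
    list(labf = 0.5 * (log(1 - r) + r * z^2), z = z, r = r,
         prior_sd = prior_sd),
    class = "abf_table"
  )
}

#' Estimate the trait standard deviation from summary statistics
#'
#' For a quantitative trait, \code{var(beta_j) ~ sdY^2 / (2 n_j maf_j (1 -
#' maf_j))}, so \code{sdY^2} is the zero-intercept regression slope of
#' \code{2 n maf (1 - maf)} on \code{1 / se^2}. Used to set the effect
#' prior SD to \code{0.2 * sdY} when the trait scale is unknown.
#'
#' @param se Standard errors.
#' @param maf Minor (or effect) allele frequencies in (0, 1).
#' @param n Sample sizes.
#' @return Estimated sdY (scalar), or \code{NA} when the estimate fails.
#' @export
estimate_sdy <- function(se, maf, n) {
  ok <- is.finite(se) & is.finite(maf) & is.finite(n) &
    se > 0 & maf > 0 & maf < 1 & n > 0
  if (sum(ok) < 2L) return(NA_real_)
  oneover <- 1 / se[ok]^2
  nvx <- 2 * n[ok] * maf[ok] * (1 - maf[ok])
  cf <- tryCatch(stats::coef(stats::lm(nvx ~ oneover - 1))[[1L]],
                 error = function(e) NA_real_)
  if (!is.finite(cf) || cf <= 0) return(NA_real_)
  sqrt(cf)
}

## Effect-prior SD convention: 0.15 for case-control traits (log-odds
## scale), 0.2 * sdY for quantitative traits, estimating sdY from
## beta/SE/MAF/N when not supplied; falls back to 0.2 with a warning.
choose_prior_sd <- function(trait_type, se = NULL, maf = NULL, n = NULL,
                            sdY = NULL, prior_sd = NULL) {
  if (!is.null(prior_sd)) return(prior_sd)
  if (identical(trait_type, "cc")) return(0.15)
  if (is.null(sdY)) sdY <- estimate_sdy(se, maf, n)
  if (!is.finite(sdY)) {
    warning("sdY estimation failed; falling back to prior_sd = 0.2")
    return(0.2)
  }
  0.2 * sdY
}

new_coloc_result <- function(pp, n_snps, threshold = 0.75, locus = NA,
                             gene = NA, cell_type = NA, state = NA,
                             gwas_ancestry = NA, eqtl_ancestry = NA,
                             prior_sd_1 = NA, prior_sd_2 = NA,
                             priors = coloc_priors()) {
  pp <- pp / sum(pp)
  names(pp) <- paste0("pph", 0:4)
  ratio <- if (pp[["pph3"]] == 0) Inf else pp[["pph4"]] / pp[["pph3"]]
  res <- structure(
    list(locus = locus, gene = gene, cell_type = cell_type, state = state,
         gwas_ancestry = gwas_ancestry, eqtl_ancestry = eqtl_ancestry,
         n_snps = n_snps,
         pph0 = pp[["pph0"]], pph1 = pp[["pph1"]], pph2 = pp[["pph2"]],
         pph3 = pp[["pph3"]], pph4 = pp[["pph4"]],
         ratio_h4_h3 = ratio, call = NA_character_,
         priors = unclass(priors),
         prior_sd_1 = prior_sd_1, prior_sd_2 = prior_sd_2),
    class = "coloc_result"
  )
  res$call <- classify(res, threshold = threshold)$call
  res
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d SNPs | PPH0-4: %s | H4/H3 = %.3g | call: %s\n",
              x$n_snps,
              paste(sprintf("%.3f", c(x$pph0, x$pph1, x$pph2, x$pph3, x$pph4)),
                    collapse = " "),
              x$ratio_h4_h3, x$call))
  invisible(x)
}

#' Posterior probabilities of the five colocalisation hypotheses
#'
#' Combines per-SNP log approximate Bayes factors for two traits at one
#' locus into posteriors for: H0 no association with either trait; H1/H2
#' association with one trait only; H3 two distinct causal variants; H4 one
#' shared causal variant. With \code{S_k = sum_i exp(labf_k_i)} and
#' \code{S12 = sum_i exp(labf1_i + labf2_i)}, the unnormalised hypothesis
#' weights are \code{1}, \code{p1 S1}, \code{p2 S2},
#' \code{p1 p2 (S1 S2 - S12)} and \code{p12 S12}; all sums are carried in
#' log space, so arbitrarily large Bayes factors are safe. The five
#' posteriors sum to 1.
#'
#' @param labf1,labf2 Per-SNP log approximate Bayes factors (equal length
#'   \code{Q >= 1}), in the same harmonised SNP order.
#' @param priors A [coloc_priors()] object.
#' @param threshold Decision threshold passed to [classify()].
#' @param ... Locus/gene/ancestry identifiers stored in the result.
#' @return A \code{coloc_result}.
#' @examples
#' posterior(rep(0, 3), rep(0, 3))$pph0  # null locus: H0 dominates
#' @export
posterior <- function(labf1, labf2, priors = coloc_priors(),
                      threshold = 0.75, ...) {
  if (inherits(labf1, "abf_table")) labf1 <- labf1$labf
  if (inherits(labf2, "abf_table")) labf2 <- labf2$labf
  Q <- length(labf1)
  if (Q == 0L) stop("at least one SNP is required")
  if (length(labf2) != Q) stop("labf vectors must have equal length")
  if (any(!is.finite(labf1)) || any(!is.finite(labf2))) {
    stop("log Bayes factors must be finite")
  }
  lS1 <- logsumexp(labf1)
  lS2 <- logsumexp(labf2)
  lS12 <- logsumexp(labf1 + labf2)

  lH0 <- 0
  lH1 <- log(priors$p1) + lS1
  lH2 <- log(priors$p2) + lS2
  ## S1*S2 - S12 = sum over distinct pairs; exactly 0 when Q = 1
  d <- lS12 - (lS1 + lS2)
  lH3 <- if (Q == 1L || d >= 0) -Inf else {
    log(priors$p1) + log(priors$p2) + lS1 + lS2 + log1p(-exp(d))
  }
  lH4 <- if (priors$p12 == 0) -Inf else log(priors$p12) + lS12

  lw <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(lw - logsumexp(lw))
  new_coloc_result(pp, n_snps = Q, threshold = threshold, priors = priors,
                   ...)
}

#' Posterior by explicit enumeration of causal configurations
#'
#' Independent reference computation of the same posterior as
#' [posterior()]: every pair of causal configurations — SNP \code{i} (or
#' none) causal for trait 1, SNP \code{j} (or none) for trait 2 — is
#' enumerated and its log weight accumulated under the hypothesis it
#' belongs to. Quadratic in the number of SNPs, so restricted to
#' \code{Q <= 20}; intended as a testing oracle.
#'
#' @inheritParams posterior
#' @return A \code{coloc_result}.
#' @export
brute_force_posterior <- function(labf1, labf2, priors = coloc_priors(),
                                  threshold = 0.75, ...) {
  if (inherits(labf1, "abf_table")) labf1 <- labf1$labf
  if (inherits(labf2, "abf_table")) labf2 <- labf2$labf
  Q <- length(labf1)
  if (Q == 0L) stop("at least one SNP is required")
  if (Q > 20L) stop("brute-force enumeration is limited to Q <= 20")
  if (length(labf2) != Q) stop("labf vectors must have equal length")

  acc <- list(H0 = c(), H1 = c(), H2 = c(), H3 = c(), H4 = c())
  lp1 <- log(priors$p1); lp2 <- log(priors$p2)
  lp12 <- if (priors$p12 == 0) -Inf else log(priors$p12)
  for (i in 0:Q) {
    for (j in 0:Q) {
      if (i == 0L && j == 0L) {
        acc$H0 <- c(acc$H0, 0)
      } else if (j == 0L) {
        acc$H1 <- c(acc$H1, lp1 + labf1[i])
      } else if (i == 0L) {
        acc$H2 <- c(acc$H2, lp2 + labf2[j])
      } else if (i == j) {
        acc$H4 <- c(acc$H4, lp12 + labf1[i] + labf2[j])
      } else {
        acc$H3 <- c(acc$H3, lp1 + lp2 + labf1[i] + labf2[j])
      }
    }
  }
  lw <- vapply(acc, function(v) if (length(v) == 0L) -Inf else logsumexp(v),
               numeric(1L))
  pp <- exp(lw - logsumexp(lw))
  new_coloc_result(pp, n_snps = Q, threshold = threshold, priors = priors,
                   ...)
}

#' Classify a colocalisation result
#'
#' Applies the power-aware decision rule: a locus is \emph{underpowered}
#' when \code{PPH3 + PPH4 < threshold} (the two studies cannot be
#' compared); otherwise \emph{colocalised} when \code{PPH4 > threshold},
#' \emph{distinct} when \code{PPH3 > threshold}, and \emph{indeterminate}
#' when neither single hypothesis clears the threshold. The PPH4/PPH3
#' ratio is always reported (\code{Inf} when PPH3 = 0).
#'
#' @param result A \code{coloc_result}, or a numeric vector of the five
#'   posteriors \code{pph0..pph4}.
#' @param threshold Decision threshold in (0, 1), default 0.75.
#' @return List with \code{call} and \code{ratio_h4_h3}.
#' @examples
#' classify(c(0.01, 0.02, 0.02, 0.02, 0.93))$call  # "colocalised"
#' @export
classify <- function(result, threshold = 0.75) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (is.numeric(result)) {
    if (length(result) != 5L) stop("expected five posteriors pph0..pph4")
    pph3 <- result[4L]; pph4 <- result[5L]
  } else {
    pph3 <- result$pph3; pph4 <- result$pph4
  }
  ratio <- if (pph3 == 0) Inf else pph4 / pph3
  call <- if (pph3 + pph4 < threshold) {
    "underpowered"
  } else if (pph4 > threshold) {
    "colocalised"
  } else if (pph3 > threshold) {
    "distinct"
  } else {
    "indeterminate"
  }
  list(call = call, ratio_h4_h3 = ratio)
}

#' Colocalisation test of one harmonised pair
#'
#' Convenience wrapper: computes per-trait log Bayes factors from a
#' harmonised pair's beta/SE columns (choosing each trait's effect-prior SD
#' by its declared type) and evaluates the five-hypothesis posterior.
#'
#' @param pair A \code{harmonised_pair}.
#' @param priors A [coloc_priors()] object.
#' @param threshold Decision threshold.
#' @param prior_sd_1,prior_sd_2 Optional explicit effect-prior SDs for
#'   trait a/b; by default 0.15 for case-control traits and
#'   \code{0.2 * sdY} (estimated) for quantitative traits.
#' @return A \code{coloc_result}.
#' @export
coloc_test_pair <- function(pair, priors = coloc_priors(), threshold = 0.75,
                            prior_sd_1 = NULL, prior_sd_2 = NULL) {
  stopifnot(inherits(pair, "harmonised_pair"))
  d <- pair$data
  if (nrow(d) == 0L) stop("harmonised pair has no variants")
  w1 <- choose_prior_sd(pair$meta_a$trait_type %||% "cc",
                        se = d$se_a, maf = pmin(d$eaf_a, 1 - d$eaf_a),
                        n = d$n_a, prior_sd = prior_sd_1)
  w2 <- choose_prior_sd(pair$meta_b$trait_type %||% "quant",
                        se = d$se_b, maf = pmin(d$eaf_b, 1 - d$eaf_b),
                        n = d$n_b, prior_sd = prior_sd_2)
  l1 <- labf(d$beta_a, d$se_a, w1)
  l2 <- labf(d$beta_b, d$se_b, w2)
  posterior(l1, l2, priors = priors, threshold = threshold,
            locus = paste0(d$chrom[1L], ":", min(d$pos), "-", max(d$pos)),
            gene = pair$meta_b$gene, cell_type = pair$meta_b$cell_type,
            state = pair$meta_b$state,
            gwas_ancestry = pair$meta_a$ancestry,
            eqtl_ancestry = pair$meta_b$ancestry,
            prior_sd_1 = w1, prior_sd_2 = w2)
}

coloc_result_row <- function(r) {
  data.frame(
    locus = r$locus, gene = r$gene, cell_type = r$cell_type,
    state = r$state, gwas_ancestry = r$gwas_ancestry,
    eqtl_ancestry = r$eqtl_ancestry, n_snps = r$n_snps,
    pph0 = r$pph0, pph1 = r$pph1, pph2 = r$pph2, pph3 = r$pph3,
    pph4 = r$pph4, ratio_h4_h3 = r$ratio_h4_h3, call = r$call,
    p1 = r$priors$p1, p2 = r$priors$p2, p12 = r$priors$p12,
    prior_sd_1 = r$prior_sd_1, prior_sd_2 = r$prior_sd_2,
    stringsAsFactors = FALSE
  )
}

#' Scan GWAS locus windows against a set of eQTL tables
#'
#' Runs the full colocalisation pass: every (GWAS window x eQTL table)
#' pairing with at least \code{min_snps} overlapping variants is
#' harmonised, scored with per-trait log Bayes factors and the
#' five-hypothesis posterior, and classified. Pairings below the SNP
#' minimum, or without any overlap, are skipped with a recorded reason, so
#' ancestry-specific scans remain auditable.
#'
#' @param gwas_windows List of \code{sumstats} windows from
#'   [extract_window()] (or whole tables).
#' @param eqtl_tables List of eQTL \code{sumstats} tables labelled with
#'   gene/cell type/state/ancestry.
#' @param priors A [coloc_priors()] object.
#' @param threshold Decision threshold (default 0.75).
#' @param min_snps Minimum overlapping variants per tested pair
#'   (default 50).
#' @param prior_sd_1,prior_sd_2 Optional explicit effect-prior SDs.
#' @param drop_palindromic_above_maf Passed to [harmonise()].
#' @return List with \code{results} (one data.frame row per tested pair)
#'   and \code{skipped} (pairings not tested, with reasons).
#' @export
run_coloc_scan <- function(gwas_windows, eqtl_tables,
                           priors = coloc_priors(), threshold = 0.75,
                           min_snps = 50, prior_sd_1 = NULL,
                           prior_sd_2 = NULL,
                           drop_palindromic_above_maf = 0.42) {
  if (inherits(gwas_windows, "sumstats")) gwas_windows <- list(gwas_windows)
  if (inherits(eqtl_tables, "sumstats")) eqtl_tables <- list(eqtl_tables)
  results <- list()
  skipped <- list()
  for (w in gwas_windows) {
    wid <- if (!is.null(w$metadata$window)) {
      sprintf("%s:%d-%d", w$metadata$window$chrom,
              as.integer(w$metadata$window$start),
              as.integer(w$metadata$window$end))
    } else {
      sprintf("%s:%d-%d", w$data$chrom[1L], as.integer(min(w$data$pos)),
              as.integer(max(w$data$pos)))
    }
    for (e in eqtl_tables) {
      eid <- paste(e$metadata$gene, e$metadata$cell_type, e$metadata$state,
                   e$metadata$ancestry, sep = "/")
      pair <- tryCatch(
        harmonise(w, e,
                  drop_palindromic_above_maf = drop_palindromic_above_maf),
        error = function(err) err)
      if (inherits(pair, "error")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          locus = wid, eqtl = eid, reason = conditionMessage(pair),
          stringsAsFactors = FALSE)
        next
      }
      if (nrow(pair$data) < min_snps) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          locus = wid, eqtl = eid,
          reason = sprintf("only %d overlapping variants (< %d)",
                           nrow(pair$data), min_snps),
          stringsAsFactors = FALSE)
        next
      }
      r <- coloc_test_pair(pair, priors = priors, threshold = threshold,
                           prior_sd_1 = prior_sd_1, prior_sd_2 = prior_sd_2)
      r$locus <- wid
      results[[length(results) + 1L]] <- coloc_result_row(r)
    }
  }
  list(
    results = if (length(results)) do.call(rbind, results) else
      coloc_result_row(new_coloc_result(c(1, 0, 0, 0, 0), 1L))[0, ],
    skipped = if (length(skipped)) do.call(rbind, skipped) else
      data.frame(locus = character(), eqtl = character(),
                 reason = character(), stringsAsFactors = FALSE)
  )
}
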