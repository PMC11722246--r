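#' Effect-direction analysis at a colocalised locus
#'
#' Quantifies concordance of the two association signals across the
#' harmonised variants of a locus: Pearson correlation of the
#' \code{-log10} p-values, Pearson correlation of the effect sizes with its
#' two-sided p-value, and an ordinary least-squares line (with 95% CI) for
#' the trait-2-on-trait-1 beta relation. The direction of risk is called
#' from the sign of the beta correlation when its p-value clears
#' \code{alpha}: a positive correlation means higher expression accompanies
#' higher disease risk.
#'
#' @param pair A \code{harmonised_pair} with at least 3 variants (trait a =
#'   GWAS, trait b = eQTL by convention).
#' @param alpha Significance level for calling a direction (default 0.05).
#' @return List of class \code{direction_result}: \code{pearson_r_p},
#'   \code{pearson_r_beta}, \code{p_value}, \code{slope},
#'   \code{intercept}, \code{ci95} (slope), \code{direction} in
#'   \code{"risk-increasing with expression"},
#'   \code{"risk-decreasing with expression"}, \code{"indeterminate"},
#'   plus \code{n_snps} and identifiers.
#' @export
direction_analysis <- function(pair, alpha = 0.05) {
  stopifnot(inherits(pair, "harmonised_pair"))
  d <- pair$data
  if (nrow(d) < 3L) stop("direction analysis needs at least 3 variants")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")

  zero_var <- stats::sd(d$beta_a) == 0 || stats::sd(d$beta_b) == 0
  if (zero_var) {
    warning("zero-variance effect sizes; direction indeterminate")
    r_beta <- NA_real_; p_val <- NA_real_
    slope <- NA_real_; intercept <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    ct <- stats::cor.test(d$beta_a, d$beta_b, method = "pearson")
    r_beta <- unname(ct$estimate)
    p_val <- ct$p.value
    fit <- stats::lm(beta_b ~ beta_a, data = d)
    cf <- stats::coef(fit)
    intercept <- unname(cf[1L]); slope <- unname(cf[2L])
    ## suppressWarnings: summary.lm warns on an exactly collinear fit,
    ## where the CI legitimately collapses to the slope
    ci <- tryCatch(
      suppressWarnings(
        unname(stats::confint(fit, "beta_a", level = 0.95)[1, ])),
      error = function(e) c(NA_real_, NA_real_))
    ## exact collinearity: cor.test p underflows to 0, keep it
  }
  lp_a <- -log10(d$p_a); lp_b <- -log10(d$p_b)
  r_p <- if (stats::sd(lp_a) == 0 || stats::sd(lp_b) == 0) NA_real_ else
    stats::cor(lp_a, lp_b)

  direction <- if (!is.na(p_val) && p_val < alpha && !is.na(r_beta)) {
    if (r_beta > 0) "risk-increasing with expression"
    else "risk-decreasing with expression"
  } else {
    "indeterminate"
  }

  structure(
    list(gene = pair$meta_b$gene, cell_type = pair$meta_b$cell_type,
         state = pair$meta_b$state,
         gwas_ancestry = pair$meta_a$ancestry,
         eqtl_ancestry = pair$meta_b$ancestry,
         n_snps = nrow(d),
         pearson_r_p = r_p, pearson_r_beta = r_beta, p_value = p_val,
         slope = slope, intercept = intercept, ci95 = ci,
         alpha = alpha, direction = direction),
    class = "direction_result"
  )
}

#' @export
print.direction_result <- function(x, ...) {
  cat(sprintf(
    "<direction_result> %d SNPs | r(-log10 p) = %.3f | r(beta) = %.3f (p = %.3g) | slope = %.3f | %s\n",
    x$n_snps, x$pearson_r_p, x$pearson_r_beta, x$p_value, x$slope,
    x$direction))
  invisible(x)
}

#' Export a plot-ready locus comparison table
#'
#' Serialises the per-variant quantities behind a locus comparison
#' (positions, both traits' betas and \code{-log10} p-values) as a
#' long-format table, together with the summary statistics as JSON.
#'
#' @param pair A \code{harmonised_pair}.
#' @param result The matching \code{direction_result}.
#' @param path Optional basename; when given, writes \code{<path>.tsv} and
#'   \code{<path>.json}.
#' @return List with \code{table} (data.frame: rsid, pos, beta1, beta2,
#'   neglog10_p1, neglog10_p2) and \code{summary} (list), invisibly when
#'   written.
#' @export
locus_table_export <- function(pair, result, path = NULL) {
  stopifnot(inherits(pair, "harmonised_pair"),
            inherits(result, "direction_result"))
  d <- pair$data
  tab <- data.frame(
    rsid = d$rsid, pos = d$pos,
    beta1 = d$beta_a, beta2 = d$beta_b,
    neglog10_p1 = -log10(d$p_a), neglog10_p2 = -log10(d$p_b),
    stringsAsFactors = FALSE
  )
  summary <- result[c("gene", "cell_type", "state", "gwas_ancestry",
                      "eqtl_ancestry", "n_snps", "pearson_r_p",
                      "pearson_r_beta", "p_value", "slope", "intercept",
                      "ci95", "alpha", "direction")]
  out <- list(table = tab, summary = summary)
  if (!is.null(path)) {
    utils::write.table(tab, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(out))
  }
  out
}

#' Scatter plot of a locus comparison
#'
#' Draws the beta-beta (or p-p) panel of a locus comparison with the
#' fitted line. Requires ggplot2.
#'
#' @param pair A \code{harmonised_pair}.
#' @param what \code{"beta"} or \code{"p"}.
#' @return A ggplot object.
#' @export
plot_locus_compare <- function(pair, what = c("beta", "p")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_locus_compare requires ggplot2")
  }
  what <- match.arg(what)
  d <- pair$data
  if (what == "beta") {
    df <- data.frame(x = d$beta_a, y = d$beta_b)
    labs <- c("GWAS beta", "eQTL beta")
  } else {
    df <- data.frame(x = -log10(d$p_a), y = -log10(d$p_b))
    labs <- c("GWAS -log10 p", "eQTL -log10 p")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = labs[1L], y = labs[2L]) +
    ggplot2::theme_minimal()
}
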