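#' Construct a gene x (cell type, state) expression matrix
#'
#' Container for raw TPM values of genes across cell-type/activation-state
#' column pairs, with an ancestry label. Column pairs must be unique and
#' TPM non-negative.
#'
#' @param tpm Numeric matrix, genes in rows, (cell type, state) columns.
#' @param genes Gene identifiers (row names).
#' @param cell_type,state Character vectors labelling each column.
#' @param ancestry Ancestry label of the donors.
#' @return An object of class \code{expr_matrix}.
#' @export
expr_matrix <- function(tpm, genes, cell_type, state, ancestry = "multi") {
  tpm <- as.matrix(tpm)
  stopifnot(length(genes) == nrow(tpm),
            length(cell_type) == ncol(tpm),
            length(state) == ncol(tpm))
  if (any(!is.finite(tpm)) || any(tpm < 0)) {
    stop("TPM values must be finite and non-negative")
  }
  if (anyDuplicated(paste(cell_type, state))) {
    stop("(cell_type, state) column pairs must be unique")
  }
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  dimnames(tpm) <- list(genes, paste(cell_type, state, sep = "|"))
  structure(
    list(tpm = tpm, genes = as.character(genes),
         cell_type = as.character(cell_type), state = as.character(state),
         ancestry = ancestry),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d columns (%d cell types x %d states), ancestry=%s\n",
              nrow(x$tpm), ncol(x$tpm), length(unique(x$cell_type)),
              length(unique(x$state)), x$ancestry))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Expects a headered tab-delimited file whose first column is the gene
#' identifier and whose remaining column names are
#' \code{cellType|state} pairs.
#'
#' @param path Path to the file.
#' @param ancestry Ancestry label to attach.
#' @return An \code{expr_matrix}.
#' @export
read_expression <- function(path, ancestry = "multi") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  labels <- strsplit(colnames(m), "|", fixed = TRUE)
  if (any(lengths(labels) != 2L)) {
    stop("column headers must be 'cellType|state' pairs")
  }
  expr_matrix(m, genes,
              cell_type = vapply(labels, `[`, "", 1L),
              state = vapply(labels, `[`, "", 2L),
              ancestry = ancestry)
}

#' Write an expression matrix to TSV
#' @param x An \code{expr_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = x$genes, x$tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Proportion-of-maximum expression of one gene
#'
#' Normalises a TPM row by its maximum, the "proportion of expression"
#' metric used to compare a gene across cell types and activation states.
#' An all-zero row maps to all-zero proportions.
#'
#' @param tpm_row Non-negative numeric vector.
#' @return Numeric vector of proportions in \code{[0, 1]}.
#' @examples
#' proportion_of_expression(c(10, 5, 0))
#' @export
proportion_of_expression <- function(tpm_row) {
  if (any(!is.finite(tpm_row)) || any(tpm_row < 0)) {
    stop("TPM values must be finite and non-negative")
  }
  m <- max(tpm_row)
  if (m == 0) return(rep(0, length(tpm_row)))
  tpm_row / m
}

#' Tau expression-specificity index
#'
#' Computes \code{tau = sum_i (1 - x_i) / (N - 1)}, where \code{x_i} are
#' the expression components normalised by the maximal component and
#' \code{N} is the number of categories (tissues, cell types or states).
#' Uniform expression gives 0; expression confined to a single category
#' gives 1. The statistic is invariant to positive rescaling of the input.
#'
#' @param x Non-negative expression vector with at least 2 components, not
#'   all zero (raw TPM or proportions; both give the same tau).
#' @return tau in \code{[0, 1]}.
#' @examples
#' tau(c(1, 1, 1, 1))   # 0
#' tau(c(1, 0, 0, 0))   # 1
#' tau(c(1, 0.5))       # 0.5
#' @export
tau <- function(x) {
  if (length(x) < 2L) stop("tau is undefined for fewer than 2 components")
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("expression values must be finite and non-negative")
  }
  if (max(x) == 0) stop("tau is undefined for an all-zero vector")
  xn <- x / max(x)
  sum(1 - xn) / (length(x) - 1L)
}

## Fixed tie-break orders: cell types alphabetically, states in the
## documented biological order.
state_rank <- function(states, state_order) {
  r <- match(states, state_order)
  r[is.na(r)] <- length(state_order) + rank(states[is.na(r)],
                                            ties.method = "first")
  r
}

#' Maximal cell type/state and specificity statistics for one gene
#'
#' Implements the per-gene expression summary: the cell type of the
#' globally maximal (cell type, state) column; the cell-type tau computed
#' over per-cell-type maxima across states (each cell type represented by
#' its maximal cell state); and, within the maximal cell type, the
#' activation-state tau and the state with maximal expression (reported as
#' \code{"-"} when unstimulated cells are maximal). Ties are broken by a
#' fixed order — cell types alphabetically, states unstimulated <
#' influenza < SARS-CoV-2 — and logged via a \code{tie} flag.
#'
#' @param gene Gene identifier present in \code{matrix}.
#' @param matrix An \code{expr_matrix}.
#' @param flatten Compute the cell-type tau over all (cell type, state)
#'   columns instead of per-cell-type maxima (default FALSE).
#' @param state_order Documented tie-break/collapse order of states.
#' @return A one-row data.frame: \code{gene}, \code{expressed} (any
#'   TPM > 0), \code{max_cell_type}, \code{max_state}, \code{tau_celltype},
#'   \code{tau_state}, \code{tie}.
#' @export
max_cell_state <- function(gene, matrix, flatten = FALSE,
                           state_order = ACTIVATION_STATES) {
  stopifnot(inherits(matrix, "expr_matrix"))
  i <- match(gene, matrix$genes)
  if (is.na(i)) stop("gene not found: ", gene)
  row <- matrix$tpm[i, ]
  if (max(row) == 0) {
    return(data.frame(gene = gene, expressed = FALSE,
                      max_cell_type = NA_character_,
                      max_state = NA_character_,
                      tau_celltype = NA_real_, tau_state = NA_real_,
                      tie = FALSE, stringsAsFactors = FALSE))
  }
  ## deterministic column order: cell type alphabetical, then state order
  ord <- order(matrix$cell_type, state_rank(matrix$state, state_order))
  ct <- matrix$cell_type[ord]
  st <- matrix$state[ord]
  v <- row[ord]

  imax <- which.max(v)  # first max in tie-break order
  tie <- sum(v == v[imax]) > 1L
  max_cell_type <- ct[imax]
  if (tie) {
    message("tie for maximal expression of ", gene,
            "; broken by fixed label order")
  }

  ## cell-type axis: each cell type represented by its maximal cell state
  per_ct <- tapply(v, ct, max)
  per_ct <- per_ct[sort(names(per_ct))]
  tau_celltype <- if (flatten) tau(v) else tau(as.numeric(per_ct))

  ## state axis within the maximal cell type
  in_ct <- ct == max_cell_type
  v_st <- v[in_ct]
  st_ct <- st[in_ct]
  tau_state <- if (length(v_st) >= 2L && max(v_st) > 0) tau(v_st) else NA_real_
  ismax <- which.max(v_st)
  max_state <- if (st_ct[ismax] == state_order[1L]) "-" else st_ct[ismax]

  data.frame(gene = gene, expressed = TRUE,
             max_cell_type = max_cell_type, max_state = max_state,
             tau_celltype = tau_celltype, tau_state = tau_state,
             tie = tie, stringsAsFactors = FALSE)
}

#' Call a gene expressed
#'
#' A gene is called expressed when its maximal TPM over all cell types and
#' states reaches \code{threshold} (inclusive). The detection criterion is
#' a package default (1 TPM), configurable because no community standard
#' exists.
#'
#' @param tpm_row Non-negative TPM vector.
#' @param threshold Detection threshold (>= 0), default 1 TPM.
#' @return Logical scalar.
#' @export
expressed_call <- function(tpm_row, threshold = 1) {
  if (threshold < 0) stop("`threshold` must be non-negative")
  max(tpm_row) >= threshold
}

#' Per-gene specificity table for an expression matrix
#'
#' Applies [max_cell_state()] and [expressed_call()] to every gene.
#'
#' @param matrix An \code{expr_matrix}.
#' @param threshold Expression-call threshold in TPM.
#' @param flatten Passed to [max_cell_state()].
#' @return data.frame, one row per gene, of class \code{specificity_result}.
#' @export
specificity_table <- function(matrix, threshold = 1, flatten = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  rows <- suppressMessages(
    lapply(matrix$genes, max_cell_state, matrix = matrix, flatten = flatten)
  )
  out <- do.call(rbind, rows)
  out$expressed <- apply(matrix$tpm, 1L, expressed_call,
                         threshold = threshold)
  class(out) <- c("specificity_result", "data.frame")
  out
}

#' Long-format proportion-of-expression table
#'
#' Serialises per-gene proportions of maximal expression across columns,
#' heatmap-ready.
#'
#' @param matrix An \code{expr_matrix}.
#' @return data.frame with columns \code{gene}, \code{cell_type},
#'   \code{state}, \code{tpm}, \code{proportion}.
#' @export
proportion_table <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  prop <- t(apply(matrix$tpm, 1L, proportion_of_expression))
  data.frame(
    gene = rep(matrix$genes, each = ncol(matrix$tpm)),
    cell_type = rep(matrix$cell_type, times = nrow(matrix$tpm)),
    state = rep(matrix$state, times = nrow(matrix$tpm)),
    tpm = as.vector(t(matrix$tpm)),
    proportion = as.vector(t(prop)),
    stringsAsFactors = FALSE
  )
}

#' Compare tau between two gene groups
#'
#' Welch (unequal-variance) two-sample t-test on cell-type tau between two
#' gene sets, e.g. genes maximal in myeloid versus NK cells.
#'
#' @param results A \code{specificity_result} data.frame.
#' @param group_a,group_b Character vectors of gene identifiers; each must
#'   contribute at least 2 genes with defined tau.
#' @return List of class \code{tau_comparison}: group means, \code{t_statistic},
#'   \code{p_value}, group sizes.
#' @export
compare_tau_groups <- function(results, group_a, group_b) {
  stopifnot(is.data.frame(results),
            all(c("gene", "tau_celltype") %in% names(results)))
  ta <- results$tau_celltype[match(group_a, results$gene)]
  tb <- results$tau_celltype[match(group_b, results$gene)]
  ta <- ta[!is.na(ta)]; tb <- tb[!is.na(tb)]
  if (length(ta) < 2L || length(tb) < 2L) {
    stop("each group needs at least 2 genes with defined tau")
  }
  if (stats::sd(ta) == 0 && stats::sd(tb) == 0) {
    ## degenerate constant groups: no variance to test against
    t_stat <- if (mean(ta) == mean(tb)) 0 else sign(mean(ta) - mean(tb)) * Inf
    p_val <- if (mean(ta) == mean(tb)) 1 else 0
  } else {
    ht <- stats::t.test(ta, tb, var.equal = FALSE)
    t_stat <- unname(ht$statistic)
    p_val <- ht$p.value
  }
  structure(
    list(mean_tau_a = mean(ta), mean_tau_b = mean(tb),
         n_a = length(ta), n_b = length(tb),
         t_statistic = t_stat, p_value = p_val),
    class = "tau_comparison"
  )
}

#' @export
print.tau_comparison <- function(x, ...) {
  cat(sprintf(
    "<tau_comparison> mean tau %.3f (n=%d) vs %.3f (n=%d); Welch t=%.3f, p=%.3g\n",
    x$mean_tau_a, x$n_a, x$mean_tau_b, x$n_b, x$t_statistic, x$p_value))
  invisible(x)
}
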