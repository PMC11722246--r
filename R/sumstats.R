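SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "p", "n")
SUMSTATS_NUMERIC <- c("pos", "eaf", "beta", "se", "p", "n")
ANCESTRY_LABELS <- c("AFR", "EAS", "EUR", "multi")

#' Construct a summary-statistics table
#'
#' Wraps a per-variant association data.frame (one GWAS, or one gene x cell
#' type x activation state eQTL) together with trait metadata, validating
#' each record: positive standard errors, non-identical upper-case alleles,
#' p-values in (0, 1], biallelic single-nucleotide variants only. Invalid
#' rows are dropped and counted; duplicate variant identifiers are an error.
#' Consistency between p and beta/se is checked to 10% relative tolerance
#' and flagged (column \code{flag_p_inconsistent}), never fatal, because
#' published files round p-values.
#'
#' @param data data.frame with columns \code{rsid}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}, \code{eaf},
#'   \code{beta}, \code{se}, \code{p}, \code{n}. \code{eaf} may be NA
#'   (fill later with [annotate_maf()]).
#' @param trait Trait name.
#' @param ancestry One of \code{"AFR"}, \code{"EAS"}, \code{"EUR"},
#'   \code{"multi"}.
#' @param type \code{"gwas"} or \code{"eqtl"}.
#' @param gene,cell_type,state eQTL metadata (ignored for GWAS).
#' @param trait_type \code{"cc"} (case-control, log-odds betas) or
#'   \code{"quant"}; drives the effect-prior SD convention in the
#'   colocalisation engine.
#'
#' @return An object of class \code{sumstats}: list with \code{metadata},
#'   \code{data} and a \code{log} of dropped-row counts.
#' @seealso [read_sumstats()], [harmonise()], [extract_window()]
#' @export
sumstats <- function(data, trait = "trait", ancestry = "EUR", type = "gwas",
                     gene = NA_character_, cell_type = NA_character_,
                     state = NA_character_,
                     trait_type = if (type == "gwas") "cc" else "quant") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(SUMSTATS_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!ancestry %in% ANCESTRY_LABELS) {
    stop("`ancestry` must be one of ", paste(ANCESTRY_LABELS, collapse = ", "))
  }
  type <- match.arg(type, c("gwas", "eqtl"))
  trait_type <- match.arg(trait_type, c("cc", "quant"))

  df <- data[, SUMSTATS_COLS, drop = FALSE]
  df$rsid <- as.character(df$rsid)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in SUMSTATS_NUMERIC) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }

  n_in <- nrow(df)
  ## numeric fields other than eaf must parse
  bad_numeric <- rowSums(is.na(df[, setdiff(SUMSTATS_NUMERIC, "eaf")])) > 0
  ## record invariants
  bad_se <- !bad_numeric & df$se <= 0
  bad_alleles <- df$effect_allele == df$other_allele |
    !(df$effect_allele %in% DNA_BASES) | !(df$other_allele %in% DNA_BASES)
  bad_p <- !bad_numeric & (df$p <= 0 | df$p > 1)
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  drop <- bad_numeric | bad_se | bad_alleles | bad_p | bad_eaf
  df <- df[!drop, , drop = FALSE]

  dup <- duplicated(df$rsid)
  if (any(dup)) {
    stop("duplicate rsid(s) in summary statistics: ",
         paste(unique(df$rsid[dup]), collapse = ", "))
  }

  ## p vs beta/se cross-check (flag only)
  p_implied <- 2 * stats::pnorm(-abs(df$beta / df$se))
  rel <- abs(df$p - p_implied) / pmax(p_implied, .Machine$double.xmin)
  df$flag_p_inconsistent <- is.finite(rel) & rel > 0.10 & p_implied > 1e-300
  rownames(df) <- NULL

  log <- list(
    n_input = n_in,
    n_kept = nrow(df),
    n_dropped = sum(drop),
    n_dropped_numeric = sum(bad_numeric),
    n_dropped_se = sum(bad_se & !bad_numeric),
    n_dropped_alleles = sum(bad_alleles & !bad_numeric & !bad_se),
    n_dropped_p = sum(bad_p),
    n_flagged_p = sum(df$flag_p_inconsistent)
  )

  structure(
    list(
      metadata = list(trait = trait, ancestry = ancestry, type = type,
                      gene = gene, cell_type = cell_type, state = state,
                      trait_type = trait_type, build = "GRCh38"),
      data = df,
      log = log
    ),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<sumstats> %s [%s, %s] %d variants\n", m$trait, m$type,
              m$ancestry, nrow(x$data)))
  if (m$type == "eqtl") {
    cat(sprintf("  gene=%s cell_type=%s state=%s\n", m$gene, m$cell_type,
                m$state))
  }
  if (x$log$n_dropped > 0) {
    cat(sprintf("  %d invalid row(s) dropped on input\n", x$log$n_dropped))
  }
  invisible(x)
}

#' Read a summary-statistics file
#'
#' Reads a headered tab-delimited file in the package's GWAS-SSF-like
#' format (columns \code{rsid chrom pos effect_allele other_allele eaf beta
#' se p n}). eQTL files may carry constant \code{gene}, \code{cell_type},
#' \code{state} and \code{ancestry} columns, which are folded into the
#' table metadata; alternatively a JSON sidecar \code{<path>.json} holding
#' the metadata is honoured. Rows violating record invariants are dropped
#' with a logged count; a missing mandatory column is a hard error.
#'
#' @param path Path to the tab-delimited file.
#' @param ... Metadata overrides passed to [sumstats()] (\code{trait},
#'   \code{ancestry}, \code{type}, ...).
#' @return A \code{sumstats} object.
#' @export
read_sumstats <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  meta <- list(...)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (k in setdiff(names(side), names(meta))) meta[[k]] <- side[[k]]
  }
  ## constant annotation columns -> metadata
  for (k in c("gene", "cell_type", "state", "ancestry")) {
    if (k %in% names(df)) {
      vals <- unique(df[[k]])
      if (length(vals) == 1L && !k %in% names(meta)) meta[[k]] <- vals
      df[[k]] <- NULL
    }
  }
  meta <- meta[intersect(names(meta), names(formals(sumstats)))]
  meta$data <- df
  do.call(sumstats, meta)
}

#' Write a summary-statistics table
#'
#' Writes the tab-delimited format read by [read_sumstats()] plus a JSON
#' metadata sidecar (\code{<path>.json}) carrying trait, ancestry, type and
#' eQTL labels, so a round trip is value-identical.
#'
#' @param x A \code{sumstats} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  df <- x$data
  df$flag_p_inconsistent <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- x$metadata
  jsonlite::write_json(meta[!vapply(meta, function(v) all(is.na(v)), TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Remap coordinates between genome builds via a lookup table
#'
#' Replaces positions using a user-supplied two-build coordinate table
#' (e.g. exported from a liftover run); chain-file parsing is deliberately
#' out of scope. Variants absent from the mapping are dropped and counted.
#'
#' @param x A \code{sumstats} object.
#' @param mapping data.frame with columns \code{chrom}, \code{pos},
#'   \code{new_chrom}, \code{new_pos} (source build -> target build).
#' @return A \code{sumstats} object on the target build; the drop count is
#'   recorded in \code{$log$n_unmapped}.
#' @export
map_build <- function(x, mapping) {
  stopifnot(inherits(x, "sumstats"), is.data.frame(mapping))
  need <- c("chrom", "pos", "new_chrom", "new_pos")
  if (!all(need %in% names(mapping))) {
    stop("mapping must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(x$data$chrom, x$data$pos)
  mkey <- paste(mapping$chrom, mapping$pos)
  idx <- match(key, mkey)
  n_unmapped <- sum(is.na(idx))
  keep <- !is.na(idx)
  df <- x$data[keep, , drop = FALSE]
  df$chrom <- as.character(mapping$new_chrom[idx[keep]])
  df$pos <- as.numeric(mapping$new_pos[idx[keep]])
  rownames(df) <- NULL
  x$data <- df
  x$log$n_unmapped <- n_unmapped
  x
}

#' Assign rsIDs from a variant-location lookup
#'
#' Fills the \code{rsid} column by matching chromosome, position and the
#' unordered allele pair against a lookup table. When several lookup rows
#' match one variant, the lexicographically smallest rsID is kept and the
#' conflict counted. Unmatched variants keep a synthetic
#' \code{chr<chrom>:<pos>:<other>:<effect>} identifier.
#'
#' @param x A \code{sumstats} object.
#' @param snp_locations data.frame with columns \code{chrom}, \code{pos},
#'   \code{allele1}, \code{allele2}, \code{rsid}.
#' @return A \code{sumstats} object with rsids assigned;
#'   \code{$log$n_rsid_conflicts} and \code{$log$n_rsid_unmatched} record
#'   the bookkeeping.
#' @export
assign_rsids <- function(x, snp_locations) {
  stopifnot(inherits(x, "sumstats"), is.data.frame(snp_locations))
  need <- c("chrom", "pos", "allele1", "allele2", "rsid")
  if (!all(need %in% names(snp_locations))) {
    stop("snp_locations must have columns: ", paste(need, collapse = ", "))
  }
  lk <- snp_locations
  lk$chrom <- as.character(lk$chrom)
  lk$allele1 <- toupper(as.character(lk$allele1))
  lk$allele2 <- toupper(as.character(lk$allele2))
  ## allele-order-insensitive key
  amin <- pmin(lk$allele1, lk$allele2)
  amax <- pmax(lk$allele1, lk$allele2)
  lkey <- paste(lk$chrom, lk$pos, amin, amax)

  df <- x$data
  qkey <- paste(df$chrom, df$pos,
                pmin(df$effect_allele, df$other_allele),
                pmax(df$effect_allele, df$other_allele))
  n_conflicts <- 0L
  assigned <- character(nrow(df))
  split_rsids <- split(lk$rsid, lkey)
  hit <- split_rsids[qkey]
  for (i in seq_len(nrow(df))) {
    cand <- hit[[i]]
    if (is.null(cand)) {
      assigned[i] <- sprintf("chr%s:%d:%s:%s", df$chrom[i],
                             as.integer(df$pos[i]),
                             df$other_allele[i], df$effect_allele[i])
    } else {
      cand <- sort(unique(cand))
      if (length(cand) > 1L) n_conflicts <- n_conflicts + 1L
      assigned[i] <- cand[1L]
    }
  }
  if (anyDuplicated(assigned)) {
    stop("rsid assignment produced duplicates: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
  }
  df$rsid <- assigned
  x$data <- df
  x$log$n_rsid_conflicts <- n_conflicts
  x$log$n_rsid_unmatched <- sum(startsWith(assigned, "chr"))
  x
}

#' Fill missing effect-allele frequencies from a reference panel
#'
#' Fills \code{eaf} where missing using an ancestry-specific frequency
#' panel keyed on rsID and allele; when the panel stores the frequency of
#' the other allele the complement is used. Existing frequencies are never
#' overwritten. Variants still lacking a frequency are flagged (column
#' \code{flag_no_maf}), not dropped, since the Bayes-factor engine only
#' requires MAF on its sample-size path.
#'
#' @param x A \code{sumstats} object.
#' @param freq_panel data.frame with columns \code{rsid}, \code{allele},
#'   \code{freq} and optionally \code{ancestry} (filtered to the table's
#'   ancestry when present).
#' @return A \code{sumstats} object with \code{eaf} filled where possible.
#' @export
annotate_maf <- function(x, freq_panel) {
  stopifnot(inherits(x, "sumstats"), is.data.frame(freq_panel))
  need <- c("rsid", "allele", "freq")
  if (!all(need %in% names(freq_panel))) {
    stop("freq_panel must have columns: ", paste(need, collapse = ", "))
  }
  fp <- freq_panel
  if ("ancestry" %in% names(fp) && !is.na(x$metadata$ancestry)) {
    fp <- fp[fp$ancestry == x$metadata$ancestry, , drop = FALSE]
  }
  fp$allele <- toupper(as.character(fp$allele))
  df <- x$data
  miss <- which(is.na(df$eaf))
  if (length(miss) > 0) {
    kEff <- paste(df$rsid[miss], df$effect_allele[miss])
    kOth <- paste(df$rsid[miss], df$other_allele[miss])
    pkey <- paste(fp$rsid, fp$allele)
    iEff <- match(kEff, pkey)
    iOth <- match(kOth, pkey)
    df$eaf[miss] <- ifelse(!is.na(iEff), fp$freq[iEff],
                           ifelse(!is.na(iOth), 1 - fp$freq[iOth], NA_real_))
  }
  df$flag_no_maf <- is.na(df$eaf)
  x$data <- df
  x$log$n_no_maf <- sum(df$flag_no_maf)
  x
}
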