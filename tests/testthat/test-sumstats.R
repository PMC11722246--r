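test_that("read_sumstats validates records and logs drops", {
  df <- toy_sumstats_df(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  x <- read_sumstats(path, trait = "toy", ancestry = "EUR", type = "gwas")
  expect_s3_class(x, "sumstats")
  expect_equal(nrow(x$data), 3)
  expect_equal(x$log$n_dropped, 0)

  # se = 0 violates the record invariant: dropped, counted
  df_bad <- toy_sumstats_df(3)
  df_bad$se[2] <- 0
  write.table(df_bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  x2 <- read_sumstats(path, trait = "toy")
  expect_equal(nrow(x2$data), 2)
  expect_equal(x2$log$n_dropped, 1)

  # duplicate rsid is a hard error naming the rsid
  df_dup <- toy_sumstats_df(3)
  df_dup$rsid[3] <- "rs1"
  write.table(df_dup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "rs1")

  # missing mandatory column is a hard error
  df_mc <- toy_sumstats_df(3)
  df_mc$se <- NULL
  write.table(df_mc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "se")

  # unparseable numeric: row dropped, not fatal
  df_np <- toy_sumstats_df(3)
  df_np$beta <- as.character(df_np$beta)
  df_np$beta[1] <- "not_a_number"
  write.table(df_np, path, sep = "\t", quote = FALSE, row.names = FALSE)
  x3 <- read_sumstats(path)
  expect_equal(nrow(x3$data), 2)
})

test_that("p/beta/se inconsistency is flagged, never fatal", {
  df <- toy_sumstats_df(3)
  df$p[1] <- df$p[1] * 2  # 100% relative error on a small p
  x <- sumstats(df)
  expect_equal(nrow(x$data), 3)
  expect_true(x$data$flag_p_inconsistent[1])
  expect_false(any(x$data$flag_p_inconsistent[-1]))
})

test_that("write/read round trip is value-identical", {
  x <- sumstats(toy_sumstats_df(6), trait = "toy", ancestry = "EAS",
                type = "eqtl", gene = "SNCA", cell_type = "CD16_monocyte",
                state = "unstimulated")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path, type = "eqtl")
  for (col in c("rsid", "chrom", "effect_allele", "other_allele")) {
    expect_identical(y$data[[col]], x$data[[col]])
  }
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    expect_equal(y$data[[col]], x$data[[col]], tolerance = 1e-12)
  }
  expect_equal(y$metadata$gene, "SNCA")
  expect_equal(y$metadata$ancestry, "EAS")
})

test_that("map_build remaps per lookup and drops unmapped variants", {
  x <- sumstats(toy_sumstats_df(5))
  # identity mapping leaves the table unchanged
  ident <- data.frame(chrom = x$data$chrom, pos = x$data$pos,
                      new_chrom = x$data$chrom, new_pos = x$data$pos)
  expect_equal(map_build(x, ident)$data[, 1:10], x$data[, 1:10])
  # a variant absent from the mapping is dropped
  y <- map_build(x, ident[-2, ])
  expect_equal(nrow(y$data), 4)
  expect_equal(y$log$n_unmapped, 1)
  expect_false("rs2" %in% y$data$rsid)
  # 2 of 5 remapped (mapping covers all 5): 5 rows out, 2 new positions
  mp <- ident
  mp$new_pos[c(1, 4)] <- mp$new_pos[c(1, 4)] + 777
  z <- map_build(x, mp)
  expect_equal(nrow(z$data), 5)
  expect_equal(sum(z$data$pos != x$data$pos), 2)
  expect_equal(z$data$pos[c(1, 4)], x$data$pos[c(1, 4)] + 777)
})

test_that("assign_rsids matches on position and unordered alleles", {
  df <- toy_sumstats_df(3, effect_allele = c("A", "A", "C"),
                        other_allele = c("G", "G", "T"))
  x <- sumstats(df)
  lookup <- data.frame(
    chrom = "1", pos = df$pos[1:2],
    allele1 = c("A", "G"), allele2 = c("G", "A"),  # second is allele-swapped
    rsid = c("rs100", "rs200"), stringsAsFactors = FALSE)
  y <- assign_rsids(x, lookup)
  expect_equal(y$data$rsid[1], "rs100")
  expect_equal(y$data$rsid[2], "rs200")  # swapped lookup order still matches
  # no match: synthetic chrom:pos:ref:alt identifier retained
  expect_equal(y$data$rsid[3],
               sprintf("chr1:%d:T:C", as.integer(df$pos[3])))
  expect_equal(y$log$n_rsid_unmatched, 1)
  # conflicting rsids at one position resolve to the smallest, logged
  lookup2 <- rbind(lookup,
                   data.frame(chrom = "1", pos = df$pos[1],
                              allele1 = "A", allele2 = "G", rsid = "rs050"))
  y2 <- assign_rsids(x, lookup2)
  expect_equal(y2$data$rsid[1], "rs050")
  expect_equal(y2$log$n_rsid_conflicts, 1)
})

test_that("annotate_maf fills missing frequencies with the complement rule", {
  df <- toy_sumstats_df(3)
  df$eaf <- c(NA, NA, NA)
  x <- sumstats(df, ancestry = "EUR")
  panel <- data.frame(
    rsid = c("rs1", "rs2"),
    allele = c("A", "G"),  # rs2 stores the other allele's frequency
    freq = c(0.23, 0.23),
    stringsAsFactors = FALSE)
  y <- annotate_maf(x, panel)
  expect_equal(y$data$eaf[1], 0.23)
  expect_equal(y$data$eaf[2], 0.77)  # complement of the other allele
  expect_true(is.na(y$data$eaf[3]))
  expect_true(y$data$flag_no_maf[3])  # flagged, not dropped
  expect_equal(nrow(y$data), 3)
  # existing eaf preserved
  df2 <- toy_sumstats_df(1)
  df2$eaf <- 0.4
  y2 <- annotate_maf(sumstats(df2), panel[1, ])
  expect_equal(y2$data$eaf, 0.4)
})

test_that("extract_window merges overlapping intervals and finds leads", {
  # one significant SNP at 2 Mb with a 1 Mb window
  df <- toy_sumstats_df(3, start_pos = 2e6 - 1000)
  df$pos <- c(2e6 - 1000, 2e6, 2e6 + 1000)
  df$beta <- c(0.01, 0.2, 0.01)
  df$p <- 2 * pnorm(-abs(df$beta / df$se))
  x <- sumstats(df)
  w <- extract_window(x, sig_threshold = 5e-8, window = 1e6)
  expect_length(w, 1)
  expect_equal(w[[1]]$metadata$window$start, 1e6)
  expect_equal(w[[1]]$metadata$window$end, 3e6)
  expect_equal(w[[1]]$metadata$window$lead_rsid, "rs2")

  # two significant SNPs 500 kb apart merge into one window
  df2 <- toy_sumstats_df(2)
  df2$pos <- c(2e6, 2.5e6)
  df2$beta <- c(0.2, 0.3)
  df2$p <- 2 * pnorm(-abs(df2$beta / df2$se))
  w2 <- extract_window(sumstats(df2), window = 1e6)
  expect_length(w2, 1)
  expect_equal(w2[[1]]$metadata$window$start, 1e6)
  expect_equal(w2[[1]]$metadata$window$end, 3.5e6)

  # no significant SNP: empty list, not an error
  expect_message(w0 <- extract_window(sumstats(toy_sumstats_df(3))),
                 "no variants")
  expect_length(w0, 0)
})

test_that("windows across chromosomes match a brute-force merge oracle", {
  set.seed(41)
  df <- toy_sumstats_df(40)
  df$chrom <- rep(c("1", "7"), each = 20)
  df$pos <- rep(seq(1e6, 20e6, length.out = 20), 2)
  df$beta <- rep(0.002, 40)
  sig_idx <- c(3, 5, 28)  # two on chr1 close together, one on chr7
  df$beta[sig_idx] <- 0.25
  df$p <- 2 * pnorm(-abs(df$beta / df$se))
  x <- sumstats(df)
  win <- 1.5e6
  got <- extract_window(x, window = win)

  # oracle: brute-force interval merge per chromosome
  sig <- df[df$p < 5e-8, ]
  expected <- list()
  for (chr in unique(sig$chrom)) {
    s <- sig[sig$chrom == chr, ]
    ivs <- cbind(pmax(0, s$pos - win), s$pos + win)
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    merged <- ivs[1, , drop = FALSE]
    if (nrow(ivs) > 1) for (k in 2:nrow(ivs)) {
      last <- nrow(merged)
      if (ivs[k, 1] < merged[last, 2]) {
        merged[last, 2] <- max(merged[last, 2], ivs[k, 2])
      } else merged <- rbind(merged, ivs[k, ])
    }
    for (k in seq_len(nrow(merged))) {
      expected[[length(expected) + 1]] <- list(chrom = chr,
                                               start = merged[k, 1],
                                               end = merged[k, 2])
    }
  }
  expect_length(got, length(expected))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$metadata$window$chrom, expected[[i]]$chrom)
    expect_equal(got[[i]]$metadata$window$start, expected[[i]]$start)
    expect_equal(got[[i]]$metadata$window$end, expected[[i]]$end)
    inside <- df[df$chrom == expected[[i]]$chrom &
                   df$pos >= expected[[i]]$start &
                   df$pos < expected[[i]]$end, ]
    expect_equal(got[[i]]$metadata$window$lead_rsid,
                 inside$rsid[which.min(inside$p)])
  }
})
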