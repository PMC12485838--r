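toy_counts <- function(n_genes = 50L, seed = 71L, factor = 1) {
  set.seed(seed)
  mu <- rlnorm(n_genes, log(200), 0.5)
  m <- cbind(
    matrix(rpois(n_genes * 2L, mu), ncol = 2L),
    matrix(rpois(n_genes * 2L, mu * factor), ncol = 2L)
  )
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- c("control_1", "control_2", "induced_1", "induced_2")
  list(counts = m,
       design = data.frame(sample = colnames(m),
                           condition = rep(c("control", "induced"), each = 2L)))
}

test_that("identical conditions give log2fc exactly 0", {
  tc <- toy_counts()
  m <- tc$counts
  m[, 3:4] <- m[, 1:2]
  expr <- compute_log2fc(m, tc$design)
  expect_true(all(expr$log2fc == 0))
  expect_true(all(expr$baseMean >= 0))
})

test_that("a clean 2x induction estimates log2fc near 1", {
  # counts are exact (no sampling noise); only a minority of genes shift so
  # the median-of-ratios size factors stay equal across samples
  n <- 200L
  base <- round(seq(100, 2000, length.out = n))
  shifted <- seq_len(40L)
  ind <- base
  ind[shifted] <- 2L * base[shifted]
  m <- cbind(base, base, ind, ind)
  rownames(m) <- sprintf("g%03d", 1:n)
  colnames(m) <- c("control_1", "control_2", "induced_1", "induced_2")
  design <- data.frame(sample = colnames(m),
                       condition = rep(c("control", "induced"), each = 2))
  expr <- compute_log2fc(m, design)
  sf <- attr(expr, "size_factors")
  expect_lt(max(abs(sf - sf[1])), 1e-12)
  # pseudocount distortion stays below 0.01 at means >= 100
  expect_true(all(abs(expr$log2fc[shifted] - 1) < 0.01))
  expect_true(all(expr$log2fc[-shifted] == 0))
})

test_that("all-zero genes are retained with zero baseMean and lfc", {
  tc <- toy_counts()
  m <- tc$counts
  m[5, ] <- 0L
  expr <- compute_log2fc(m, tc$design)
  expect_equal(expr$baseMean[5], 0)
  expect_equal(expr$log2fc[5], 0)
  expect_error(compute_log2fc(m[, c(1, 3)],
                              tc$design[c(1, 3), ]), "2 samples")
})

test_that("DE table ingest validates columns and round-trips", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(gene_id = c("a", "b", "c"),
                   baseMean = c(10.5, 200, 3),
                   log2FoldChange = c(-1.2, 0.3, 2.5),
                   padj = c(0.001, NA, 0.2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- ingest_de_table(path)
  expect_equal(nrow(expr), 3L)
  expect_equal(expr$log2fc, df$log2FoldChange)
  expect_equal(expr$padj, df$padj)
  # significance view: padj <= 0.05 and |lfc| > 1; missing padj excluded
  sig <- significant_genes(expr)
  expect_equal(sig$gene_id, "a")
  # round trip
  out <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = expr$gene_id, baseMean = expr$baseMean,
                         log2FoldChange = expr$log2fc, padj = expr$padj),
              out, sep = "\t", quote = FALSE, row.names = FALSE)
  again <- ingest_de_table(out)
  expect_equal(again, expr)
  bad <- tempfile(fileext = ".tsv")
  write.table(df[, -2], bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(ingest_de_table(bad), "baseMean")
})

test_that("cdf is a right-continuous step reaching 1, matching a rank oracle", {
  expect_equal(cdf(0), data.frame(value = 0, fraction = 1))
  out <- cdf(c(1, 2, 2, 3))
  expect_equal(out$value, c(1, 2, 3))
  expect_equal(out$fraction, c(0.25, 0.75, 1))
  expect_error(cdf(numeric(0)), "empty")
  set.seed(73)
  v <- rnorm(200)
  out <- cdf(v)
  expect_true(all(diff(out$fraction) > 0))
  expect_equal(tail(out$fraction, 1), 1)
  # oracle: sort-and-rank
  for (i in sample(nrow(out), 20L)) {
    expect_equal(out$fraction[i], mean(v <= out$value[i]))
  }
})

test_that("median of log2 fold changes commutes with log2 of median (odd n)", {
  set.seed(74)
  fc <- rlnorm(101, 0, 1)
  expect_equal(median(log2(fc)), log2(median(fc)))
})

sim_binned <- function(seed, delta = 1.0) {
  cfg <- sim_config(seed = seed, n_transcripts = 1000L,
                    utr5_range = c(20L, 40L), cds_range = c(60L, 120L),
                    utr3_range = c(60L, 120L), delta = delta)
  tx <- generate_transcriptome(cfg)
  tid <- tx$transcripts$transcript_id
  plan <- rbind(
    data.frame(transcript_id = tid[1:60], region = "utr3",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = tid[61:120], region = "utr3",
               motif = canonical_motif(), n_copies = 2L),
    data.frame(transcript_id = tid[121:160], region = "cds",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = tid[161:200], region = "utr5",
               motif = canonical_motif(), n_copies = 1L)
  )
  tx <- plant_motifs(tx, plan, seed = cfg$seed + 1L)
  cnt <- simulate_counts(tx, cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_transcriptome_gtf(tx, gtf)
  ann <- read_annotation(gtf)
  summ <- summarize_genes(tx, ann)
  expr <- compute_log2fc(cnt$counts, cnt$design)
  list(expr = expr, summ = summ, cfg = cfg)
}

test_that("site-count bins recover the suppression ordering", {
  s <- sim_binned(seed = 75L)
  b <- bin_by_site_count(s$expr, s$summ, count_space = "region")
  med <- setNames(b$summary$median_lfc, b$summary$label)
  expect_lt(med[["ge2"]], med[["one"]])
  expect_lt(med[["one"]], med[["unbound"]])
  expect_gte(med[["one"]], -1.3)
  expect_lte(med[["one"]], -0.7)
  # bins partition the filtered gene set
  members <- unlist(lapply(b$bins, `[[`, "gene_ids"))
  expect_equal(anyDuplicated(members), 0L)
  filtered <- s$expr$gene_id[s$expr$baseMean >= 10]
  expect_setequal(members, intersect(filtered, s$summ$gene_id))
  # per-bin CDFs are valid step functions
  for (bin in b$bins) {
    if (is.null(bin$cdf)) next
    expect_true(all(diff(bin$cdf$fraction) > 0))
    expect_equal(tail(bin$cdf$fraction, 1), 1)
  }
})

test_that("median lfc bins behave under the trivial cases", {
  expr <- structure(
    data.frame(gene_id = c("a", "b", "c"), baseMean = c(50, 50, 50),
               log2fc = c(-1, 0, 1), padj = NA_real_),
    class = c("expression_table", "data.frame"))
  summ <- data.frame(gene_id = c("a", "b", "c"), transcript_id = c("a", "b", "c"),
                     n_utr5 = 0L, n_cds = 0L, n_utr3 = c(1L, 1L, 1L),
                     n_in_clusters = 0L, n_clusters = 0L, bound = FALSE)
  b <- bin_by_site_count(expr, summ, count_space = "region")
  expect_equal(b$summary$median_lfc[b$summary$label == "one"], 0)
  # all genes below the expression filter: all bins empty
  b2 <- bin_by_site_count(expr, summ, min_basemean = 100)
  expect_true(all(b2$summary$n == 0L))
  expect_true(all(is.na(b2$summary$median_lfc)))
})

test_that("region bins isolate the 3'UTR effect", {
  s <- sim_binned(seed = 76L)
  b <- bin_by_region(s$expr, s$summ)
  med <- setNames(b$summary$median_lfc, b$summary$label)
  # motif-free genes anchor the comparison: residual normalization bias under
  # one-sided suppression shifts every bin equally
  expect_lt(abs(med[["cds"]] - med[["none"]]), 0.1)
  expect_lt(abs(med[["utr5"]] - med[["none"]]), 0.1)
  expect_lt(abs(med[["utr3_1"]] - med[["none"]] + s$cfg$delta), 0.3)
  members <- unlist(lapply(b$bins, `[[`, "gene_ids"))
  expect_equal(anyDuplicated(members), 0L)
})

test_that("region-bin priority sends multi-region genes to the 3'UTR bin", {
  expr <- structure(
    data.frame(gene_id = c("a", "b"), baseMean = 50,
               log2fc = c(-1, 0.5), padj = NA_real_),
    class = c("expression_table", "data.frame"))
  summ <- data.frame(gene_id = c("a", "b"), transcript_id = c("a", "b"),
                     n_utr5 = 0L, n_cds = c(1L, 1L), n_utr3 = c(1L, 0L),
                     n_in_clusters = 0L, n_clusters = 0L, bound = FALSE)
  b <- bin_by_region(expr, summ)
  expect_equal(b$bins$utr3_1$gene_ids, "a")
  expect_equal(b$bins$cds$gene_ids, "b")
})

test_that("null simulation keeps every bin median near zero", {
  s <- sim_binned(seed = 77L, delta = 0)
  b <- bin_by_site_count(s$expr, s$summ, count_space = "region")
  med <- b$summary$median_lfc[b$summary$n >= 20L]
  expect_true(all(abs(med) < 0.1))
})

test_that("the variant tile isolates canonical-motif suppression", {
  cfg <- sim_config(seed = 78L, n_transcripts = 1000L,
                    utr5_range = c(20L, 40L), cds_range = c(60L, 120L),
                    utr3_range = c(60L, 120L), delta = 1.0)
  tx <- generate_transcriptome(cfg)
  tid <- tx$transcripts$transcript_id
  variants <- enumerate_variants(canonical_motif())
  plan <- rbind(
    data.frame(transcript_id = tid[1:40], region = "utr3",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = tid[41:250], region = "utr3",
               motif = rep(variants$seq, each = 10L), n_copies = 1L)
  )
  tx <- plant_motifs(tx, plan, seed = cfg$seed + 1L)
  cnt <- simulate_counts(tx, cfg)
  gtf <- tempfile(fileext = ".gtf")
  write_transcriptome_gtf(tx, gtf)
  summ <- summarize_genes(tx, read_annotation(gtf))
  expr <- compute_log2fc(cnt$counts, cnt$design)
  tile <- variant_tile(expr, summ)
  expect_equal(nrow(tile), 22L)
  expect_equal(anyDuplicated(tile$label), 0L)
  canon <- tile$median_lfc[tile$label == "canonical"]
  vcells <- tile[tile$label != "canonical", ]
  expect_true(all(vcells$n > 0))
  expect_true(all(abs(vcells$median_lfc) < abs(canon) / 2))
  # cell identity: pos3C groups genes carrying ATCAATT and no canonical
  g_pos3C <- summ$gene_id[summ$var_pos3C]
  planted <- tx$placements$gene_id[tx$placements$motif == "ATCAATT"]
  expect_setequal(g_pos3C, planted)
})
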