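make_aln <- function(reads, mismatches = NULL) {
  mm <- mismatches %||% data.frame(
    read_id = character(0), reference_name = character(0), pos = integer(0),
    ref_base = character(0), read_base = character(0),
    stringsAsFactors = FALSE)
  structure(list(reads = reads, mismatches = mm,
                 n_skipped_indel = 0L, n_dropped_mismatch = 0L),
            class = "aligned_reads")
}

test_that("background rate applies the 12/11 uniform-substitution correction", {
  reads <- data.frame(
    read_id = sprintf("r%d", 1:10), reference_name = "t1",
    start = 0L, end = 20L, seq = strrep("A", 20),
    stringsAsFactors = FALSE)
  mm <- data.frame(read_id = c("r1", "r2"), reference_name = "t1",
                   pos = c(3L, 7L), ref_base = c("A", "G"),
                   read_base = c("G", "T"), stringsAsFactors = FALSE)
  bg <- estimate_background(make_aln(reads, mm))
  expect_equal(bg$aligned_bases, 200L)
  expect_equal(bg$n_non_t2c, 2L)
  expect_equal(bg$r_bg, (2 / 200) * (12 / 11))
  # T->C events do not enter the numerator
  mm2 <- rbind(mm, data.frame(read_id = "r3", reference_name = "t1",
                              pos = 9L, ref_base = "T", read_base = "C"))
  expect_equal(estimate_background(make_aln(reads, mm2))$n_non_t2c, 2L)
  empty <- make_aln(reads[0, ], mm[0, ])
  expect_error(estimate_background(empty), "aligned bases")
})

test_that("estimated background rate recovers the simulated mismatch rate", {
  cfg <- sim_config(seed = 31L, n_transcripts = 40L, p_conv = 0,
                    p_bg = 0.01, bg_read_rate = 0, read_depth = 100L)
  tx <- generate_transcriptome(cfg)
  plan <- data.frame(transcript_id = tx$transcripts$transcript_id,
                     region = "cds", motif = canonical_motif(), n_copies = 1L)
  tx <- plant_motifs(tx, plan, seed = cfg$seed + 1L)
  pc <- simulate_parclip(tx, cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(pc, tx, sam)
  aln <- read_alignments(sam, max_mismatches = Inf)
  bg <- estimate_background(aln)
  expect_gte(bg$aligned_bases, 1e5)
  expect_lt(abs(bg$r_bg - 0.01) / 0.01, 0.15)
})

test_that("poisson_tail matches direct pmf summation and its limits", {
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(1, 0), 0)
  # oracle: sum the pmf terms directly
  expect_equal(poisson_tail(4, 2),
               1 - exp(-2) * (1 + 2 + 2 + 4 / 3))
  for (mu in c(0.01, 0.1, 1, 2, 5, 10)) {
    for (k in 0:50) {
      oracle <- 1 - sum(exp(-mu) * mu^(seq_len(max(k, 0)) - 1) /
                          factorial(seq_len(max(k, 0)) - 1))
      if (k == 0) oracle <- 1
      expect_lt(abs(poisson_tail(k, mu) - oracle), 1e-12)
    }
  }
})

test_that("poisson_tail is monotone in k and in mu", {
  for (mu in c(0.05, 1, 7)) {
    p <- poisson_tail(0:30, mu)
    expect_true(all(diff(p) <= 0))
  }
  for (k in c(1L, 3L, 10L)) {
    p <- poisson_tail(k, seq(0.01, 10, length.out = 50))
    expect_true(all(diff(p) >= -1e-15))
  }
})

test_that("candidates are maximal coverage intervals above min depth", {
  reads <- data.frame(
    read_id = c("a", "b", "c", "d"),
    reference_name = "t1",
    start = c(0L, 5L, 10L, 50L), end = c(20L, 25L, 30L, 70L),
    seq = strrep("A", 20), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("AT", 50)))
  # single read: no candidate at default depth 3
  one <- build_candidates(make_aln(reads[1, ]), seqs)
  expect_equal(nrow(one), 0L)
  # three mutually overlapping reads merge into one candidate
  cand <- build_candidates(make_aln(reads), seqs)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 0L)
  expect_equal(cand$end, 30L)
  expect_equal(cand$read_count, 3L)
  expect_error(build_candidates(make_aln(transform(reads, reference_name = "zz")), seqs),
               "missing")
})

test_that("candidate formation equals a per-base coverage oracle", {
  set.seed(41)
  L <- 500L
  n <- 200L
  starts <- sample.int(L - 20L, n, replace = TRUE) - 1L
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:n), reference_name = "t1",
    start = starts, end = starts + 20L, seq = strrep("A", 20),
    stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(c(t1 = paste(
    sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")))
  cand <- build_candidates(make_aln(reads), seqs, min_depth = 1L)
  # oracle: per-base coverage, maximal nonzero runs
  cov <- integer(L)
  for (i in seq_len(n)) {
    idx <- (reads$start[i] + 1L):reads$end[i]
    cov[idx] <- cov[idx] + 1L
  }
  r <- rle(cov > 0L)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths
  oracle <- data.frame(start = starts0[r$values], end = ends[r$values])
  expect_equal(cand$start, oracle$start)
  expect_equal(cand$end, oracle$end)
  # read_count and covered_T oracle per candidate
  tpos <- strsplit(as.character(seqs[[1]]), "")[[1]] == "T"
  for (i in seq_len(nrow(cand))) {
    inside <- reads$start < cand$end[i] & reads$end > cand$start[i]
    expect_equal(cand$read_count[i], sum(inside))
    idx <- (cand$start[i] + 1L):cand$end[i]
    expect_equal(cand$covered_T_bases[i], sum(cov[idx][tpos[idx]]))
  }
})

test_that("cluster calling recovers planted sites with high precision", {
  fx <- fixture_planted()
  cl <- fx$clusters
  pl <- fx$txome$placements
  hit <- vapply(seq_len(nrow(pl)), function(i) {
    any(cl$reference_name == pl$transcript_id[i] &
          cl$start <= pl$start[i] & cl$end >= pl$start[i] + 7L)
  }, logical(1))
  recall <- mean(hit)
  true_cl <- vapply(seq_len(nrow(cl)), function(i) {
    any(pl$transcript_id == cl$reference_name[i] &
          pl$start >= cl$start[i] & pl$start + 7L <= cl$end[i])
  }, logical(1))
  expect_gte(recall, 0.9)
  expect_gte(mean(true_cl), 0.9)
  expect_true(all(cl$region == "utr3"))
  expect_true(all(diff(cl$count_T2C) <= 0))  # ranked by count_T2C
})

test_that("a zero-conversion candidate gets p = 1 and is never retained", {
  reads <- data.frame(
    read_id = c("a", "b", "c"), reference_name = "t1",
    start = 0L, end = 20L, seq = strrep("A", 20), stringsAsFactors = FALSE)
  mm <- data.frame(read_id = "a", reference_name = "t1", pos = 2L,
                   ref_base = "A", read_base = "G", stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(c(t1 = strrep("AT", 25)))
  aln <- make_aln(reads, mm)
  cand <- build_candidates(aln, seqs)
  expect_equal(cand$count_T2C, 0L)
  expect_equal(poisson_tail(cand$count_T2C, 0.5), 1)
  cl <- call_clusters(aln, seqs, min_loc_t2c = 1L)
  expect_equal(nrow(cl), 0L)
})

test_that("calling is invariant to read input order", {
  fx <- fixture_planted()
  aln <- fx$aln
  set.seed(5)
  perm <- sample(nrow(aln$reads))
  aln2 <- aln
  aln2$reads <- aln$reads[perm, ]
  cl1 <- call_clusters(aln, fx$txome, fx$ann)
  cl2 <- call_clusters(aln2, fx$txome, fx$ann)
  rownames(cl1) <- rownames(cl2) <- NULL
  expect_equal(cl1, cl2)
})

test_that("BH q-values dominate p-values and clusters respect filters", {
  fx <- fixture_planted()
  cl <- fx$clusters
  expect_true(all(cl$q_value >= cl$p_value - 1e-15))
  expect_true(all(cl$q_value <= 0.05))
  expect_true(all(cl$read_count >= 3L))
  expect_true(all(cl$loc_T2C >= 2L))
  expect_true(all(cl$loc_T2C <= cl$count_T2C))
  expect_true(all(cl$count_T2C <= cl$covered_T_bases))
})

test_that("majority-rule annotation matches a per-base oracle", {
  fx <- fixture_planted()
  ann <- fx$ann
  cl <- random_clusters(fx$txome, 100L, seed = 6L)
  out <- annotate_clusters(cl, ann)
  prec <- c(utr3 = 1L, cds = 2L, utr5 = 3L, intron = 4L)
  for (i in seq_len(nrow(out))) {
    a <- ann[ann$reference_name == out$reference_name[i], ]
    votes <- c(utr5 = 0L, cds = 0L, utr3 = 0L)
    for (j in seq_len(nrow(a))) {
      ov <- min(a$end[j], out$end[i]) - max(a$start[j], out$start[i])
      if (ov > 0) votes[a$region[j]] <- votes[a$region[j]] + ov
    }
    if (all(votes == 0L)) {
      expect_equal(out$region[i], "unannotated")
    } else {
      best <- names(votes)[votes == max(votes)]
      best <- best[order(prec[best])][1]
      expect_equal(out$region[i], best)
    }
  }
})

test_that("cluster straddling CDS/3'UTR is assigned by majority", {
  ann <- data.frame(reference_name = "t1", transcript_id = "t1",
                    gene_id = "g1", region = c("cds", "utr3"),
                    start = c(0L, 100L), end = c(100L, 200L),
                    stringsAsFactors = FALSE)
  cl <- random_clusters(fixture_planted()$txome, 1L)[1, ]
  cl$reference_name <- "t1"; cl$start <- 70L; cl$end <- 120L  # 60% in CDS
  expect_equal(annotate_clusters(cl, ann)$region, "cds")
  cl$start <- 90L; cl$end <- 130L  # majority utr3
  expect_equal(annotate_clusters(cl, ann)$region, "utr3")
  cl$start <- 80L; cl$end <- 120L  # tie: precedence utr3 > cds
  expect_equal(annotate_clusters(cl, ann)$region, "utr3")
})

test_that("top-cluster selection equals a full sort-and-slice oracle", {
  fx <- fixture_planted()
  cl <- random_clusters(fx$txome, 60L, seed = 7L)
  expect_equal(nrow(select_top_clusters(
    transform(cl, read_count = 3L), min_reads = 10L)), 0L)
  top1 <- select_top_clusters(cl, n = 1L, min_reads = 0L)
  expect_equal(top1$count_T2C, max(cl$count_T2C))
  sel <- select_top_clusters(cl, n = 20L, min_reads = 10L)
  oracle <- cl[cl$read_count >= 10L, ]
  oracle <- oracle[order(-oracle$count_T2C, -oracle$loc_T2C, oracle$start), ]
  oracle <- head(oracle, 20L)
  rownames(sel) <- rownames(oracle) <- NULL
  expect_equal(sel, oracle)
})
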