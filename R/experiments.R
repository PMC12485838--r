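#' Planted-site recovery experiment
#'
#' Simulates a transcriptome with canonical motifs planted in a subset of
#' 3'UTRs, runs the full PAR-CLIP path (reads -> SAM -> alignment parsing ->
#' cluster calling), and scores recall and precision of the retained clusters
#' against the planted truth. A placement is recovered when a retained
#' cluster contains its window; a cluster is a true positive when it contains
#' a planted window.
#'
#' @param seed Integer seed.
#' @param n_transcripts Transcriptome size (default 300).
#' @param n_planted Transcripts receiving one canonical 3'UTR motif
#'   (default 30).
#' @param p_conv Crosslink conversion probability (default 0.3).
#' @param p_bg Background mismatch probability (default 0.002).
#' @param read_depth Reads per planted site (default 50).
#' @param ... Further arguments to [sim_config()].
#' @return List: `recall`, `precision`, `n_planted`, `n_clusters`, plus the
#'   underlying `txome`, `aln`, `ann`, and `clusters` for downstream reuse.
#' @export
planted_recovery <- function(seed, n_transcripts = 300L, n_planted = 30L,
                             p_conv = 0.3, p_bg = 0.002, read_depth = 50L,
                             ...) {
  cfg <- sim_config(seed = seed, n_transcripts = n_transcripts,
                    p_conv = p_conv, p_bg = p_bg, read_depth = read_depth,
                    ...)
  txome <- generate_transcriptome(cfg)
  plan <- data.frame(
    transcript_id = txome$transcripts$transcript_id[seq_len(n_planted)],
    region = "utr3", motif = canonical_motif(), n_copies = 1L,
    stringsAsFactors = FALSE
  )
  txome <- plant_motifs(txome, plan, seed = cfg$seed + 1L)
  pc <- simulate_parclip(txome, cfg)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  write_sam(pc, txome, sam)
  aln <- read_alignments(sam)
  gtf <- tempfile(fileext = ".gtf")
  on.exit(unlink(gtf), add = TRUE)
  write_transcriptome_gtf(txome, gtf)
  ann <- read_annotation(gtf)
  clusters <- call_clusters(aln, txome, ann)
  pl <- txome$placements
  w <- nchar(canonical_motif())
  recovered <- vapply(seq_len(nrow(pl)), function(i) {
    any(clusters$reference_name == pl$transcript_id[i] &
          clusters$start <= pl$start[i] & clusters$end >= pl$start[i] + w)
  }, logical(1))
  true_pos <- vapply(seq_len(nrow(clusters)), function(i) {
    any(pl$transcript_id == clusters$reference_name[i] &
          pl$start >= clusters$start[i] &
          pl$start + w <= clusters$end[i])
  }, logical(1))
  list(
    recall = mean(recovered),
    precision = if (nrow(clusters)) mean(true_pos) else NA_real_,
    n_planted = nrow(pl), n_clusters = nrow(clusters),
    cfg = cfg, txome = txome, aln = aln, ann = ann, clusters = clusters
  )
}

#' Type-I error experiment for the cluster caller
#'
#' Background-only simulation: reads pile up at planted windows exactly as in
#' the signal experiment, but with `p_conv = 0` every T->C arises from the
#' uniform background mismatch process. Reports the fraction of candidates
#' with uncorrected Poisson p below `alpha_raw`.
#'
#' @param seed Integer seed.
#' @param n_transcripts Transcriptome size (default 300).
#' @param sites_per_transcript Read pile-ups per transcript, giving
#'   `n_transcripts x sites_per_transcript` candidates (default 2).
#' @param p_bg Background mismatch probability (default 0.002).
#' @param alpha_raw Uncorrected threshold (default 0.05).
#' @param ... Further arguments to [sim_config()].
#' @return List: `fraction` (candidates with p < alpha_raw), `n_candidates`,
#'   `n_retained` (after the full filter chain).
#' @export
type1_experiment <- function(seed, n_transcripts = 300L,
                             sites_per_transcript = 2L, p_bg = 0.002,
                             alpha_raw = 0.05, ...) {
  cfg <- sim_config(seed = seed, n_transcripts = n_transcripts,
                    p_conv = 0, p_bg = p_bg, utr3_range = c(250L, 500L), ...)
  txome <- generate_transcriptome(cfg)
  plan <- data.frame(
    transcript_id = txome$transcripts$transcript_id,
    region = "utr3", motif = canonical_motif(),
    n_copies = sites_per_transcript, stringsAsFactors = FALSE
  )
  txome <- plant_motifs(txome, plan, seed = cfg$seed + 1L)
  pc <- simulate_parclip(txome, cfg)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  write_sam(pc, txome, sam)
  aln <- read_alignments(sam)
  bg <- estimate_background(aln)
  cand <- build_candidates(aln, txome)
  p <- poisson_tail(cand$count_T2C, bg$r_bg * cand$covered_T_bases)
  retained <- call_clusters(aln, txome)
  list(fraction = mean(p < alpha_raw), n_candidates = nrow(cand),
       n_retained = nrow(retained))
}

#' Motif-discovery experiment: 5-mer ranks on a planted simulation
#'
#' Runs [planted_recovery()] (or reuses its result) and ranks all 1024
#' 5-mers by Z-score enrichment of cluster sequences over flanking
#' background.
#'
#' @param seed Integer seed (ignored when `recovery` is supplied).
#' @param recovery Optional result of [planted_recovery()].
#' @param ... Passed to [planted_recovery()].
#' @return List: `ranks` (named integer rank of ATGAA/TGAAT/GAATT),
#'   `worst_rank`, and the full `stats` table.
#' @export
motif_rank_experiment <- function(seed = 1L, recovery = NULL, ...) {
  rec <- recovery %||% planted_recovery(seed, ...)
  bg <- extract_background(rec$clusters, rec$txome)
  stats <- kmer_zscores(cluster_sequences(rec$clusters, rec$txome), bg)
  motif_kmers <- c("ATGAA", "TGAAT", "GAATT")
  ranks <- match(motif_kmers, stats$kmer)
  names(ranks) <- motif_kmers
  list(ranks = ranks, worst_rank = max(ranks), stats = stats)
}

#' Suppression-ordering experiment (motif-count bins)
#'
#' Simulates counts where each canonical 3'UTR motif halves induced
#' expression (delta = 1 by default), estimates fold changes, and bins genes
#' by motif count in the 3'UTR.
#'
#' @param seed Integer seed.
#' @param n_transcripts Transcriptome size (default 1000; only a small
#'   minority of
#'   genes carry motifs, keeping median-of-ratios size factors anchored on
#'   the unchanged majority).
#' @param delta Per-motif log2 suppression (default 1).
#' @param include_variants Also plant 10 genes per single-nucleotide variant
#'   (for [variant_tile()] analyses). Default FALSE.
#' @return List: `bins` (a `bin_result` from [bin_by_site_count()]),
#'   `tile` (variant tile when `include_variants`), `expr`, `summaries`.
#' @export
suppression_experiment <- function(seed, n_transcripts = 1000L, delta = 1.0,
                                   include_variants = FALSE) {
  if (include_variants && n_transcripts < 1000L) n_transcripts <- 1000L
  cfg <- sim_config(seed = seed, n_transcripts = n_transcripts,
                    utr5_range = c(20L, 40L), cds_range = c(60L, 120L),
                    utr3_range = c(60L, 120L), delta = delta)
  txome <- generate_transcriptome(cfg)
  tid <- txome$transcripts$transcript_id
  plan <- rbind(
    data.frame(transcript_id = tid[1:60], region = "utr3",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = tid[61:120], region = "utr3",
               motif = canonical_motif(), n_copies = 2L)
  )
  if (include_variants) {
    variants <- enumerate_variants(canonical_motif())
    plan <- rbind(plan, data.frame(
      transcript_id = tid[121:330],
      region = "utr3", motif = rep(variants$seq, each = 10L), n_copies = 1L
    ))
  }
  txome <- plant_motifs(txome, plan, seed = cfg$seed + 1L)
  cnt <- simulate_counts(txome, cfg)
  gtf <- tempfile(fileext = ".gtf")
  on.exit(unlink(gtf))
  write_transcriptome_gtf(txome, gtf)
  ann <- read_annotation(gtf)
  summaries <- summarize_genes(txome, ann)
  expr <- compute_log2fc(cnt$counts, cnt$design)
  bins <- bin_by_site_count(expr, summaries, count_space = "region")
  tile <- if (include_variants) variant_tile(expr, summaries) else NULL
  list(bins = bins, tile = tile, expr = expr, summaries = summaries,
       cfg = cfg, txome = txome)
}
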