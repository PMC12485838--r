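#' Default motif-planting plan for demos and end-to-end tests
#'
#' Mixes the conditions the downstream analyses bin over: genes with one or
#' two canonical 3'UTR motifs, one gene per single-nucleotide variant, a few
#' custom-mutant genes, and canonical motifs in CDS/5'UTR; remaining
#' transcripts stay motif-free.
#'
#' @param txome A `transcriptome`.
#' @param mutant Custom mutant motif (default "GCCACTC").
#' @return A plan data.frame for [plant_motifs()].
#' @export
default_plan <- function(txome, mutant = "GCCACTC") {
  tid <- txome$transcripts$transcript_id
  variants <- enumerate_variants(canonical_motif())
  need <- 12L + 6L + nrow(variants) + 3L + 4L
  if (length(tid) < need) {
    stop("default_plan needs at least ", need, " transcripts")
  }
  i <- 0L
  take <- function(n) { out <- tid[i + seq_len(n)]; i <<- i + n; out }
  rbind(
    data.frame(transcript_id = take(12L), region = "utr3",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = take(6L), region = "utr3",
               motif = canonical_motif(), n_copies = 2L),
    data.frame(transcript_id = take(nrow(variants)), region = "utr3",
               motif = variants$seq, n_copies = 1L),
    data.frame(transcript_id = take(3L), region = "utr3",
               motif = mutant, n_copies = 1L),
    data.frame(transcript_id = take(2L), region = "cds",
               motif = canonical_motif(), n_copies = 1L),
    data.frame(transcript_id = take(2L), region = "utr5",
               motif = canonical_motif(), n_copies = 1L)
  )
}

#' Simulate a complete dataset and write its files
#'
#' Runs the four generators (transcriptome, motif planting, PAR-CLIP reads,
#' counts) under one seed and writes FASTA, GTF, SAM, the count matrix, and
#' truth tables (placements, per-gene motif copy number and true effect, and
#' every written T->C event).
#'
#' @param config A [sim_config()].
#' @param plan Planting plan (default [default_plan()] on the generated
#'   transcriptome).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory objects (`txome`, `parclip`,
#'   `counts`) and the written `paths`.
#' @export
simulate_dataset <- function(config, plan = NULL, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  txome <- generate_transcriptome(config)
  if (is.null(plan)) plan <- default_plan(txome)
  txome <- plant_motifs(txome, plan, seed = config$seed + 1L)
  pc <- simulate_parclip(txome, config, seed = config$seed + 2L)
  cnt <- simulate_counts(txome, config, seed = config$seed + 3L)
  paths <- c(
    fasta = file.path(outdir, "transcripts.fa"),
    gtf = file.path(outdir, "transcripts.gtf"),
    sam = file.path(outdir, "parclip.sam"),
    counts = file.path(outdir, "counts.tsv"),
    placements = file.path(outdir, "truth_placements.tsv"),
    gene_truth = file.path(outdir, "truth_genes.tsv"),
    t2c_truth = file.path(outdir, "truth_t2c.tsv"),
    design = file.path(outdir, "design.tsv")
  )
  write_transcriptome_fasta(txome, paths[["fasta"]])
  write_transcriptome_gtf(txome, paths[["gtf"]])
  write_sam(pc, txome, paths[["sam"]])
  write_counts(cnt$counts, paths[["counts"]])
  write_tsv(txome$placements, paths[["placements"]])
  write_tsv(cnt$truth, paths[["gene_truth"]])
  write_tsv(pc$t2c_truth, paths[["t2c_truth"]])
  write_tsv(cnt$design, paths[["design"]])
  invisible(list(txome = txome, parclip = pc, counts = cnt, paths = paths))
}

#' Run the whole pipeline end to end on one seed
#'
#' simulate -> cluster calling -> k-mer enrichment -> motif scan ->
#' expression binning -> QC, writing each stage's tables under `outdir` plus
#' a checksum manifest. Two PAR-CLIP libraries are simulated so the Spearman
#' reproducibility matrix is defined. Deterministic stages are byte-identical
#' across reruns with the same seed.
#'
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @param config Optional [sim_config()]; default uses `seed` with a
#'   150-transcript demo-sized transcriptome.
#' @return Invisibly, the manifest data.frame (file, md5, bytes).
#' @export
run_demo <- function(seed = 7L, outdir, config = NULL) {
  config <- config %||% sim_config(seed = seed, n_transcripts = 150L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  # stage 1: simulate (library 1 is the analysis library)
  sim <- simulate_dataset(config, outdir = file.path(outdir, "sim"))
  txome <- sim$txome
  pc2 <- simulate_parclip(txome, config, seed = config$seed + 50L)
  sam2 <- file.path(outdir, "sim", "parclip_rep2.sam")
  write_sam(pc2, txome, sam2)

  # stage 2: cluster calling
  aln <- read_alignments(sim$paths[["sam"]])
  ann <- read_annotation(sim$paths[["gtf"]])
  clusters <- call_clusters(aln, txome, ann, verbose = TRUE)
  clusters_bed <- file.path(outdir, "clusters.bed")
  write_clusters(clusters, clusters_bed)

  # stage 3: k-mer enrichment
  kmers_tsv <- file.path(outdir, "kmers.tsv")
  if (nrow(clusters) >= 1L) {
    bg <- extract_background(clusters, txome)
    km <- kmer_zscores(cluster_sequences(clusters, txome), bg)
    write_tsv(km, kmers_tsv)
  } else {
    write_tsv(data.frame(), kmers_tsv)
  }

  # stage 4: motif scan
  summaries <- summarize_genes(txome, ann, clusters)
  summaries_tsv <- file.path(outdir, "gene_summaries.tsv")
  write_tsv(summaries, summaries_tsv)
  variants <- enumerate_variants(canonical_motif())
  hits <- scan_regions(txome, ann,
                       c(stats::setNames(canonical_motif(), "canonical"),
                         stats::setNames(variants$seq, variants$label)))
  hits_tsv <- file.path(outdir, "motif_hits.tsv")
  write_tsv(hits, hits_tsv)

  # stage 5: expression binning
  expr <- compute_log2fc(read_counts(sim$paths[["counts"]]),
                         sim$counts$design)
  bins_sites <- bin_by_site_count(expr, summaries, count_space = "region")
  bins_region <- bin_by_region(expr, summaries)
  tile <- variant_tile(expr, summaries)
  bins_sites_tsv <- file.path(outdir, "bins_site_count.tsv")
  bins_region_tsv <- file.path(outdir, "bins_region.tsv")
  tile_tsv <- file.path(outdir, "variant_tile.tsv")
  write_tsv(bins_sites$summary, bins_sites_tsv)
  write_tsv(bins_region$summary, bins_region_tsv)
  write_tsv(tile, tile_tsv)

  # stage 6: QC over both libraries
  aln2 <- read_alignments(sam2)
  clusters2 <- call_clusters(aln2, txome, ann)
  x1 <- xrpm_per_gene(aln, clusters)
  x2 <- xrpm_per_gene(aln2, clusters2)
  sp <- spearman_matrix(list(rep1 = x1, rep2 = x2))
  mg <- metagene_profile(clusters, ann)
  rc <- region_composition(clusters)
  qc_dir <- file.path(outdir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  xrpm_tsv <- file.path(qc_dir, "xrpm_rep1.tsv")
  spearman_tsv <- file.path(qc_dir, "spearman.tsv")
  metagene_tsv <- file.path(qc_dir, "metagene.tsv")
  composition_tsv <- file.path(qc_dir, "region_composition.tsv")
  write_tsv(x1, xrpm_tsv)
  utils::write.table(sp, spearman_tsv, sep = "\t", quote = FALSE)
  write_tsv(mg, metagene_tsv)
  write_tsv(rc, composition_tsv)

  files <- c(sim$paths, sam2 = sam2, clusters = clusters_bed,
             kmers = kmers_tsv, summaries = summaries_tsv, hits = hits_tsv,
             bins_sites = bins_sites_tsv, bins_region = bins_region_tsv,
             tile = tile_tsv, xrpm = xrpm_tsv, spearman = spearman_tsv,
             metagene = metagene_tsv, composition = composition_tsv)
  manifest <- data.frame(
    stage = names(files),
    file = vapply(files, function(f) sub(paste0("^", outdir, "/?"), "", f),
                  character(1)),
    md5 = unname(tools::md5sum(unlist(files))),
    bytes = unname(file.size(unlist(files))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(manifest)
}
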