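#!/usr/bin/env Rscript
# Stage 6: reproducibility and localization QC. Simulates a second PAR-CLIP
# library from the same transcriptome, computes per-gene XRPM for both,
# their Spearman correlation, the metagene profile of crosslink signal, and
# the region composition of calls.
suppressPackageStartupMessages(library(clipkit))

seed <- 1L
cfg <- sim_config(seed = seed)
txome <- generate_transcriptome(cfg)
plan <- data.frame(
  transcript_id = txome$transcripts$transcript_id[1:45],
  region = "utr3", motif = canonical_motif(),
  n_copies = rep(c(1L, 2L), c(30L, 15L))
)
txome <- plant_motifs(txome, plan, seed = cfg$seed + 1L)

ann <- read_annotation("results/sim/transcripts.gtf")
aln1 <- read_alignments("results/sim/parclip.sam")
cl1 <- read_clusters("results/clusters.bed")

pc2 <- simulate_parclip(txome, cfg, seed = cfg$seed + 50L)
sam2 <- "results/sim/parclip_rep2.sam"
write_sam(pc2, txome, sam2)
aln2 <- read_alignments(sam2)
cl2 <- call_clusters(aln2, txome, ann)

dir.create("results/qc", showWarnings = FALSE, recursive = TRUE)
x1 <- xrpm_per_gene(aln1, cl1)
x2 <- xrpm_per_gene(aln2, cl2)
write.table(x1, "results/qc/xrpm_rep1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(x2, "results/qc/xrpm_rep2.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sp <- spearman_matrix(list(rep1 = x1, rep2 = x2))
write.table(sp, "results/qc/spearman.tsv", sep = "\t", quote = FALSE)
message(sprintf("replicate XRPM Spearman correlation: %.3f",
                sp["rep1", "rep2"]))

mg <- metagene_profile(cl1, ann)
write.table(mg, "results/qc/metagene.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
frac_utr3 <- sum(mg$density[mg$region == "utr3"])
message(sprintf("fraction of crosslink signal in 3'UTR bins: %.3f",
                frac_utr3))
write.table(region_composition(cl1), "results/qc/region_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
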