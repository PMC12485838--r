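#!/usr/bin/env Rscript
# Stage 3: 5-mer Z-score enrichment of cluster sequences against 200-nt
# flanking background regions. The three constituent 5-mers of the planted
# heptamer (ATGAA, TGAAT, GAATT) should dominate the ranking.
suppressPackageStartupMessages(library(clipkit))

clusters <- read_clusters("results/clusters.bed")
fasta <- "results/sim/transcripts.fa"
bg <- extract_background(clusters, fasta)
km <- kmer_zscores(cluster_sequences(clusters, fasta), bg)
write.table(km, "results/kmers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("top 10 of ", nrow(km), " 5-mers by Z:")
print(head(km[, c("kmer", "x_cluster", "mu_bg", "sigma_bg", "z",
                  "au_rich", "atg_containing")], 10))
message("ranks of heptamer constituents: ",
        paste(sprintf("%s=%d", c("ATGAA", "TGAAT", "GAATT"),
                      match(c("ATGAA", "TGAAT", "GAATT"), km$kmer)),
              collapse = ", "))
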