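#!/usr/bin/env Rscript
# Stage 2: call binding-site clusters from the simulated PAR-CLIP library.
# T->C conversions in each candidate (a maximal run of overlapping reads,
# >= 3 reads) are tested against a Poisson expectation from the non-T->C
# background mismatch rate; BH-corrected clusters passing q <= 0.05 and
# loc_T2C >= 2 are kept, then compared against the planted truth.
suppressPackageStartupMessages(library(clipkit))

aln <- read_alignments("results/sim/parclip.sam")
print(aln)
ann <- read_annotation("results/sim/transcripts.gtf")
clusters <- call_clusters(aln, "results/sim/transcripts.fa", ann,
                          verbose = TRUE)
write_clusters(clusters, "results/clusters.bed")

truth <- read.table("results/sim/truth_placements.tsv", header = TRUE,
                    sep = "\t")
hit <- vapply(seq_len(nrow(truth)), function(i) {
  any(clusters$reference_name == truth$transcript_id[i] &
        clusters$start <= truth$start[i] &
        clusters$end >= truth$start[i] + nchar(truth$motif[i]))
}, logical(1))
message(sprintf("recall %.3f (%d/%d planted sites), %d clusters called",
                mean(hit), sum(hit), nrow(truth), nrow(clusters)))
message("region composition of calls:")
print(region_composition(clusters))
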