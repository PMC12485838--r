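# clipkit

An R toolkit and analysis workflow for PAR-CLIP binding-site discovery and
motif-conditioned expression analysis, built around the regulatory logic of
an RNA-binding protein complex that recognizes the heptamer element
AUGAAUU (`ATGAATT` in DNA space) in mRNA 3'UTRs and destabilizes the
transcripts carrying it.

It is written for computational biologists who want a self-contained,
testable reimplementation of this analysis chain:

1. **Cluster calling** — PAR-CLIP T→C conversions are tested per candidate
   interval against a Poisson background estimated from non-T→C mismatches:
   `r_bg = (n_non_T2C / aligned_bases) × 12/11`, expected conversions
   `μ = r_bg × covered_T_bases`, p = P(Poisson(μ) ≥ count_T2C), BH-corrected
   across candidates, filtered by read depth (≥ 3), distinct converted
   positions (loc_T2C ≥ 2) and q ≤ 0.05, ranked by count_T2C.
2. **5-mer enrichment** — Z = (X − μ)/σ, with X the k-mer proportion in
   pooled cluster sequences and μ, σ the mean/sd of its proportion across
   ≤ 200-nt flanking background regions.
3. **Motif scanning** — the canonical heptamer and its 21 single-nucleotide
   variants over annotated 5'UTR/CDS/3'UTR regions and called clusters,
   summarized per gene with an exclusivity rule for variant carriers.
4. **Expression binning** — median-of-ratios normalized log2 fold changes
   binned by 3'UTR motif count, motif region, and variant identity (CDFs,
   per-bin median log2FC, 21-cell variant tolerance tile).
5. **QC** — per-gene XRPM (crosslinked reads per million), Spearman
   replicate correlation, metagene profiles, region composition.

A synthetic-data generator (FASTA/GTF/SAM-with-MD/count-matrix writers
included) plants motifs and crosslink signal with known truth, so every
stage is validated end to end without downloading anything.

## Worked example

The numbered drivers under `analysis/` run the whole study on one seed and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # transcriptome + reads + counts
Rscript analysis/02_call_clusters.R       # Poisson cluster calling
Rscript analysis/03_kmer_enrichment.R     # 5-mer Z-scores
Rscript analysis/04_motif_scan.R          # heptamer + variant scan
Rscript analysis/05_expression_binning.R  # motif-conditioned fold changes
Rscript analysis/06_qc.R                  # XRPM, Spearman, metagene
```

Stage 1 simulates 300 transcripts, 30 of which carry one canonical 3'UTR
element and 15 two, with 50 reads per site, 30% T→C conversion at
crosslinked Ts and 0.2% background mismatches. Stage 2 then reports

```
call_clusters: r_bg=0.00157, 56 candidates, 56 retained
recall 1.000 (60/60 planted sites), 56 clusters called
```

— every planted site is recovered (two-copy sites whose read piles touch
merge into one cluster, hence 56 calls for 60 placements), and all calls
annotate to the 3'UTR. Stage 3 ranks all 1024 5-mers; the top of the table
is exactly the three constituent 5-mers of the planted heptamer:

```
 kmer   x_cluster       mu_bg    sigma_bg        z
TGAAT 0.021943574 0.000356333 0.001343373 16.06944
ATGAA 0.021246952 0.000404924 0.001420423 14.67312
GAATT 0.021246952 0.000482950 0.001750714 11.86030
```

Stage 5 bins expressed genes (baseMean ≥ 10) by 3'UTR motif count and
prints the per-bin median log2 fold change:

```
         label   n median_lfc
           ge2  15 -1.7687813
           one  30 -0.7596618
       unbound 255  0.1139466
```

— genes with two elements are suppressed about twice as strongly (in log2
units) as genes with one, and motif-free genes sit near zero: the planted
per-element halving (δ = 1) is recovered. Stage 6 reports the replicate
XRPM Spearman correlation (0.733 on this seed) and a metagene profile with
all crosslink mass in the 3'UTR segment.

In code, the same chain is three calls:

```r
library(clipkit)
aln      <- read_alignments("results/sim/parclip.sam")
ann      <- read_annotation("results/sim/transcripts.gtf")
clusters <- call_clusters(aln, "results/sim/transcripts.fa", ann)
```

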