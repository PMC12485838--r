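---
title: "Methods: PAR-CLIP cluster calling and motif-conditioned expression analysis"
author: "clipkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAR-CLIP cluster calling and motif-conditioned expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

clipkit analyses photoactivatable-ribonucleoside-enhanced crosslinking and
immunoprecipitation (PAR-CLIP) data in *transcript space*: reads are aligned
against spliced transcript sequences, and all coordinates are 0-based
half-open on the transcript, converted only at file boundaries (GTF and SAM
are 1-based on read/write). The pipeline has five analytical stages —
cluster calling, k-mer enrichment, motif scanning, motif-conditioned
expression binning, and QC — plus a synthetic-data generator that produces
inputs with the statistical structure each stage assumes, so the whole chain
is testable without external data.

The biological setting is an RNA-binding protein complex that recognizes a
heptamer element (AUGAAUU; stored as `ATGAATT` because every file format
touched is DNA-space) in mRNA 3'UTRs and destabilizes the transcripts that
carry it. The analyses ask three questions: where does the complex bind
(cluster calling, metagene, region composition), what sequence does it
prefer (5-mer Z-scores), and what happens to transcripts carrying the
element (fold-change binning, variant tolerance).

## Cluster calling

4-thiouridine crosslinking leaves a diagnostic T→C conversion in cDNA at
crosslinked positions. The caller separates this signal from sequencing/
alignment noise with a Poisson background model:

1. **Background rate.** Every non-T→C mismatch across the library is
   background by construction. With `n_non` such events over `N` aligned
   bases, the per-base background mismatch probability is
   `r_bg = (n_non / N) × (12/11)`. Under a uniform substitution model a
   background mismatch lands on a reference T and becomes a C with
   probability 1/4 × 1/3 = 1/12 of all mismatches; the 12/11 factor restores
   that share, which the numerator necessarily excludes.
2. **Candidates.** Maximal intervals of contiguous read coverage (the union
   of overlapping reads), keeping those with ≥ `min_depth` (default 3)
   overlapping reads — the simplest deterministic candidate rule; PAR-CLIP
   reads cluster tightly at sites, so unions stay local.
3. **Test.** For each candidate, `count_T2C` (total T→C events) is compared
   with the expectation `μ = r_bg × covered_T_bases`, where
   `covered_T_bases` sums read coverage over reference-T positions in the
   interval — conversions can only happen at covered Ts, so the opportunity
   set is covered Ts, not interval length. The p-value is the upper Poisson
   tail `P(X ≥ count_T2C)`. Note `μ` deliberately uses the *total*
   background mismatch rate rather than the T→C share of it (`r_bg/3`);
   the expectation is therefore conservative by about 3×, which the type-I
   simulations confirm (raw positive fraction ≪ 0.05) and which buys
   robustness against clustered background errors.
4. **Correction and filters.** Benjamini–Hochberg across all candidates at
   α = 0.05 (per-candidate Poisson p-values need a multiplicity correction
   and BH is the field default), then `read_count ≥ 3` and `loc_T2C ≥ 2`
   (distinct converted positions; requiring two suppresses single-position
   sequencing artifacts and is configurable). Output is ranked by
   `count_T2C` descending, the conventional crosslink-evidence ranking for
   downstream cluster selection.

Degenerate cases: `μ = 0` with `k ≥ 1` yields p = 0; a candidate with
`count_T2C = 0` has p = 1 and can never pass `loc_T2C ≥ 1`.

Region annotation is majority-rule: the region overlapping most of the
cluster wins, ties break utr3 > cds > utr5 > intron (3'UTR binding is the
phenomenon of interest, so ties resolve toward it; in transcript space
introns never occur but the precedence slot is kept for generality).

## k-mer enrichment

For k-mer words (default k = 5) the enrichment statistic is

  Z = (X − μ) / σ

where X is the proportion of the k-mer among all overlapping windows of the
pooled cluster sequences, and μ, σ are the mean and standard deviation of
that k-mer's proportion across *background regions* — the ≤ 200-nt slices
upstream and downstream of each cluster, clipped at transcript bounds and
excluding any overlap with other clusters. Treating each background region
as one observation preserves the between-region variance the statistic
needs — pooling the background would collapse σ to a binomial error and
overstate significance wherever background composition varies. σ is the
sample (n−1)
standard deviation by default (`sd_population = TRUE` switches to n); a
binomial-standard-error alternative is available via
`sigma_mode = "binomial"`.

Two numerical guards matter in practice:

* **Sliver regions.** A background slice clipped to a handful of windows
  turns a single occurrence into an extreme proportion and inflates σ for
  every k-mer it contains. Regions with fewer than `min_windows` (default
  30) windows are excluded from μ/σ (with a fallback to all non-empty
  regions if fewer than two survive).
* **σ = 0.** A k-mer absent from every usable background region has σ = 0
  while possibly being strongly enriched in clusters — the most interesting
  case, not an excludable one. Such k-mers are flagged (`sigma_zero`) and
  ranked with a floored σ: the binomial standard error of the pooled
  background proportion with a half-count continuity correction. The
  degenerate x = μ = 0 case scores z = 0.

Classification follows the field's convention for 5-mers: `au_rich` (≥ 3
A's or ≥ 3 T's) and `atg_containing` (ATG substring).

## Motif scanning and gene summaries

`enumerate_variants()` produces the 21 Hamming-distance-1 neighbours of the
heptamer. Scanning is exact and overlapping (step 1), and a hit requires the
complete window inside the queried region. Per gene, a representative
transcript is chosen as the one with the longest annotated 3'UTR (gene-level
expression tables say nothing about transcript choice; the 3'UTR is where
the biology happens). `n_in_clusters` counts canonical hits whose window
lies *fully* inside a retained cluster.

Variant presence uses an exclusivity rule: a gene counts for variant v only
if its 3'UTR contains v and *no* canonical occurrence. Without exclusivity a
variant cell would mix in the canonical effect and the tolerance tile would
be uninterpretable; `exclusive = FALSE` disables it.

## Expression binning

The stand-in fold-change estimator mirrors the standard bulk workflow
without inference: median-of-ratios size factors (geometric-mean reference
over genes with all-positive counts), `baseMean` = mean normalized count
over all samples, and `log2fc = log2((mean_induced + 0.5) /
(mean_control + 0.5))`. No dispersion estimation, shrinkage or test — the
binning analyses need only `baseMean` and `log2fc`, and a real
differential-expression table can be ingested instead
(`ingest_de_table()`, with the significance rule padj ≤ 0.05 and
|log2FC| > 1 available as a filter).

One estimator property to keep in mind: under one-sided suppression of a
sizeable minority of genes, median-of-ratios size factors absorb part of the
effect and every gene shifts slightly in the opposite direction. The bins
all shift together, so *differences* between bins are unbiased; absolute
medians are accurate when the affected fraction is small (the simulation
experiments keep it near 12%, where the residual shift is ≈ +0.1 log2
units).

Bins are mutually exclusive partitions of the expressed gene set
(`baseMean ≥ 10`; the ≥ 100 variant used for expression-dependent analyses
is a parameter):

* by motif count — {≥ 2, 1, bound-without-motif, unbound}, with the count
  taken either anywhere in the 3'UTR (`count_space = "region"`) or only
  inside called binding sites (`"sites"`); both readings of "motif count"
  are defensible and both are implemented;
* by region — {utr3_ge2, utr3_1, cds, utr5, none}, multi-region genes
  assigned by priority utr3 > cds > utr5 (exclusive bins need a rule; the
  3'UTR is the active compartment);
* the 21-cell variant tolerance tile, plus a canonical reference cell.

Each bin reports n, the median log2 fold change (even-sized bins use the
mean of the two central values), and empirical CDF points (right-continuous,
ties share a step). For odd n the median of log2 fold changes equals the
log2 of the median fold change (monotone-transform commutation), so
reporting medians of log2FC and log2 of median abundance change are the
same statistic.

## QC

* **XRPM** — crosslinked reads (≥ 1 T→C) per million library crosslinked
  reads, per gene. The default universe counts a read toward a gene when it
  overlaps one of that gene's retained clusters (tying reproducibility to
  called sites); `universe = "all"` counts every crosslinked read on the
  gene's transcript. XRPM sums to 10^6 whenever any crosslinked read exists.
* **Spearman matrix** across libraries on the union gene universe, absent
  genes imputed as 0, average ranks on ties; constant vectors give NA.
* **Metagene profile** — each cluster contributes its `count_T2C` at its
  midpoint's normalized position within its region; 5'UTR/CDS/3'UTR are
  concatenated with fixed widths of 10/30/30 bins (fixed rather than
  data-scaled widths keep profiles comparable across libraries); density
  sums to 1.
* **Region composition** — cluster fractions over
  {utr5, cds, utr3, intron, unannotated}.

## The synthetic-data generator

The generator defines the study conditions the tests and the acceptance
script run under:

* **Transcriptome.** One gene per transcript; region lengths uniform over
  50–150 (5'UTR), 300–600 (CDS), 200–500 nt (3'UTR) — compact but
  realistically proportioned transcripts. Background sequence is
  rejection-sampled (cap 1000 attempts per region) so no region contains the
  canonical heptamer or any single-nucleotide variant: every downstream
  motif occurrence is planted and known. Planting redraws positions if an
  overwrite creates a spurious junction occurrence, so a rescan finds
  exactly the planted set. Custom mutant motifs (e.g. `GCCACTC`) are planted
  the same way but the background is not purged of them; pre-existing
  occurrences would only add null genes to a mutant bin.
* **PAR-CLIP reads.** 50 reads per planted site, start uniform over the
  window of 30-nt reads fully covering the placement; each covered
  placement T converts with p_conv = 0.3; every aligned base additionally
  mismatches with p_bg = 0.002 (substitute uniform over the three
  alternatives, so background T→C carries share 1/3 — the realistic null
  for the caller's type-I behaviour); background reads at Poisson rate 1
  per transcript. Output is coordinate-sorted SAM with MD/NM tags.
  p_conv = 0.3 reflects the efficient end of 4SU crosslinking; p_bg = 0.002
  a well-filtered modern library.
* **Counts.** Control means log-normal(log 200, 1); the induced mean of a
  gene with k canonical 3'UTR motifs is μ·2^(−δk) with δ = 1 (a per-element
  halving, the magnitude at which CDF separation is unambiguous);
  negative-binomial with dispersion 0.05; 4 replicates per condition.
* **Determinism.** Every generator takes an explicit seed
  (`config$seed + fixed offset` per stage); identical configurations give
  byte-identical files.

What the generator does *not* emulate — spliced genome-space alignment,
PCR-duplicate and adapter artifacts, antisense (A→G) libraries,
expression-coupled binding, motif context preferences — bounds what a green
test suite shows: the pipeline's statistics are correct and well-calibrated
under the stated generative model, not that the model captures every
property of real libraries.

## Problem sizes and reader filters

Simulation experiments use 300-transcript transcriptomes with 30 planted
sites for recovery/type-I/motif-rank analyses, and 1000-transcript
transcriptomes (120 suppressed genes ≈ 12%) for the binning analyses —
sizes chosen so each bin holds tens of genes and medians are stable, while
a full pipeline run stays in seconds. The alignment reader drops reads
with more than 2 mismatches, mirroring a strict end-to-end alignment
setting; indel-containing records are skipped (and counted) because the
MD-based mismatch decoding assumes ungapped alignments.

## Known limitations

* Transcript space only: no multi-exon/genome coordinates, so no intronic
  clusters in practice.
* The per-cluster (not per-position) Poisson test cannot localize multiple
  crosslink sites within one merged candidate; adjacent planted sites whose
  read piles touch merge into one cluster.
* The conservative background expectation trades power for type-I safety;
  at very low conversion rates (p_conv ≲ 0.05) weak sites fall below the
  detection threshold.
* The fold-change estimator carries the normalization shift described above
  and provides no uncertainty; for inference, ingest a proper
  differential-expression table.
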