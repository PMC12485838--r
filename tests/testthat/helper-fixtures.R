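`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small planted simulation reused across io/cluster/kmer/qc tests:
# 60 transcripts, 10 with one canonical 3'UTR motif.
fixture_planted <- function() {
  cached("planted", function() {
    cfg <- sim_config(seed = 101L, n_transcripts = 60L)
    txome <- generate_transcriptome(cfg)
    plan <- data.frame(
      transcript_id = txome$transcripts$transcript_id[1:10],
      region = "utr3", motif = canonical_motif(), n_copies = 1L,
      stringsAsFactors = FALSE
    )
    txome <- plant_motifs(txome, plan, seed = cfg$seed + 1L)
    pc <- simulate_parclip(txome, cfg)
    dir <- file.path(tempdir(), "clipkit-fixture-planted")
    dir.create(dir, showWarnings = FALSE)
    sam <- file.path(dir, "reads.sam")
    gtf <- file.path(dir, "regions.gtf")
    fasta <- file.path(dir, "transcripts.fa")
    write_sam(pc, txome, sam)
    write_transcriptome_gtf(txome, gtf)
    write_transcriptome_fasta(txome, fasta)
    aln <- read_alignments(sam, max_mismatches = Inf)
    ann <- read_annotation(gtf)
    clusters <- call_clusters(aln, txome, ann)
    list(cfg = cfg, txome = txome, plan = plan, parclip = pc,
         sam = sam, gtf = gtf, fasta = fasta, aln = aln, ann = ann,
         clusters = clusters)
  })
}

# Random unscored clusters over a fixture transcriptome, for round-trip and
# annotation tests.
random_clusters <- function(txome, n, seed = 1L) {
  set.seed(seed)
  tx <- txome$transcripts
  lens <- Biostrings::width(txome$sequences)
  i <- sample(nrow(tx), n, replace = TRUE)
  w <- sample(20:60, n, replace = TRUE)
  start <- vapply(seq_len(n), function(j) {
    sample.int(max(1L, lens[i[j]] - w[j]), 1L) - 1L
  }, integer(1))
  data.frame(
    reference_name = tx$transcript_id[i], start = start, end = start + w,
    read_count = sample(3:50, n, replace = TRUE),
    count_T2C = sample(0:30, n, replace = TRUE),
    loc_T2C = sample(0:5, n, replace = TRUE),
    covered_T_bases = sample(50:500, n, replace = TRUE),
    expected_T2C = stats::runif(n, 0.01, 2),
    p_value = stats::runif(n), q_value = stats::runif(n),
    region = "unannotated", gene_id = "", stringsAsFactors = FALSE
  )
}

# Naive substring counter: overlapping occurrences of `kmer` in `seq`.
naive_kmer_count <- function(seqs, kmer) {
  k <- nchar(kmer)
  sum(vapply(seqs, function(s) {
    if (nchar(s) < k) return(0L)
    wins <- substring(s, seq_len(nchar(s) - k + 1L),
                      seq_len(nchar(s) - k + 1L) + k - 1L)
    sum(wins == kmer & !grepl("[^ACGT]", wins))
  }, integer(1)))
}
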