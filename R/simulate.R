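#' Generate a synthetic transcriptome
#'
#' Draws per-transcript 5'UTR/CDS/3'UTR lengths uniformly from the configured
#' ranges and fills each region with random sequence. Region background is
#' rejection-sampled so that no region contains the canonical heptamer or any
#' of its 21 single-nucleotide variants: motif occurrences exist downstream
#' only where [plant_motifs()] puts them. One gene per transcript.
#'
#' @param config A [sim_config()].
#' @return A `transcriptome` object: list with `transcripts` (data.frame of
#'   transcript_id, gene_id, region lengths), `sequences` (named
#'   [Biostrings::DNAStringSet]), and an empty `placements` data.frame.
#' @export
generate_transcriptome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts
  excl <- Biostrings::PDict(motif_exclusion_set())
  draw_len <- function(rng) {
    # uniform over the inclusive range; robust to degenerate ranges
    rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
  }
  tx <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(n)),
    gene_id = sprintf("g%04d", seq_len(n)),
    utr5_len = if (n) draw_len(config$utr5_range) else integer(0),
    cds_len = if (n) draw_len(config$cds_range) else integer(0),
    utr3_len = if (n) draw_len(config$utr3_range) else integer(0),
    stringsAsFactors = FALSE
  )
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- paste0(
      sample_motif_free_region(tx$utr5_len[i], excl),
      sample_motif_free_region(tx$cds_len[i], excl),
      sample_motif_free_region(tx$utr3_len[i], excl)
    )
  }
  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- tx$transcript_id
  txome <- list(
    transcripts = tx,
    sequences = sequences,
    placements = empty_placements()
  )
  class(txome) <- "transcriptome"
  txome
}

empty_placements <- function() {
  data.frame(
    transcript_id = character(0), gene_id = character(0),
    region = character(0), start = integer(0),
    motif = character(0), label = character(0),
    stringsAsFactors = FALSE
  )
}

# Canonical heptamer plus its 21 single-nucleotide variants.
motif_exclusion_set <- function() {
  c(canonical_motif(), enumerate_variants(canonical_motif())$seq)
}

# Rejection-sample a region sequence containing none of the excluded motifs
# (exclusion is a precompiled Biostrings::PDict of equal-width patterns).
sample_motif_free_region <- function(len, exclusion, max_attempts = 1000L) {
  if (len == 0L) return("")
  w <- Biostrings::width(exclusion)[1]
  for (attempt in seq_len(max_attempts)) {
    s <- rand_dna(len)
    if (len < w ||
        sum(Biostrings::countPDict(exclusion, Biostrings::DNAString(s))) == 0L) {
      return(s)
    }
  }
  stop("rejection sampling failed after ", max_attempts,
       " attempts for a region of length ", len)
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", nrow(x$transcripts), "transcripts,",
      nrow(x$placements), "planted motifs\n")
  invisible(x)
}

#' Plant motif occurrences into transcript regions
#'
#' Overwrites background sequence with motif copies at random non-overlapping
#' positions inside the named region. After planting, each affected region is
#' rescanned for the canonical heptamer and all its single-nucleotide
#' variants; placements are redrawn if an overwrite created a spurious
#' junction occurrence, so a rescan of the final sequence finds exactly the
#' planted occurrences.
#'
#' @param txome A `transcriptome`.
#' @param plan data.frame with columns `transcript_id`, `region` (one of
#'   utr5/cds/utr3), `motif` (ACGT string), `n_copies`.
#' @param seed Integer seed; defaults to `config` seed offset is not known
#'   here, so callers pass one (the pipeline uses `config$seed + 1`).
#' @return The transcriptome with updated `sequences` and rows appended to
#'   `placements` (`label` is "canonical", a variant label like "pos3C", or
#'   "custom").
#' @export
plant_motifs <- function(txome, plan, seed = NULL) {
  stopifnot(inherits(txome, "transcriptome"))
  if (!is.null(seed)) set.seed(seed)
  if (nrow(plan) == 0L) return(txome)
  stopifnot(all(c("transcript_id", "region", "motif", "n_copies") %in% names(plan)))
  stop_if_not_acgt(plan$motif, "motif")
  stopifnot(all(plan$region %in% c("utr5", "cds", "utr3")))
  bounds <- region_bounds(txome)
  excl <- motif_exclusion_set()
  pdict <- Biostrings::PDict(excl)
  seqs <- as.character(txome$sequences)
  new_pl <- list()

  for (tid in unique(plan$transcript_id)) {
    rows <- plan[plan$transcript_id == tid & plan$n_copies > 0L, , drop = FALSE]
    if (nrow(rows) == 0L) next
    if (!tid %in% names(seqs)) stop("unknown transcript_id: ", tid)
    gid <- txome$transcripts$gene_id[match(tid, txome$transcripts$transcript_id)]
    for (j in seq_len(nrow(rows))) {
      rb <- bounds[bounds$transcript_id == tid & bounds$region == rows$region[j], ]
      w <- nchar(rows$motif[j])
      if (nrow(rb) == 0L || (rb$end - rb$start) < w * rows$n_copies[j]) {
        stop("region ", rows$region[j], " of ", tid, " too short for ",
             rows$n_copies[j], " copies of ", rows$motif[j])
      }
    }
    placed <- place_transcript_motifs(seqs[[tid]], rows, bounds, excl, pdict)
    seqs[[tid]] <- placed$seq
    placed$placements$gene_id <- gid
    new_pl[[tid]] <- placed$placements
  }

  txome$sequences <- Biostrings::DNAStringSet(seqs)
  names(txome$sequences) <- txome$transcripts$transcript_id
  add <- do.call(rbind, new_pl)
  add$label <- vapply(add$motif, motif_label, character(1))
  txome$placements <- rbind(
    txome$placements,
    add[, c("transcript_id", "gene_id", "region", "start", "motif", "label")]
  )
  rownames(txome$placements) <- NULL
  txome
}

# Draw non-overlapping positions for all of one transcript's planned motifs,
# overwrite, and verify the rescan finds exactly the planted canonical/variant
# occurrences; redraw on junction artifacts.
place_transcript_motifs <- function(seq, rows, bounds, excl, pdict,
                                    max_tries = 50L) {
  tid <- rows$transcript_id[1]
  for (try in seq_len(max_tries)) {
    s <- seq
    taken <- IRanges::IRanges()
    pl <- list()
    ok <- TRUE
    for (j in seq_len(nrow(rows))) {
      rb <- bounds[bounds$transcript_id == tid & bounds$region == rows$region[j], ]
      w <- nchar(rows$motif[j])
      for (copy in seq_len(rows$n_copies[j])) {
        pos <- draw_free_start(rb$start, rb$end, w, taken)
        if (is.na(pos)) { ok <- FALSE; break }
        taken <- c(taken, IRanges::IRanges(pos + 1L, pos + w))
        substr(s, pos + 1L, pos + w) <- rows$motif[j]
        pl[[length(pl) + 1L]] <- data.frame(
          transcript_id = tid, region = rows$region[j],
          start = pos, motif = rows$motif[j], stringsAsFactors = FALSE
        )
      }
      if (!ok) break
    }
    if (!ok) next
    pl <- do.call(rbind, pl)
    if (rescan_matches_plan(s, pl, bounds, excl, pdict)) {
      return(list(seq = s, placements = pl))
    }
  }
  stop("could not place motifs in ", tid, " without spurious occurrences ",
       "after ", max_tries, " attempts")
}

draw_free_start <- function(r_start, r_end, w, taken, max_tries = 200L) {
  hi <- r_end - w
  if (hi < r_start) return(NA_integer_)
  for (i in seq_len(max_tries)) {
    pos <- r_start + sample.int(hi - r_start + 1L, 1L) - 1L
    cand <- IRanges::IRanges(pos + 1L, pos + w)
    if (length(taken) == 0L ||
        !any(IRanges::overlapsAny(cand, taken))) {
      return(pos)
    }
  }
  NA_integer_
}

# TRUE iff scanning every region of `s` for the canonical/variant exclusion
# set finds exactly the planted canonical/variant starts.
rescan_matches_plan <- function(s, pl, bounds, excl, pdict) {
  tid <- pl$transcript_id[1]
  rb <- bounds[bounds$transcript_id == tid, , drop = FALSE]
  w <- nchar(excl[1])
  mt <- Biostrings::matchPDict(pdict, Biostrings::DNAString(s))
  starts <- BiocGenerics::start(mt)
  n_per <- S4Vectors::elementNROWS(starts)
  all_hits <- data.frame(motif = rep(excl, n_per),
                         start = unlist(starts, use.names = FALSE) - 1L,
                         stringsAsFactors = FALSE)
  found <- list()
  for (i in seq_len(nrow(rb))) {
    inside <- all_hits$start >= rb$start[i] & all_hits$start + w <= rb$end[i]
    if (any(inside)) {
      found[[length(found) + 1L]] <-
        data.frame(region = rb$region[i], start = all_hits$start[inside],
                   motif = all_hits$motif[inside], stringsAsFactors = FALSE)
    }
  }
  found <- if (length(found)) do.call(rbind, found) else
    data.frame(region = character(0), start = integer(0), motif = character(0))
  want <- pl[pl$motif %in% excl, c("region", "start", "motif")]
  key <- function(d) sort(paste(d$region, d$start, d$motif))
  identical(key(found), key(want))
}

motif_label <- function(m) {
  can <- canonical_motif()
  if (m == can) return("canonical")
  if (nchar(m) == nchar(can)) {
    d <- which(strsplit(m, "")[[1]] != strsplit(can, "")[[1]])
    if (length(d) == 1L) return(paste0("pos", d, substr(m, d, d)))
  }
  "custom"
}

#' Simulate PAR-CLIP reads over planted binding sites
#'
#' For each planted motif, `read_depth` reads are drawn with start positions
#' uniform over the window of starts whose reads fully cover the placement
#' (clipped at transcript bounds). Aligned reference T positions inside a
#' placement convert T->C independently with probability `p_conv`; every
#' aligned base additionally mismatches with probability `p_bg` (substitute
#' uniform over the three alternatives; crosslink conversion takes precedence
#' at a shared position). Background reads are added per transcript at
#' Poisson rate `bg_read_rate` with uniform starts.
#'
#' @param txome A `transcriptome` (typically after [plant_motifs()]).
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed + 1`).
#' @return A `parclip_sim` object: list with `reads` (coordinate-sorted
#'   data.frame: read_id, reference_name, start 0-based, seq) and `t2c_truth`
#'   (data.frame of every written T->C mismatch: read_id, reference_name,
#'   pos, source "crosslink" or "background").
#' @export
simulate_parclip <- function(txome, config, seed = config$seed + 1L) {
  stopifnot(inherits(txome, "transcriptome"))
  validate_sim_config(config)
  set.seed(seed)
  rl <- config$read_len
  tx <- txome$transcripts
  lens <- Biostrings::width(txome$sequences)
  if (nrow(tx) > 0L && rl > min(lens)) {
    stop("read_len (", rl, ") exceeds shortest transcript (", min(lens), ")")
  }

  reads_l <- list()
  truth_l <- list()
  counter <- 0L
  for (i in seq_len(nrow(tx))) {
    tid <- tx$transcript_id[i]
    L <- lens[i]
    ref_chars <- strsplit(as.character(txome$sequences[[i]]), "")[[1]]
    pls <- txome$placements[txome$placements$transcript_id == tid, , drop = FALSE]

    starts <- integer(0)
    if (nrow(pls) > 0L && config$read_depth > 0L) {
      for (j in seq_len(nrow(pls))) {
        pl_s <- pls$start[j]
        pl_e <- pls$start[j] + nchar(pls$motif[j])
        lo <- max(0L, pl_e - rl)
        hi <- min(L - rl, pl_s)
        if (hi < lo) { lo <- hi <- max(0L, min(L - rl, pl_s)) }
        starts <- c(starts, lo + sample.int(hi - lo + 1L, config$read_depth,
                                            replace = TRUE) - 1L)
      }
    }
    nbg <- stats::rpois(1L, config$bg_read_rate)
    if (nbg > 0L) {
      starts <- c(starts, sample.int(L - rl + 1L, nbg, replace = TRUE) - 1L)
    }
    n_reads <- length(starts)
    if (n_reads == 0L) next

    # site_T[p+1]: reference position p is a T inside some placement
    site_T <- rep(FALSE, L)
    for (j in seq_len(nrow(pls))) {
      idx <- (pls$start[j] + 1L):(pls$start[j] + nchar(pls$motif[j]))
      site_T[idx] <- site_T[idx] | (ref_chars[idx] == "T")
    }

    # one long vector over all aligned bases of all reads of this transcript
    pos0 <- rep(starts, each = rl) + rep.int(seq_len(rl) - 1L, n_reads)
    refb <- ref_chars[pos0 + 1L]
    conv <- site_T[pos0 + 1L] & (stats::runif(length(pos0)) < config$p_conv)
    bg <- !conv & (stats::runif(length(pos0)) < config$p_bg)
    readb <- refb
    readb[conv] <- "C"
    if (any(bg)) {
      alt <- vapply(refb[bg], function(b) sample(setdiff(DNA_BASES, b), 1L),
                    character(1))
      readb[bg] <- alt
    }

    m <- matrix(readb, nrow = rl)
    seqs <- apply(m, 2L, paste, collapse = "")
    ids <- sprintf("read%07d", counter + seq_len(n_reads))
    counter <- counter + n_reads
    reads_l[[tid]] <- data.frame(
      read_id = ids, reference_name = tid, start = starts, seq = seqs,
      stringsAsFactors = FALSE
    )
    is_t2c <- refb == "T" & readb == "C"
    if (any(is_t2c)) {
      ri <- rep(ids, each = rl)
      truth_l[[tid]] <- data.frame(
        read_id = ri[is_t2c], reference_name = tid, pos = pos0[is_t2c],
        source = ifelse(conv[is_t2c], "crosslink", "background"),
        stringsAsFactors = FALSE
      )
    }
  }

  reads <- if (length(reads_l)) do.call(rbind, reads_l) else
    data.frame(read_id = character(0), reference_name = character(0),
               start = integer(0), seq = character(0))
  truth <- if (length(truth_l)) do.call(rbind, truth_l) else
    data.frame(read_id = character(0), reference_name = character(0),
               pos = integer(0), source = character(0))
  ord <- order(match(reads$reference_name, tx$transcript_id), reads$start,
               reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  rownames(reads) <- NULL
  rownames(truth) <- NULL
  out <- list(reads = reads, t2c_truth = truth, read_len = rl)
  class(out) <- "parclip_sim"
  out
}

#' Simulate a two-condition count matrix with per-motif suppression
#'
#' Control means are log-normal; the induced-condition mean of gene *g* is
#' \eqn{\mu_g 2^{-\delta k_g}} where \eqn{k_g} is the number of canonical
#' motifs planted in its 3'UTR (variant and custom placements contribute 0
#' unless `variant_delta` supplies a per-label effect). Counts are
#' negative-binomial with the configured dispersion.
#'
#' @param txome A `transcriptome`.
#' @param config A [sim_config()].
#' @param seed Integer seed (default `config$seed + 2`).
#' @param variant_delta Optional named numeric: log2 suppression per placement
#'   for non-canonical labels (names as in `placements$label`).
#' @return List with `counts` (integer matrix genes x samples), `design`
#'   (data.frame sample/condition), `truth` (gene_id, k, control mean mu,
#'   true_lfc).
#' @export
simulate_counts <- function(txome, config, seed = config$seed + 2L,
                            variant_delta = NULL) {
  stopifnot(inherits(txome, "transcriptome"))
  validate_sim_config(config)
  if (config$n_replicates < 2L) stop("need >= 2 replicates per condition")
  set.seed(seed)
  tx <- txome$transcripts
  n <- nrow(tx)
  pl <- txome$placements
  k <- vapply(tx$gene_id, function(g) {
    sum(pl$gene_id == g & pl$region == "utr3" & pl$label == "canonical")
  }, integer(1))
  extra <- rep(0, n)
  if (!is.null(variant_delta)) {
    for (lab in names(variant_delta)) {
      extra <- extra + variant_delta[[lab]] * vapply(tx$gene_id, function(g) {
        sum(pl$gene_id == g & pl$region == "utr3" & pl$label == lab)
      }, integer(1))
    }
  }
  mu <- stats::rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  true_lfc <- -(config$delta * k + extra)
  mu_ind <- mu * 2^true_lfc
  size <- 1 / config$nb_dispersion
  nr <- config$n_replicates
  ctrl <- matrix(stats::rnbinom(n * nr, size = size, mu = rep(mu, nr)),
                 nrow = n)
  ind <- matrix(stats::rnbinom(n * nr, size = size, mu = rep(mu_ind, nr)),
                nrow = n)
  counts <- cbind(ctrl, ind)
  rownames(counts) <- tx$gene_id
  colnames(counts) <- c(paste0("control_", seq_len(nr)),
                        paste0("induced_", seq_len(nr)))
  design <- data.frame(
    sample = colnames(counts),
    condition = rep(c("control", "induced"), each = nr),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene_id = tx$gene_id, k = k, mu = mu,
                      true_lfc = true_lfc, stringsAsFactors = FALSE)
  list(counts = counts, design = design, truth = truth)
}
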