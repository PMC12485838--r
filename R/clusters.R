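get_sequences <- function(reference) {
  if (inherits(reference, "transcriptome")) return(reference$sequences)
  if (methods::is(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    return(Biostrings::readDNAStringSet(reference))
  }
  stop("reference must be a transcriptome, DNAStringSet, or FASTA path")
}

#' Estimate the background mismatch rate from non-T-to-C mismatches
#'
#' T->C conversions are the crosslink signature, so they are excluded from
#' the background numerator; under a uniform-substitution background T->C
#' accounts for 1/12 of all mismatches (P(ref T) x P(sub C) = 1/4 x 1/3), and
#' the 12/11 factor restores that excluded share.
#'
#' @param aln An `aligned_reads` object.
#' @return A `background_model`: list with `n_non_t2c`, `aligned_bases`,
#'   `r_bg` (per-aligned-base background mismatch probability).
#' @export
estimate_background <- function(aln) {
  stopifnot(inherits(aln, "aligned_reads"))
  aligned_bases <- sum(aln$reads$end - aln$reads$start)
  if (aligned_bases == 0L) stop("no aligned bases; cannot estimate background")
  mm <- aln$mismatches
  is_t2c <- mm$ref_base == "T" & mm$read_base == "C"
  n_non <- sum(!is_t2c)
  out <- list(
    n_non_t2c = n_non,
    aligned_bases = aligned_bases,
    r_bg = (n_non / aligned_bases) * (12 / 11)
  )
  class(out) <- "background_model"
  out
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: %d non-T2C mismatches / %d aligned bases, r_bg = %.3g\n",
              x$n_non_t2c, x$aligned_bases, x$r_bg))
  invisible(x)
}

#' Upper tail of the Poisson distribution
#'
#' `poisson_tail(k, mu)` is \eqn{P(X \ge k)} for \eqn{X \sim Poisson(\mu)},
#' including `k` itself. `k = 0` gives 1 for any `mu`; `mu = 0` with
#' `k >= 1` gives 0.
#'
#' @param k Observed count(s), non-negative.
#' @param mu Expectation(s), non-negative.
#' @return Probabilities, vectorized over `k`/`mu`.
#' @export
poisson_tail <- function(k, mu) {
  stopifnot(all(k >= 0), all(mu >= 0))
  ifelse(k == 0, 1, stats::ppois(k - 1, mu, lower.tail = FALSE))
}

#' Form candidate clusters from overlapping reads
#'
#' Candidates are maximal intervals of contiguous read coverage (the union of
#' overlapping reads); candidates with fewer than `min_depth` overlapping
#' reads are dropped. T->C statistics and the covered-T opportunity set are
#' computed against the reference sequence.
#'
#' @param aln An `aligned_reads` object.
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @param min_depth Minimum overlapping reads per candidate (default 3).
#' @return data.frame of unscored candidates: reference_name, start, end
#'   (0-based half-open), read_count, count_T2C, loc_T2C, covered_T_bases.
#' @export
build_candidates <- function(aln, reference, min_depth = 3L) {
  stopifnot(inherits(aln, "aligned_reads"))
  seqs <- get_sequences(reference)
  reads <- aln$reads
  mm <- aln$mismatches
  t2c <- mm[mm$ref_base == "T" & mm$read_base == "C", , drop = FALSE]
  out <- list()
  for (ref in unique(reads$reference_name)) {
    if (!ref %in% names(seqs)) {
      stop("reference sequence missing for ", ref)
    }
    r <- reads[reads$reference_name == ref, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    cand <- IRanges::reduce(ir)
    if (length(cand) == 0L) next
    rc <- IRanges::countOverlaps(cand, ir)
    keep <- rc >= min_depth
    cand <- cand[keep]; rc <- rc[keep]
    if (length(cand) == 0L) next
    L <- Biostrings::width(seqs[ref])
    cov <- as.integer(IRanges::coverage(ir, width = L))
    ref_chars <- strsplit(as.character(seqs[[ref]]), "")[[1]]
    is_t <- ref_chars == "T"
    tt <- t2c[t2c$reference_name == ref, , drop = FALSE]
    st <- BiocGenerics::start(cand) - 1L
    en <- BiocGenerics::end(cand)
    n_t2c <- loc <- covT <- integer(length(cand))
    for (i in seq_along(cand)) {
      inside <- tt$pos >= st[i] & tt$pos < en[i]
      n_t2c[i] <- sum(inside)
      loc[i] <- length(unique(tt$pos[inside]))
      idx <- (st[i] + 1L):en[i]
      covT[i] <- sum(cov[idx][is_t[idx]])
    }
    out[[ref]] <- data.frame(
      reference_name = ref, start = st, end = en, read_count = rc,
      count_T2C = n_t2c, loc_T2C = loc, covered_T_bases = covT,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(reference_name = character(0), start = integer(0),
                      end = integer(0), read_count = integer(0),
                      count_T2C = integer(0), loc_T2C = integer(0),
                      covered_T_bases = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call PAR-CLIP clusters against a Poisson background
#'
#' Scores each candidate with the upper Poisson tail of its observed T->C
#' count against the expectation `r_bg x covered_T_bases`, applies
#' Benjamini-Hochberg correction across candidates, and retains clusters
#' passing the q-value, read-depth, and loc_T2C filters. Output is ranked by
#' `count_T2C` descending.
#'
#' @param aln An `aligned_reads` object.
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @param annotation Optional region annotation ([read_annotation()]); when
#'   supplied each cluster gets a majority-rule region label and gene_id.
#' @param min_depth Minimum reads per cluster (default 3).
#' @param min_loc_t2c Minimum distinct T->C positions (default 2).
#' @param alpha BH q-value cutoff (default 0.05).
#' @param verbose Log background rate and candidate/retained counts.
#' @return data.frame of clusters with the columns of [write_clusters()].
#' @export
call_clusters <- function(aln, reference, annotation = NULL,
                          min_depth = 3L, min_loc_t2c = 2L, alpha = 0.05,
                          verbose = FALSE) {
  bg <- estimate_background(aln)
  cand <- build_candidates(aln, reference, min_depth = min_depth)
  if (nrow(cand) == 0L) {
    if (verbose) message("call_clusters: no candidates at min_depth ", min_depth)
    return(empty_clusters())
  }
  cand$expected_T2C <- bg$r_bg * cand$covered_T_bases
  cand$p_value <- poisson_tail(cand$count_T2C, cand$expected_T2C)
  cand$q_value <- stats::p.adjust(cand$p_value, method = "BH")
  keep <- cand$q_value <= alpha & cand$read_count >= min_depth &
    cand$loc_T2C >= min_loc_t2c
  res <- cand[keep, , drop = FALSE]
  res <- annotate_clusters(res, annotation)
  res <- res[order(-res$count_T2C, -res$loc_T2C, res$reference_name,
                   res$start), , drop = FALSE]
  rownames(res) <- NULL
  if (verbose) {
    message(sprintf("call_clusters: r_bg=%.3g, %d candidates, %d retained",
                    bg$r_bg, nrow(cand), nrow(res)))
  }
  res[, cluster_columns]
}

#' Annotate clusters with transcript regions
#'
#' The region overlapping the majority of the cluster interval wins; ties
#' break by precedence utr3 > cds > utr5 > intron. `gene_id` comes from the
#' transcript contributing the winning overlap. Clusters with no annotated
#' overlap are labelled `unannotated`.
#'
#' @param clusters Cluster data.frame.
#' @param annotation Region annotation from [read_annotation()], or NULL.
#' @return The clusters with `region` and `gene_id` columns filled.
#' @export
annotate_clusters <- function(clusters, annotation = NULL) {
  if (nrow(clusters) == 0L) {
    clusters$region <- character(0); clusters$gene_id <- character(0)
    return(clusters)
  }
  clusters$region <- "unannotated"
  clusters$gene_id <- ""
  if (is.null(annotation)) return(clusters)
  prec <- c(utr3 = 1L, cds = 2L, utr5 = 3L, intron = 4L)
  for (i in seq_len(nrow(clusters))) {
    a <- annotation[annotation$reference_name == clusters$reference_name[i], ,
                    drop = FALSE]
    if (nrow(a) == 0L) next
    ov <- pmin(a$end, clusters$end[i]) - pmax(a$start, clusters$start[i])
    a <- a[ov > 0L, , drop = FALSE]; ov <- ov[ov > 0L]
    if (length(ov) == 0L) next
    best <- which(ov == max(ov))
    if (length(best) > 1L) best <- best[order(prec[a$region[best]])][1L]
    clusters$region[i] <- a$region[best]
    clusters$gene_id[i] <- a$gene_id[best]
  }
  clusters
}

#' Select top-ranked clusters
#'
#' Filters to clusters with at least `min_reads` reads, ranks by `count_T2C`
#' descending (ties: `loc_T2C` descending, then start ascending), and keeps
#' the first `n`.
#'
#' @param clusters Cluster data.frame.
#' @param n Number to keep (default 2000).
#' @param min_reads Minimum read count (default 10).
#' @return The selected subset, ranked.
#' @export
select_top_clusters <- function(clusters, n = 2000L, min_reads = 10L) {
  keep <- clusters[clusters$read_count >= min_reads, , drop = FALSE]
  keep <- keep[order(-keep$count_T2C, -keep$loc_T2C, keep$start), ,
               drop = FALSE]
  utils::head(keep, n)
}
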