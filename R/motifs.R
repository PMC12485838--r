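#' Enumerate all single-nucleotide variants of a motif
#'
#' @param motif ACGT string (canonically the heptamer `ATGAATT`).
#' @return data.frame with `label` (e.g. "pos3C"), `seq`, `position` (1-based
#'   position of the substitution), `base`, one row per variant: exactly
#'   `3 * nchar(motif)` rows, the motif itself excluded.
#' @export
enumerate_variants <- function(motif) {
  stop_if_not_acgt(motif, "motif")
  chars <- strsplit(motif, "")[[1]]
  out <- list()
  for (i in seq_along(chars)) {
    for (b in setdiff(DNA_BASES, chars[i])) {
      v <- chars
      v[i] <- b
      out[[length(out) + 1L]] <- data.frame(
        label = paste0("pos", i, b), seq = paste(v, collapse = ""),
        position = i, base = b, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Scan a sequence for exact motif occurrences within bounds
#'
#' All overlapping exact occurrences whose window lies fully inside
#' `[start, end)` (0-based half-open).
#'
#' @param sequence Character string or `DNAString`.
#' @param motif ACGT pattern.
#' @param start,end Region bounds, 0-based half-open; default whole sequence.
#' @return Sorted integer vector of 0-based hit starts.
#' @export
scan_motif <- function(sequence, motif, start = 0L, end = NULL) {
  s <- as.character(sequence)
  end <- end %||% nchar(s)
  stopifnot(start >= 0L, end <= nchar(s))
  if (end - start < nchar(motif)) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(s))
  hits <- BiocGenerics::start(m) - 1L
  sort(hits[hits >= start & hits + nchar(motif) <= end])
}

#' Scan annotated transcript regions for a set of motifs
#'
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @param annotation Region annotation ([read_annotation()]).
#' @param motifs Named character vector of patterns (names become
#'   `variant_label`; unnamed entries are labelled by their sequence).
#' @return data.frame of hits: transcript_id, gene_id, region, start (0-based
#'   transcript offset), motif, variant_label; position-sorted and
#'   duplicate-free.
#' @export
scan_regions <- function(reference, annotation, motifs) {
  seqs <- get_sequences(reference)
  if (is.null(names(motifs))) names(motifs) <- motifs
  names(motifs)[names(motifs) == ""] <- motifs[names(motifs) == ""]
  keep <- names(seqs) %in% annotation$reference_name
  seqs <- seqs[keep]
  empty <- data.frame(transcript_id = character(0), gene_id = character(0),
                      region = character(0), start = integer(0),
                      motif = character(0), variant_label = character(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  out <- list()
  for (lab in names(motifs)) {
    w <- nchar(motifs[[lab]])
    m <- Biostrings::vmatchPattern(motifs[[lab]], seqs)
    st <- BiocGenerics::start(m)
    n_per <- S4Vectors::elementNROWS(st)
    if (sum(n_per) == 0L) next
    hit <- data.frame(reference_name = rep(names(seqs), n_per),
                      hit_start = unlist(st, use.names = FALSE) - 1L,
                      stringsAsFactors = FALSE)
    mg <- merge(hit, annotation, by = "reference_name")
    mg <- mg[mg$hit_start >= mg$start & mg$hit_start + w <= mg$end, ,
             drop = FALSE]
    if (nrow(mg) == 0L) next
    out[[lab]] <- data.frame(
      transcript_id = mg$transcript_id, gene_id = mg$gene_id,
      region = mg$region, start = mg$hit_start,
      motif = motifs[[lab]], variant_label = lab, stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res[order(res$transcript_id, res$start, res$variant_label), ])
  rownames(res) <- NULL
  res
}

#' Per-gene motif and binding-site summary
#'
#' For each gene a representative transcript is chosen (the one with the
#' longest annotated 3'UTR; a message reports multi-transcript genes).
#' Canonical-motif hits are counted per region and inside retained cluster
#' intervals (a hit counts only if its window lies fully within a cluster).
#' Variant presence in the 3'UTR is reported per variant; under the
#' exclusivity rule (default) a gene counts for a variant only if its 3'UTR
#' carries no canonical occurrence.
#'
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @param annotation Region annotation.
#' @param clusters Retained clusters (may be empty; [empty_clusters()]).
#' @param canonical Canonical motif (default [canonical_motif()]).
#' @param exclusive Apply the variant-exclusivity rule (default TRUE).
#' @return data.frame: gene_id, transcript_id, n_utr5, n_cds, n_utr3,
#'   n_in_clusters, n_clusters, bound, plus one logical `var_<label>` column
#'   per single-nucleotide variant.
#' @export
summarize_genes <- function(reference, annotation, clusters = empty_clusters(),
                            canonical = canonical_motif(), exclusive = TRUE) {
  variants <- enumerate_variants(canonical)
  motifs <- c(stats::setNames(canonical, "canonical"),
              stats::setNames(variants$seq, variants$label))
  # representative transcript: longest 3'UTR
  u3 <- annotation[annotation$region == "utr3", , drop = FALSE]
  u3$len <- u3$end - u3$start
  utr3_len <- if (nrow(u3)) stats::aggregate(len ~ transcript_id, u3, sum) else
    data.frame(transcript_id = character(0), len = integer(0))
  all_tx <- unique(annotation[, c("transcript_id", "gene_id")])
  all_tx$len <- utr3_len$len[match(all_tx$transcript_id,
                                   utr3_len$transcript_id)]
  all_tx$len[is.na(all_tx$len)] <- 0L
  multi <- table(all_tx$gene_id)
  if (any(multi > 1L)) {
    message(sum(multi > 1L),
            " gene(s) with multiple transcripts; using longest 3'UTR")
  }
  all_tx <- all_tx[order(all_tx$gene_id, -all_tx$len, all_tx$transcript_id), ]
  rep_tx <- all_tx[!duplicated(all_tx$gene_id), ]

  ann_rep <- annotation[annotation$transcript_id %in% rep_tx$transcript_id, ]
  hits <- scan_regions(reference, ann_rep, motifs)
  w <- nchar(canonical)

  res <- rep_tx[, c("gene_id", "transcript_id")]
  can <- hits[hits$variant_label == "canonical", , drop = FALSE]
  count_by_region <- function(reg) {
    tab <- table(can$transcript_id[can$region == reg])
    cnt <- as.integer(tab[match(res$transcript_id, names(tab))])
    ifelse(is.na(cnt), 0L, cnt)
  }
  res$n_utr5 <- count_by_region("utr5")
  res$n_cds <- count_by_region("cds")
  res$n_utr3 <- count_by_region("utr3")

  # canonical hits fully contained in a retained cluster interval
  in_cluster <- logical(nrow(can))
  if (nrow(can) && nrow(clusters)) {
    ref_of <- ann_rep$reference_name[match(can$transcript_id,
                                           ann_rep$transcript_id)]
    for (ref in unique(ref_of)) {
      cl <- clusters[clusters$reference_name == ref, , drop = FALSE]
      if (nrow(cl) == 0L) next
      idx <- which(ref_of == ref)
      in_cluster[idx] <- vapply(can$start[idx], function(s) {
        any(cl$start <= s & cl$end >= s + w)
      }, logical(1))
    }
  }
  tab_in <- table(can$transcript_id[in_cluster])
  n_in <- as.integer(tab_in[match(res$transcript_id, names(tab_in))])
  res$n_in_clusters <- ifelse(is.na(n_in), 0L, n_in)

  tab_cl <- table(clusters$gene_id[clusters$gene_id != ""])
  n_cl <- as.integer(tab_cl[match(res$gene_id, names(tab_cl))])
  res$n_clusters <- ifelse(is.na(n_cl), 0L, n_cl)
  res$bound <- res$n_clusters > 0L

  vhits <- hits[hits$variant_label != "canonical" & hits$region == "utr3", ]
  for (j in seq_len(nrow(variants))) {
    lab <- variants$label[j]
    pres <- res$transcript_id %in% vhits$transcript_id[vhits$variant_label == lab]
    if (exclusive) pres <- pres & res$n_utr3 == 0L
    res[[paste0("var_", lab)]] <- pres
  }
  rownames(res) <- NULL
  res
}
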