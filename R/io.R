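#' Write transcript sequences to FASTA
#'
#' @param txome A `transcriptome`.
#' @param path Output path.
#' @export
write_transcriptome_fasta <- function(txome, path) {
  Biostrings::writeXStringSet(txome$sequences, path)
  invisible(path)
}

#' Write transcript region annotation to GTF
#'
#' Emits one `five_prime_utr`/`CDS`/`three_prime_utr` feature per non-empty
#' region, on the transcript itself as sequence (transcript-space pipeline),
#' 1-based inclusive coordinates per GTF convention.
#'
#' @param txome A `transcriptome`.
#' @param path Output path.
#' @export
write_transcriptome_gtf <- function(txome, path) {
  rb <- region_bounds(txome)
  feat <- c(utr5 = "five_prime_utr", cds = "CDS", utr3 = "three_prime_utr")
  if (nrow(rb) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rb$transcript_id,
    ranges = IRanges::IRanges(start = rb$start + 1L, end = rb$end),
    strand = "+",
    type = unname(feat[rb$region]),
    source = "clipkit",
    phase = ifelse(rb$region == "cds", 0L, NA_integer_),
    gene_id = rb$gene_id,
    transcript_id = rb$transcript_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript region annotation from GTF
#'
#' Converts GTF 1-based inclusive features to the package-internal 0-based
#' half-open convention. Recognized feature types: `five_prime_utr`, `CDS`,
#' `three_prime_utr` (others are ignored).
#'
#' @param gtf_path Path to a GTF file.
#' @return data.frame with columns `reference_name`, `transcript_id`,
#'   `gene_id`, `region` (utr5/cds/utr3), `start`, `end` (0-based half-open).
#'   Errors if two features of different region type overlap on one
#'   transcript.
#' @export
read_annotation <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  map <- c(five_prime_utr = "utr5", CDS = "cds", three_prime_utr = "utr3")
  keep <- as.character(gr$type) %in% names(map)
  gr <- gr[keep]
  ann <- data.frame(
    reference_name = as.character(GenomicRanges::seqnames(gr)),
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    region = unname(map[as.character(gr$type)]),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
  # contradictory overlapping features within one transcript are an error
  for (tid in unique(ann$transcript_id)) {
    a <- ann[ann$transcript_id == tid, ]
    if (nrow(a) < 2L) next
    ir <- IRanges::IRanges(a$start + 1L, a$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    bad <- qh < sh & a$region[qh] != a$region[sh]
    if (any(bad)) {
      stop("overlapping contradictory region features for transcript ", tid)
    }
  }
  ann[order(ann$transcript_id, ann$start), , drop = FALSE]
}

#' Write PAR-CLIP alignments to SAM
#'
#' Coordinate-sorted SAM with MD and NM tags computed against the reference
#' sequences; all records are ungapped (`<read_len>M`), mapped, forward
#' strand.
#'
#' @param sim A `parclip_sim` (or a data.frame like its `$reads`).
#' @param txome The `transcriptome` the reads were simulated from.
#' @param path Output path.
#' @export
write_sam <- function(sim, txome, path) {
  reads <- if (inherits(sim, "parclip_sim")) sim$reads else sim
  tx_ids <- txome$transcripts$transcript_id
  lens <- Biostrings::width(txome$sequences)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  if (length(tx_ids)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", tx_ids, lens), con)
  }
  writeLines("@PG\tID:clipkit\tPN:clipkit", con)
  if (nrow(reads) == 0L) return(invisible(path))
  ord <- order(match(reads$reference_name, tx_ids), reads$start, reads$read_id)
  reads <- reads[ord, , drop = FALSE]
  refs <- as.character(txome$sequences)
  lines <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    rl <- nchar(r$seq)
    ref_chars <- strsplit(substr(refs[[r$reference_name]], r$start + 1L,
                                 r$start + rl), "")[[1]]
    read_chars <- strsplit(r$seq, "")[[1]]
    nm <- sum(ref_chars != read_chars)
    md <- make_md_tag(ref_chars, read_chars)
    paste(r$read_id, 0L, r$reference_name, r$start + 1L, 255L,
          paste0(rl, "M"), "*", 0L, 0L, r$seq,
          strrep("I", rl), paste0("NM:i:", nm), paste0("MD:Z:", md),
          sep = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read PAR-CLIP alignments from SAM
#'
#' Consumes mapped, primary, ungapped records and decodes each record's
#' mismatches from its MD tag plus read sequence. Records whose CIGAR
#' contains anything but a single match run are skipped with a warning and
#' counted; a record without an MD tag is an error.
#'
#' @param sam_path Path to a SAM (or BAM) file with MD tags.
#' @param max_mismatches Drop reads carrying more than this many mismatches,
#'   mirroring a strict end-to-end alignment setting. Default 2; use `Inf`
#'   to keep everything.
#' @return An `aligned_reads` object: list with `reads` (data.frame read_id,
#'   reference_name, start, end 0-based half-open, seq), `mismatches`
#'   (data.frame read_id, reference_name, pos, ref_base, read_base),
#'   `n_skipped_indel`, `n_dropped_mismatch`.
#' @export
read_alignments <- function(sam_path, max_mismatches = 2) {
  bam <- if (grepl("\\.bam$", sam_path)) sam_path else
    Rsamtools::asBam(sam_path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MD", "NM")
  )
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- res$flag
  keep <- !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  simple <- grepl("^[0-9]+M$", res$cigar) & !is.na(res$cigar)
  n_skipped <- sum(keep & !simple)
  if (n_skipped > 0L) {
    warning(n_skipped, " record(s) with non-ungapped CIGAR skipped")
  }
  keep <- keep & simple
  md <- if (is.null(res$tag$MD)) rep(NA_character_, sum(keep)) else
    res$tag$MD[keep]
  if (anyNA(md)) {
    stop("record without MD tag: ",
         paste(utils::head(res$qname[keep][is.na(md)], 3L), collapse = ", "))
  }
  qname <- res$qname[keep]
  rname <- as.character(res$rname[keep])
  start0 <- res$pos[keep] - 1L
  seqs <- as.character(res$seq[keep])
  rl <- nchar(seqs)

  mm_l <- vector("list", length(qname))
  n_mm <- integer(length(qname))
  for (i in seq_along(qname)) {
    dec <- parse_md_tag(md[i])
    n_mm[i] <- length(dec$offsets)
    if (n_mm[i] > 0L) {
      mm_l[[i]] <- data.frame(
        read_id = qname[i], reference_name = rname[i],
        pos = start0[i] + dec$offsets,
        ref_base = dec$ref_bases,
        read_base = substring(seqs[i], dec$offsets + 1L, dec$offsets + 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  ok <- n_mm <= max_mismatches
  n_dropped <- sum(!ok)
  reads <- data.frame(
    read_id = qname[ok], reference_name = rname[ok],
    start = start0[ok], end = start0[ok] + rl[ok], seq = seqs[ok],
    stringsAsFactors = FALSE
  )
  mism <- mm_l[ok]
  mism <- if (any(lengths(mism) > 0L)) do.call(rbind, mism) else
    data.frame(read_id = character(0), reference_name = character(0),
               pos = integer(0), ref_base = character(0),
               read_base = character(0), stringsAsFactors = FALSE)
  rownames(reads) <- NULL
  rownames(mism) <- NULL
  out <- list(reads = reads, mismatches = mism,
              n_skipped_indel = n_skipped, n_dropped_mismatch = n_dropped)
  class(out) <- "aligned_reads"
  out
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("aligned_reads:", nrow(x$reads), "reads,", nrow(x$mismatches),
      "mismatches (", x$n_skipped_indel, "indel-skipped,",
      x$n_dropped_mismatch, "dropped by mismatch filter )\n")
  invisible(x)
}

cluster_columns <- c("reference_name", "start", "end", "read_count",
                     "count_T2C", "loc_T2C", "covered_T_bases",
                     "expected_T2C", "p_value", "q_value", "region", "gene_id")

#' Write called clusters to BED6+
#'
#' BED coordinates are 0-based half-open; the score column carries
#' `count_T2C`. Extra columns: read_count, count_T2C, loc_T2C,
#' covered_T_bases, expected_T2C, p_value, q_value, region, gene_id. A `#`
#' header line documents the columns.
#'
#' @param clusters data.frame of clusters (see [call_clusters()]).
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  hdr <- paste0("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand\t",
                paste(cluster_columns[-(1:3)], collapse = "\t"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(clusters) > 0L) {
    num <- function(x) format(x, digits = 15, scientific = TRUE, trim = TRUE)
    lines <- paste(
      clusters$reference_name, clusters$start, clusters$end,
      sprintf("cluster_%05d", seq_len(nrow(clusters))),
      clusters$count_T2C, "+",
      clusters$read_count, clusters$count_T2C, clusters$loc_T2C,
      clusters$covered_T_bases,
      num(clusters$expected_T2C), num(clusters$p_value), num(clusters$q_value),
      clusters$region, clusters$gene_id,
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read clusters written by [write_clusters()]
#'
#' @param path BED6+ path.
#' @return data.frame with the standard cluster columns.
#' @export
read_clusters <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("reference_name", "start", "end",
                                        "name", "score", "strand",
                                        cluster_columns[-(1:3)]))
  if (nrow(df) == 0L) {
    return(empty_clusters())
  }
  df[, cluster_columns]
}

empty_clusters <- function() {
  data.frame(
    reference_name = character(0), start = integer(0), end = integer(0),
    read_count = integer(0), count_T2C = integer(0), loc_T2C = integer(0),
    covered_T_bases = integer(0), expected_T2C = numeric(0),
    p_value = numeric(0), q_value = numeric(0),
    region = character(0), gene_id = character(0), stringsAsFactors = FALSE
  )
}

#' Write a count matrix as TSV
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV path with a `gene_id` column.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  m
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
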