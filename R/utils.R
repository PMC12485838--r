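`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Region coordinate table for a transcriptome
#'
#' @param txome A `transcriptome` object.
#' @return A data.frame with one row per non-empty region per transcript:
#'   `transcript_id`, `gene_id`, `region` (utr5/cds/utr3), `start`, `end`
#'   (0-based half-open transcript coordinates).
#' @export
region_bounds <- function(txome) {
  tx <- txome$transcripts
  out <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    u5 <- tx$utr5_len[i]; cds <- tx$cds_len[i]; u3 <- tx$utr3_len[i]
    data.frame(
      transcript_id = tx$transcript_id[i],
      gene_id = tx$gene_id[i],
      region = c("utr5", "cds", "utr3"),
      start = c(0L, u5, u5 + cds),
      end = c(u5, u5 + cds, u5 + cds + u3),
      stringsAsFactors = FALSE
    )
  }))
  out[out$end > out$start, , drop = FALSE]
}

# MD tag for an ungapped alignment: runs of matches interleaved with the
# reference base at each mismatch (SAM optional-field MD semantics).
make_md_tag <- function(ref_chars, read_chars) {
  n <- length(ref_chars)
  mm <- which(ref_chars != read_chars)
  if (length(mm) == 0L) return(as.character(n))
  parts <- character(0)
  prev <- 0L
  for (i in mm) {
    parts <- c(parts, as.character(i - prev - 1L), ref_chars[i])
    prev <- i
  }
  paste0(paste(parts, collapse = ""), n - prev)
}

# Decode an MD tag for an ungapped alignment into 0-based read offsets of
# mismatches plus the reference base at each.
parse_md_tag <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[ACGTN]+|[ACGTN]", md))[[1]]
  off <- 0L
  pos <- integer(0)
  refb <- character(0)
  for (tk in toks) {
    if (grepl("^\\d+$", tk)) {
      off <- off + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      stop("MD tag with deletion not supported for ungapped alignments: ", md)
    } else {
      pos <- c(pos, off)
      refb <- c(refb, tk)
      off <- off + 1L
    }
  }
  list(offsets = pos, ref_bases = refb, aligned_len = off)
}

stop_if_not_acgt <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x))) {
    stop(what, " must contain only A/C/G/T characters")
  }
  invisible(x)
}
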