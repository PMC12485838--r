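as_char_seqs <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(as.character(x))
  if (is.list(x)) return(unlist(x, use.names = FALSE))
  as.character(x)
}

#' Count overlapping k-mers over the full 4^k space
#'
#' Overlapping windows at step 1; windows containing non-ACGT characters are
#' skipped; absent k-mers report 0.
#'
#' @param seqs Character vector, list of character vectors, or `DNAStringSet`.
#' @param k Word size (default 5; must be between 1 and 10).
#' @return Named integer vector of length `4^k` in lexicographic order.
#' @export
count_kmers <- function(seqs, k = 5L) {
  stopifnot(k >= 1L, k <= 10L)
  seqs <- as_char_seqs(seqs)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    kmers <- Biostrings::mkAllStrings(DNA_BASES, k)
    out <- integer(length(kmers)); names(out) <- kmers
    return(out)
  }
  f <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                            width = k)
  out <- as.integer(colSums(f))
  names(out) <- colnames(f)
  out
}

#' Extract flanking background regions around clusters
#'
#' For each cluster, the up-to-`flank`-nt slice upstream of its start and the
#' up-to-`flank`-nt slice downstream of its end, clipped at transcript
#' bounds, excluding any overlap with any cluster interval. A slice that a
#' neighbouring cluster punches through may yield several fragments; the
#' fragments of one (cluster, side) slice stay grouped as one background
#' region (k-mer windows never span fragment junctions).
#'
#' @param clusters Cluster data.frame.
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @param flank Flank length in nt (default 200).
#' @return Named list of background regions, each a character vector of
#'   fragment sequences; empty slices are dropped.
#' @export
extract_background <- function(clusters, reference, flank = 200L) {
  seqs <- get_sequences(reference)
  out <- list()
  for (ref in unique(clusters$reference_name)) {
    cl <- clusters[clusters$reference_name == ref, , drop = FALSE]
    L <- Biostrings::width(seqs[ref])
    occupied <- IRanges::reduce(IRanges::IRanges(cl$start + 1L, cl$end))
    s <- as.character(seqs[[ref]])
    for (i in seq_len(nrow(cl))) {
      slices <- list(
        up = c(max(0L, cl$start[i] - flank), cl$start[i]),
        down = c(cl$end[i], min(L, cl$end[i] + flank))
      )
      for (side in names(slices)) {
        b <- slices[[side]]
        if (b[2] <= b[1]) next
        frag <- IRanges::setdiff(IRanges::IRanges(b[1] + 1L, b[2]), occupied)
        if (length(frag) == 0L) next
        pieces <- substring(s, BiocGenerics::start(frag),
                            BiocGenerics::end(frag))
        out[[paste0(ref, ":", cl$start[i], "-", cl$end[i], ":", side)]] <- pieces
      }
    }
  }
  out
}

#' k-mer Z-score enrichment of cluster sequences over flanking background
#'
#' The enrichment statistic is Z = (X - mu) / sigma, where X is the pooled
#' proportion of a k-mer among all cluster-sequence windows and mu, sigma are
#' the mean and standard deviation of that k-mer's proportion across
#' background regions. k-mers whose background standard deviation is zero are
#' flagged
#' (`sigma_zero`); among those, a k-mer whose cluster proportion still
#' differs from mu is ranked with a floored sigma (the binomial standard
#' error of the pooled background proportion, half-count corrected), while
#' the degenerate x == mu == 0 case scores z = 0.
#'
#' @param cluster_seqs Cluster sequences (character vector or `DNAStringSet`).
#' @param background_regions List of background regions as returned by
#'   [extract_background()] (each element one region; a plain character
#'   vector is treated as one region per element).
#' @param k Word size (default 5).
#' @param sigma_mode `"regions"` (default): sigma is the across-region
#'   standard deviation of proportions; `"binomial"`: sigma is the binomial
#'   standard error of the pooled background proportion.
#' @param sd_population Use the population (n) rather than sample (n-1)
#'   standard deviation across regions. Default FALSE.
#' @param min_windows Background regions with fewer k-mer windows than this
#'   are excluded from the mean/sd estimate (default 30): a sliver of a few
#'   windows turns a single occurrence into an extreme proportion and
#'   inflates sigma for every k-mer it contains.
#' @return data.frame sorted by `z` descending with columns kmer, x_cluster,
#'   mu_bg, sigma_bg, z, sigma_zero, au_rich, atg_containing, and a
#'   `mu_bg_pooled` diagnostic column.
#' @export
kmer_zscores <- function(cluster_seqs, background_regions, k = 5L,
                         sigma_mode = c("regions", "binomial"),
                         sd_population = FALSE, min_windows = 30L) {
  sigma_mode <- match.arg(sigma_mode)
  if (!is.list(background_regions)) {
    background_regions <- as.list(as_char_seqs(background_regions))
  }
  cl_counts <- count_kmers(cluster_seqs, k)
  n_cl <- sum(cl_counts)
  if (n_cl == 0L) stop("cluster sequences contain no k-mer window")
  x_cluster <- cl_counts / n_cl

  bg_counts <- lapply(background_regions, count_kmers, k = k)
  wins <- vapply(bg_counts, sum, numeric(1))
  usable <- wins >= max(1L, min_windows)
  if (sum(usable) < 2L) usable <- wins > 0  # fall back on sparse input
  bg_counts <- bg_counts[usable]
  wins <- wins[usable]
  if (length(bg_counts) < 2L) {
    stop("need at least 2 background regions with k-mer windows")
  }
  props <- do.call(rbind, Map(function(cnt, w) cnt / w, bg_counts, wins))
  mu <- colMeans(props)
  if (sigma_mode == "regions") {
    n <- nrow(props)
    ss <- colSums(sweep(props, 2L, mu)^2)
    sigma <- sqrt(ss / (if (sd_population) n else n - 1L))
  } else {
    pooled <- Reduce(`+`, bg_counts) / sum(wins)
    sigma <- sqrt(pooled * (1 - pooled) / mean(wins))
  }
  pooled_mu <- Reduce(`+`, bg_counts) / sum(wins)

  res <- data.frame(
    kmer = names(cl_counts),
    x_cluster = as.numeric(x_cluster),
    mu_bg = as.numeric(mu),
    sigma_bg = as.numeric(sigma),
    mu_bg_pooled = as.numeric(pooled_mu),
    stringsAsFactors = FALSE
  )
  res$sigma_zero <- res$sigma_bg == 0
  # sigma == 0 (k-mer equally represented -- typically absent -- in every
  # background region) leaves Z undefined; rank those with a floored sigma:
  # the binomial standard error of the pooled background proportion under a
  # half-count continuity correction. Keeps cluster-only k-mers ordered by
  # evidence instead of collapsing to +/-Inf.
  n_bg <- sum(wins)
  ptilde <- (Reduce(`+`, bg_counts) + 0.5) / (n_bg + 1)
  sigma_floor <- sqrt(ptilde * (1 - ptilde) / mean(wins))
  sigma_eff <- ifelse(res$sigma_zero, sigma_floor, res$sigma_bg)
  res$z <- (res$x_cluster - res$mu_bg) / sigma_eff
  res <- classify_kmers(res)
  res[order(is.na(res$z), -ifelse(is.na(res$z), -Inf, res$z)), , drop = FALSE]
}

#' Flag AU-rich and ATG-containing k-mers
#'
#' `au_rich`: at least 3 A's or at least 3 T's among the bases (the DNA-space
#' reading of >= 3 A's or >= 3 U's); `atg_containing`: contains ATG as a
#' substring. Class semantics are defined for 5-mers but computed for any k.
#'
#' @param stats data.frame with a `kmer` column.
#' @return The input with logical `au_rich` and `atg_containing` columns.
#' @export
classify_kmers <- function(stats) {
  nA <- nchar(stats$kmer) - nchar(gsub("A", "", stats$kmer))
  nT <- nchar(stats$kmer) - nchar(gsub("T", "", stats$kmer))
  stats$au_rich <- nA >= 3L | nT >= 3L
  stats$atg_containing <- grepl("ATG", stats$kmer, fixed = TRUE)
  stats
}

#' Extract cluster interval sequences
#'
#' @param clusters Cluster data.frame.
#' @param reference Transcriptome, named `DNAStringSet`, or FASTA path.
#' @return Character vector of cluster sequences.
#' @export
cluster_sequences <- function(clusters, reference) {
  seqs <- get_sequences(reference)
  vapply(seq_len(nrow(clusters)), function(i) {
    substr(as.character(seqs[[clusters$reference_name[i]]]),
           clusters$start[i] + 1L, clusters$end[i])
  }, character(1))
}
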