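#' Crosslinked reads per million (XRPM) per gene
#'
#' A read is crosslinked when it carries at least one T->C mismatch. In the
#' default `universe = "sites"` a crosslinked read counts toward a gene if it
#' overlaps one of that gene's retained clusters; with `universe = "all"`
#' every crosslinked read counts toward its transcript's gene regardless of
#' clusters (requires `annotation`). XRPM normalizes to one million
#' crosslinked reads per library, so values sum to 1e6 whenever any
#' crosslinked read exists.
#'
#' @param aln An `aligned_reads` object.
#' @param clusters Retained clusters with `gene_id` (used for `"sites"`).
#' @param annotation Region annotation (used for `"all"`).
#' @param universe `"sites"` (default) or `"all"`.
#' @return data.frame: gene_id, crosslinked_reads, xrpm.
#' @export
xrpm_per_gene <- function(aln, clusters = NULL, annotation = NULL,
                          universe = c("sites", "all")) {
  universe <- match.arg(universe)
  mm <- aln$mismatches
  t2c_reads <- unique(mm$read_id[mm$ref_base == "T" & mm$read_base == "C"])
  reads <- aln$reads[aln$reads$read_id %in% t2c_reads, , drop = FALSE]
  if (universe == "sites") {
    if (is.null(clusters)) stop("universe='sites' requires clusters")
    genes <- sort(unique(clusters$gene_id[clusters$gene_id != ""]))
    n <- vapply(genes, function(g) {
      cl <- clusters[clusters$gene_id == g, , drop = FALSE]
      hit <- rep(FALSE, nrow(reads))
      for (i in seq_len(nrow(cl))) {
        hit <- hit | (reads$reference_name == cl$reference_name[i] &
                        reads$start < cl$end[i] & reads$end > cl$start[i])
      }
      sum(hit)
    }, integer(1))
  } else {
    if (is.null(annotation)) stop("universe='all' requires annotation")
    gmap <- unique(annotation[, c("reference_name", "gene_id")])
    genes <- sort(unique(gmap$gene_id))
    byref <- table(factor(reads$reference_name, levels = gmap$reference_name))
    n <- vapply(genes, function(g) {
      sum(byref[gmap$reference_name[gmap$gene_id == g]])
    }, numeric(1))
  }
  total <- sum(n)
  if (total == 0) {
    message("xrpm_per_gene: no crosslinked reads; all XRPM set to 0")
    xr <- rep(0, length(genes))
  } else {
    xr <- n / total * 1e6
  }
  data.frame(gene_id = genes, crosslinked_reads = as.integer(n), xrpm = xr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Spearman correlation matrix across libraries
#'
#' The gene universe is the union over libraries; genes absent from a library
#' are imputed as 0. Ties receive average ranks. A library with a constant
#' XRPM vector yields `NA` against every other library.
#'
#' @param tables Named list of XRPM tables ([xrpm_per_gene()]).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(tables) {
  stopifnot(length(tables) >= 2L)
  if (is.null(names(tables))) names(tables) <- paste0("lib", seq_along(tables))
  genes <- sort(unique(unlist(lapply(tables, `[[`, "gene_id"))))
  m <- vapply(tables, function(t) {
    x <- t$xrpm[match(genes, t$gene_id)]
    x[is.na(x)] <- 0
    x
  }, numeric(length(genes)))
  res <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(res) <- 1
  res
}

#' Metagene profile of crosslink signal
#'
#' Each annotated cluster contributes its `count_T2C` at its midpoint's
#' normalized position within its region; the 5'UTR, CDS, and 3'UTR segments
#' are concatenated on a 0-1 axis with widths proportional to
#' `bins_per_region`. The density sums to 1.
#'
#' @param clusters Annotated clusters.
#' @param annotation Region annotation.
#' @param bins_per_region Integer triple (utr5, cds, utr3); default
#'   c(10, 30, 30).
#' @return data.frame: bin (1..sum(bins)), region, axis midpoint `x` in
#'   `[0, 1]`, density. Empty if no cluster falls in an annotated region.
#' @export
metagene_profile <- function(clusters, annotation,
                             bins_per_region = c(10L, 30L, 30L)) {
  regions <- c("utr5", "cds", "utr3")
  stopifnot(length(bins_per_region) == 3L, all(bins_per_region >= 1L))
  total_bins <- sum(bins_per_region)
  offs <- c(0L, cumsum(bins_per_region))[1:3]
  names(offs) <- regions
  counts <- numeric(total_bins)
  cl <- clusters[clusters$region %in% regions, , drop = FALSE]
  if (nrow(cl) == 0L) {
    message("metagene_profile: no clusters in annotated regions")
  }
  for (i in seq_len(nrow(cl))) {
    a <- annotation[annotation$reference_name == cl$reference_name[i] &
                      annotation$region == cl$region[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    mid <- (cl$start[i] + cl$end[i]) / 2
    rel <- (mid - a$start[1]) / (a$end[1] - a$start[1])
    rel <- min(max(rel, 0), 1 - 1e-9)
    nb <- bins_per_region[match(cl$region[i], regions)]
    bin <- offs[[cl$region[i]]] + floor(rel * nb) + 1L
    counts[bin] <- counts[bin] + cl$count_T2C[i]
  }
  dens <- if (sum(counts) > 0) counts / sum(counts) else counts
  data.frame(
    bin = seq_len(total_bins),
    region = rep(regions, bins_per_region),
    x = (seq_len(total_bins) - 0.5) / total_bins,
    density = dens,
    stringsAsFactors = FALSE
  )
}

#' Region composition of called clusters
#'
#' @param clusters Annotated clusters.
#' @return data.frame of fractions over utr5/cds/utr3/intron/unannotated,
#'   summing to 1 (all zero when no clusters).
#' @export
region_composition <- function(clusters) {
  levels <- c("utr5", "cds", "utr3", "intron", "unannotated")
  n <- table(factor(clusters$region, levels = levels))
  frac <- if (sum(n) > 0) as.numeric(n) / sum(n) else as.numeric(n)
  data.frame(region = levels, n = as.integer(n), fraction = frac,
             stringsAsFactors = FALSE)
}
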