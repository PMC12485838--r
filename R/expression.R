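#' Fold-change estimation with median-of-ratios normalization
#'
#' Size factors follow the median-of-ratios construction: per-gene geometric
#' means over genes with all-positive counts form the reference, each
#' sample's factor is the median ratio to that reference. `baseMean` is the
#' mean of normalized counts over all samples; `log2fc` contrasts induced vs
#' control means with a pseudocount. No hypothesis test is performed (`padj`
#' is `NA`); an external differential-expression table can be ingested with
#' [ingest_de_table()] instead.
#'
#' @param counts Integer matrix, genes x samples, with rownames/colnames.
#' @param design data.frame with `sample` and `condition` columns; condition
#'   levels must be `control` and `induced`, each with >= 2 samples.
#' @param pseudocount Added to both condition means before the ratio
#'   (default 0.5).
#' @return data.frame (`expression_table`): gene_id, baseMean, log2fc, padj
#'   (NA); size factors in `attr(, "size_factors")`.
#' @export
compute_log2fc <- function(counts, design, pseudocount = 0.5) {
  stopifnot(all(c("sample", "condition") %in% names(design)),
            all(design$sample %in% colnames(counts)))
  ctrl <- design$sample[design$condition == "control"]
  ind <- design$sample[design$condition == "induced"]
  if (length(ctrl) < 2L || length(ind) < 2L) {
    stop("each condition needs at least 2 samples")
  }
  m <- counts[, c(ctrl, ind), drop = FALSE]
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no gene with all-positive counts for size factors")
  loggeo <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2L, function(col) {
    stats::median(exp(log(col) - loggeo))
  })
  norm <- sweep(m, 2L, sf, "/")
  base_mean <- rowMeans(norm)
  mu_c <- rowMeans(norm[, ctrl, drop = FALSE])
  mu_i <- rowMeans(norm[, ind, drop = FALSE])
  res <- data.frame(
    gene_id = rownames(counts),
    baseMean = base_mean,
    log2fc = log2((mu_i + pseudocount) / (mu_c + pseudocount)),
    padj = NA_real_,
    stringsAsFactors = FALSE
  )
  attr(res, "size_factors") <- sf
  class(res) <- c("expression_table", "data.frame")
  res
}

#' Ingest an external differential-expression table
#'
#' Reads a TSV with at least `gene_id`, `baseMean`, `log2FoldChange`
#' (optionally `padj`), e.g. a DESeq2 results export.
#'
#' @param path TSV path.
#' @return An `expression_table` data.frame (gene_id, baseMean, log2fc, padj).
#' @export
ingest_de_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "baseMean", "log2FoldChange")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  res <- data.frame(
    gene_id = df$gene_id,
    baseMean = df$baseMean,
    log2fc = df$log2FoldChange,
    padj = if ("padj" %in% names(df)) df$padj else NA_real_,
    stringsAsFactors = FALSE
  )
  class(res) <- c("expression_table", "data.frame")
  res
}

#' Significance filter for differential expression
#'
#' Keeps records with `padj <= padj_max` and `|log2fc| > lfc_min`; records
#' with missing `padj` are excluded from the filtered view.
#'
#' @param expr An `expression_table`.
#' @param padj_max Adjusted-p cutoff (default 0.05).
#' @param lfc_min Absolute log2 fold-change cutoff, exclusive (default 1).
#' @return The filtered subset.
#' @export
significant_genes <- function(expr, padj_max = 0.05, lfc_min = 1) {
  keep <- !is.na(expr$padj) & expr$padj <= padj_max & abs(expr$log2fc) > lfc_min
  expr[keep, , drop = FALSE]
}

#' Empirical cumulative distribution points
#'
#' Right-continuous step CDF: one point per distinct value (ties share a
#' step), cumulative fraction reaching 1 at the maximum.
#'
#' @param values Numeric vector, non-empty.
#' @return data.frame with sorted `value` and `fraction` columns.
#' @export
cdf <- function(values) {
  if (length(values) == 0L) stop("cdf of an empty vector is undefined")
  v <- sort(values)
  u <- unique(v)
  data.frame(value = u,
             fraction = cumsum(tabulate(match(v, u))) / length(v))
}

make_bins <- function(expr, membership) {
  bins <- lapply(names(membership), function(lab) {
    g <- membership[[lab]]
    lfc <- expr$log2fc[match(g, expr$gene_id)]
    list(label = lab, gene_ids = g, n = length(g),
         median_lfc = if (length(lfc)) stats::median(lfc) else NA_real_,
         cdf = if (length(lfc)) cdf(lfc) else NULL)
  })
  names(bins) <- names(membership)
  summary <- data.frame(
    label = names(membership),
    n = vapply(bins, `[[`, numeric(1), "n"),
    median_lfc = vapply(bins, `[[`, numeric(1), "median_lfc"),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  out <- list(summary = summary, bins = bins)
  class(out) <- "bin_result"
  out
}

#' @export
print.bin_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

filter_expressed <- function(expr, summaries, min_basemean) {
  expr <- expr[expr$baseMean >= min_basemean, , drop = FALSE]
  expr[expr$gene_id %in% summaries$gene_id, , drop = FALSE]
}

#' Bin genes by motif/binding-site count
#'
#' Genes expressed above `min_basemean` are partitioned into bins: two or
#' more motifs, exactly one, bound without a motif, and unbound. In
#' `count_space = "sites"` the motif count is the number of canonical hits
#' inside retained clusters (`n_in_clusters`); in `"region"` it is the number
#' anywhere in the 3'UTR (`n_utr3`).
#'
#' @param expr An `expression_table`.
#' @param summaries Per-gene summary from [summarize_genes()].
#' @param min_basemean Expression filter (default 10).
#' @param count_space `"sites"` or `"region"`.
#' @return A `bin_result`: `$summary` (label, n, median_lfc) and `$bins`
#'   (per-bin gene ids and CDF points).
#' @export
bin_by_site_count <- function(expr, summaries, min_basemean = 10,
                              count_space = c("sites", "region")) {
  count_space <- match.arg(count_space)
  expr <- filter_expressed(expr, summaries, min_basemean)
  s <- summaries[match(expr$gene_id, summaries$gene_id), ]
  m <- if (count_space == "sites") s$n_in_clusters else s$n_utr3
  membership <- list(
    ge2 = expr$gene_id[m >= 2L],
    one = expr$gene_id[m == 1L],
    bound_no_motif = expr$gene_id[m == 0L & s$bound],
    unbound = expr$gene_id[m == 0L & !s$bound]
  )
  make_bins(expr, membership)
}

#' Bin genes by the region holding their motifs
#'
#' Bins: `utr3_ge2`, `utr3_1`, `cds`, `utr5`, `none`. A gene with motifs in
#' several regions is assigned by priority utr3 > cds > utr5, so the bins
#' partition the filtered gene set.
#'
#' @inheritParams bin_by_site_count
#' @return A `bin_result`.
#' @export
bin_by_region <- function(expr, summaries, min_basemean = 10) {
  expr <- filter_expressed(expr, summaries, min_basemean)
  s <- summaries[match(expr$gene_id, summaries$gene_id), ]
  lab <- ifelse(s$n_utr3 >= 2L, "utr3_ge2",
         ifelse(s$n_utr3 == 1L, "utr3_1",
         ifelse(s$n_cds >= 1L, "cds",
         ifelse(s$n_utr5 >= 1L, "utr5", "none"))))
  membership <- split(expr$gene_id, factor(lab, levels = c(
    "utr3_ge2", "utr3_1", "cds", "utr5", "none")))
  make_bins(expr, membership)
}

#' Single-nucleotide-variant tolerance tile
#'
#' One cell per variant (21 for a heptamer): the median log2 fold change of
#' genes whose 3'UTR carries that variant and, under the exclusivity rule, no
#' canonical motif. A `canonical` reference cell (genes with >= 1 canonical
#' 3'UTR motif) is included.
#'
#' @inheritParams bin_by_site_count
#' @param canonical Canonical motif (default [canonical_motif()]).
#' @return data.frame of tile cells: label, position (NA for canonical),
#'   base, n, median_lfc.
#' @export
variant_tile <- function(expr, summaries, min_basemean = 10,
                         canonical = canonical_motif()) {
  expr <- filter_expressed(expr, summaries, min_basemean)
  s <- summaries[match(expr$gene_id, summaries$gene_id), ]
  variants <- enumerate_variants(canonical)
  cell <- function(label, position, base, genes) {
    lfc <- expr$log2fc[expr$gene_id %in% genes]
    data.frame(label = label, position = position, base = base,
               n = length(lfc),
               median_lfc = if (length(lfc)) stats::median(lfc) else NA_real_,
               stringsAsFactors = FALSE)
  }
  cells <- lapply(seq_len(nrow(variants)), function(j) {
    lab <- variants$label[j]
    cell(lab, variants$position[j], variants$base[j],
         expr$gene_id[s[[paste0("var_", lab)]]])
  })
  canon <- cell("canonical", NA_integer_, NA_character_,
                expr$gene_id[s$n_utr3 >= 1L])
  out <- rbind(canon, do.call(rbind, cells))
  rownames(out) <- NULL
  out
}
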