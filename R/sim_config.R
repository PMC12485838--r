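#' Canonical recognition heptamer
#'
#' The heptamer recognition element in DNA alphabet (RNA U is represented as T
#' throughout the package, because every file format touched is DNA-space).
#'
#' @return A length-1 character string, `"ATGAATT"`.
#' @export
canonical_motif <- function() "ATGAATT"

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator: transcriptome
#' geometry, expression model, and PAR-CLIP read model. All downstream
#' generator calls are deterministic given `seed`.
#'
#' @param seed Integer seed controlling all generator randomness.
#' @param n_transcripts Number of transcripts (one gene per transcript).
#' @param utr5_range,cds_range,utr3_range Integer length-2 vectors; region
#'   lengths are drawn uniformly (in nt) from these inclusive ranges.
#' @param expression_meanlog,expression_sdlog Log-normal parameters for the
#'   baseline (control) per-gene mean expression.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\alpha} so that
#'   \eqn{Var = \mu + \alpha \mu^2}; must be > 0.
#' @param n_replicates Replicates per condition (control and induced).
#' @param delta Per-motif suppression effect in log2 units: a gene carrying
#'   `k` canonical 3'UTR motifs has induced mean \eqn{\mu \cdot 2^{-\delta k}}.
#'   `delta = 0` is the null.
#' @param read_depth PAR-CLIP reads drawn per planted binding site.
#' @param bg_read_rate Expected background reads per transcript (Poisson).
#' @param p_conv Probability that an aligned reference T inside a planted site
#'   is converted T->C (the crosslink signature).
#' @param p_bg Per-aligned-base background mismatch probability; the
#'   substituted base is uniform over the three alternatives, so background
#'   T->C occurs at share 1/3 when the reference base is T.
#' @param read_len Read length in nt.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 300L,
                       utr5_range = c(50L, 150L),
                       cds_range = c(300L, 600L),
                       utr3_range = c(200L, 500L),
                       expression_meanlog = log(200),
                       expression_sdlog = 1,
                       nb_dispersion = 0.05,
                       n_replicates = 4L,
                       delta = 1.0,
                       read_depth = 50L,
                       bg_read_rate = 1,
                       p_conv = 0.3,
                       p_bg = 0.002,
                       read_len = 30L) {
  cfg <- list(
    seed = as.integer(seed),
    n_transcripts = as.integer(n_transcripts),
    utr5_range = as.integer(utr5_range),
    cds_range = as.integer(cds_range),
    utr3_range = as.integer(utr3_range),
    expression_meanlog = expression_meanlog,
    expression_sdlog = expression_sdlog,
    nb_dispersion = nb_dispersion,
    n_replicates = as.integer(n_replicates),
    delta = delta,
    read_depth = as.integer(read_depth),
    bg_read_rate = bg_read_rate,
    p_conv = p_conv,
    p_bg = p_bg,
    read_len = as.integer(read_len)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$seed) == 1L, !is.na(cfg$seed),
    cfg$n_transcripts >= 0L,
    length(cfg$utr5_range) == 2L, length(cfg$cds_range) == 2L,
    length(cfg$utr3_range) == 2L,
    all(cfg$utr5_range >= 0L), all(cfg$cds_range >= 0L),
    all(cfg$utr3_range >= 0L),
    cfg$utr5_range[1] <= cfg$utr5_range[2],
    cfg$cds_range[1] <= cfg$cds_range[2],
    cfg$utr3_range[1] <= cfg$utr3_range[2],
    cfg$nb_dispersion > 0,
    cfg$n_replicates >= 1L,
    cfg$p_conv >= 0, cfg$p_conv <= 1,
    cfg$p_bg >= 0, cfg$p_bg <= 1,
    cfg$read_depth >= 0L,
    cfg$bg_read_rate >= 0,
    cfg$read_len >= 1L
  )
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_transcripts, "transcripts, seed", x$seed, "\n")
  cat("  regions utr5", paste(x$utr5_range, collapse = "-"),
      "cds", paste(x$cds_range, collapse = "-"),
      "utr3", paste(x$utr3_range, collapse = "-"), "nt\n")
  cat("  reads: depth", x$read_depth, "len", x$read_len,
      "p_conv", x$p_conv, "p_bg", x$p_bg, "\n")
  cat("  counts:", x$n_replicates, "reps/condition, dispersion",
      x$nb_dispersion, "delta", x$delta, "\n")
  invisible(x)
}
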