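#' Upper-tail normal probability for a motif Z-score
#'
#' `P = 1 - pnorm(z)`: the probability that a standard normal exceeds `z`.
#' This is the conversion applied to ZFM values before filtering.
#'
#' @param z Z-score(s).
#' @return Upper-tail probabilities in `[0, 1]`.
#' @export
zfm_pvalue <- function(z) {
  stats::pnorm(z, lower.tail = FALSE)
}

#' Length-stratified resampling enrichment of promoter motifs (ZFM)
#'
#' Tests whether motifs occur more often in a foreground promoter set than
#' expected. The null model preserves the foreground's promoter-length
#' composition: `k_sets` surrogate sets are drawn from the genome-wide
#' promoter set, each taking -- without replacement, independently across
#' sets -- from every length bin exactly as many promoters as the foreground
#' has in that bin. For motif *i* with foreground count `N`, surrogate mean
#' `mean_i` and surrogate standard deviation `stdev_i` (divisor `k - 1`),
#' `ZFM = (N - mean_i) / stdev_i` and `P = 1 - pnorm(N, mean_i, stdev_i)`,
#' computed only when `N > mean_i`; motifs at or below their surrogate mean
#' are reported with `enriched = FALSE` and `P = 1` (depletion is not
#' scored). A zero surrogate deviation with `N > mean` is flagged as a
#' degenerate null and reported with `P = 0`.
#'
#' @param foreground A `PromoterSet`, or a character vector of promoter ids
#'   taken from `genome` (the latter avoids re-scanning).
#' @param genome Genome-wide `PromoterSet` providing the null.
#' @param motifs Motif library (data frame, `Motif` objects or patterns).
#' @param k_sets Number of surrogate sets (default 1000).
#' @param seed Optional integer seed; fixing it makes every surrogate draw,
#'   hence the whole result table, reproducible.
#' @param both_strands Count reverse-strand occurrences too?
#' @param genome_counts Optional precomputed
#'   [promoter_motif_count_matrix()] for `genome` and `motifs`.
#' @return A `MotifEnrichmentResult` data frame with columns `motif_id`,
#'   `pattern`, `keywords`, `count`, `surrogate_mean`, `surrogate_stdev`,
#'   `zfm`, `p_value`, `enriched`, `degenerate`, sorted by ascending
#'   `p_value` (ties by motif id).
#' @export
zfm_enrichment <- function(foreground, genome, motifs, k_sets = 1000,
                           seed = NULL, both_strands = FALSE,
                           genome_counts = NULL) {
  stopifnot(inherits(genome, "PromoterSet"))
  motifs <- .as_motif_table(motifs)
  if (!is.numeric(k_sets) || k_sets < 2)
    stop("`k_sets` must be >= 2")
  if (is.null(genome_counts)) {
    genome_counts <- promoter_motif_count_matrix(genome, motifs,
                                                 both_strands)
  } else {
    stopifnot(nrow(genome_counts) == length(genome$records),
              identical(colnames(genome_counts), motifs$motif_id))
  }

  if (is.character(foreground)) {
    miss <- setdiff(foreground, names(genome$records))
    if (length(miss))
      stop("foreground ids absent from genome set: ",
           paste(utils::head(miss, 5), collapse = ", "))
    fg_bins <- genome$length_bin[foreground]
    N <- colSums(genome_counts[foreground, , drop = FALSE])
  } else {
    stopifnot(inherits(foreground, "PromoterSet"))
    fg_bins <- foreground$length_bin
    N <- motif_counts(foreground, motifs, both_strands)
  }

  fg_tab <- table(fg_bins)
  gen_tab <- table(genome$length_bin)
  used <- names(fg_tab)[fg_tab > 0]
  short <- used[gen_tab[used] < fg_tab[used]]
  if (length(short))
    stop("surrogate draw infeasible: genome bin '", short[1], "' has ",
         gen_tab[short[1]], " promoters but the foreground needs ",
         fg_tab[short[1]])
  bin_ids <- split(names(genome$records), genome$length_bin)

  draw_counts <- function() {
    sel <- unlist(lapply(used, function(b) {
      ids <- bin_ids[[b]]
      ids[sample.int(length(ids), fg_tab[[b]])]
    }), use.names = FALSE)
    colSums(genome_counts[sel, , drop = FALSE])
  }
  run <- function() {
    m <- matrix(0, k_sets, ncol(genome_counts))
    for (k in seq_len(k_sets)) m[k, ] <- draw_counts()
    m
  }
  sur <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  mu <- colMeans(sur)
  sdev <- apply(sur, 2, stats::sd)
  enriched <- N > mu
  zfm <- ifelse(enriched & sdev > 0, (N - mu) / sdev, NA_real_)
  p <- rep(1, length(N))
  degenerate <- enriched & sdev == 0
  p[enriched & sdev > 0] <- stats::pnorm(N[enriched & sdev > 0],
                                         mu[enriched & sdev > 0],
                                         sdev[enriched & sdev > 0],
                                         lower.tail = FALSE)
  p[degenerate] <- 0
  res <- data.frame(motif_id = motifs$motif_id, pattern = motifs$pattern,
                    keywords = motifs$keywords,
                    count = as.integer(N),
                    surrogate_mean = mu, surrogate_stdev = sdev,
                    zfm = zfm, p_value = p,
                    enriched = enriched, degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(res$p_value, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("MotifEnrichmentResult", class(res))
  res
}

#' Filter enrichment results by P-value
#'
#' Keeps motifs flagged as enriched with `p_value < p_cutoff`. The default
#' cutoff is 0.1; displays typically use the stricter preset 0.05.
#'
#' @param results A [zfm_enrichment()] result.
#' @param p_cutoff P-value cutoff in `(0, 1]`.
#' @return The filtered data frame.
#' @export
significance_filter <- function(results, p_cutoff = 0.1) {
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1 ||
      p_cutoff <= 0 || p_cutoff > 1)
    stop("`p_cutoff` must be in (0, 1]")
  out <- results[results$enriched & results$p_value < p_cutoff, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an enrichment report (TSV)
#'
#' Columns `Motif` (pattern), `Factor` (motif id), `Count`, `ZFM`,
#' `P-value` (six decimals) and `Keywords`.
#'
#' @param results A [zfm_enrichment()] result.
#' @param path Output path.
#' @return `results`, invisibly.
#' @export
write_enrichment_report <- function(results, path) {
  df <- data.frame(
    Motif = results$pattern,
    Factor = results$motif_id,
    Count = results$count,
    ZFM = ifelse(is.na(results$zfm), "", sprintf("%.2f", results$zfm)),
    `P-value` = sprintf("%.6f", results$p_value),
    Keywords = results$keywords,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
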