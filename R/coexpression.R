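#' Pearson correlation between two expression vectors
#'
#' Thin wrapper around [stats::cor()] adding the input checks shared by the
#' network and pattern-search code paths: equal length, at least 3 paired
#' samples, and non-zero variance in both vectors (a zero-variance vector has
#' no defined correlation; callers exclude such genes from ranking).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Pearson product-moment correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need >= 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input: correlation undefined")
  stats::cor(x, y)
}

# Correlation matrix + per-gene rank matrix over the genes with non-zero
# variance. Ranks are positions in each gene's PCC-descending partner list,
# ties broken lexicographically by gene id so ranking is deterministic.
.cor_ranks <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (ncol(v) < 3) stop("need >= 3 samples to rank correlations")
  sds <- apply(v, 1, stats::sd)
  skipped <- rownames(v)[sds == 0]
  v <- v[sds > 0, , drop = FALSE]
  if (nrow(v) < 2)
    stop("fewer than 2 genes with non-zero variance")
  cm <- stats::cor(t(v))
  ids <- rownames(cm)
  n <- nrow(cm)
  R <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-cm[i, others], ids[others])]
    R[i, ord] <- seq_along(ord)
  }
  list(cor = cm, ranks = R, ids = ids, skipped = skipped)
}

#' Mutual ranks for all gene pairs
#'
#' For every unordered pair of genes with non-zero variance, computes the
#' Pearson correlation, the two reciprocal list positions (`rank_a` =
#' position of `gene_y` in `gene_x`'s PCC-descending partner list, `rank_b`
#' the converse) and the mutual rank `mr = sqrt(rank_a * rank_b)`. Smaller
#' MR means stronger co-expression; `mr = 1` iff the two genes are each
#' other's top partner.
#'
#' Genes with zero variance across samples are excluded from ranking and
#' reported in the `"skipped"` attribute.
#'
#' @param x An `ExpressionMatrix` with >= 3 samples.
#' @return A data frame with columns `gene_x`, `gene_y` (lexicographically
#'   `gene_x < gene_y`), `pcc`, `rank_a`, `rank_b`, `mr`, ordered by
#'   (`gene_x`, `gene_y`). Attributes: `ids` (ranked genes), `skipped`.
#' @export
mutual_rank <- function(x) {
  cr <- .cor_ranks(x)
  ids <- sort(cr$ids)
  cm <- cr$cor[ids, ids, drop = FALSE]
  R <- cr$ranks[ids, ids, drop = FALSE]
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  gx <- ids[ut[, 1]]
  gy <- ids[ut[, 2]]
  ra <- R[cbind(ut[, 1], ut[, 2])]
  rb <- R[cbind(ut[, 2], ut[, 1])]
  out <- data.frame(gene_x = gx, gene_y = gy,
                    pcc = cm[ut],
                    rank_a = ra, rank_b = rb,
                    mr = sqrt(as.numeric(ra) * as.numeric(rb)),
                    stringsAsFactors = FALSE)
  attr(out, "ids") <- ids
  attr(out, "skipped") <- cr$skipped
  out
}

#' Build an MR-thresholded co-expression network
#'
#' Keeps the gene pairs whose mutual rank is at most `mr_threshold`
#' (default 30, the threshold used for genome-scale plant co-expression
#' networks). All ranked genes stay in the node set, so isolated nodes are
#' retained.
#'
#' @param x An `ExpressionMatrix`.
#' @param mr_threshold Maximum mutual rank of a kept edge (default 30).
#' @return A `CoexpressionNetwork`: list with `nodes`, `edges` (a
#'   [mutual_rank()]-style data frame), `mr_threshold`, `mirna_pairs` and
#'   `skipped` (zero-variance genes).
#' @export
build_network <- function(x, mr_threshold = 30) {
  if (!is.numeric(mr_threshold) || length(mr_threshold) != 1 ||
      mr_threshold < 0)
    stop("`mr_threshold` must be a single non-negative number")
  rp <- mutual_rank(x)
  edges <- rp[rp$mr <= mr_threshold, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = attr(rp, "ids"), edges = edges,
         mr_threshold = mr_threshold,
         mirna_pairs = data.frame(mirna_id = character(),
                                  target_id = character(),
                                  tier = character(),
                                  stringsAsFactors = FALSE),
         skipped = attr(rp, "skipped")),
    class = "CoexpressionNetwork")
}

#' Average degree of a network
#'
#' The bookkeeping summary `2 * |edges| / |nodes|`, as printed in network
#' exchange-file headers. Accepts either a `CoexpressionNetwork` or raw
#' counts.
#'
#' @param n_edges Edge count, or a `CoexpressionNetwork`.
#' @param n_nodes Node count (ignored when a network is given).
#' @return Average degree as a number.
#' @export
average_degree <- function(n_edges, n_nodes = NULL) {
  if (inherits(n_edges, "CoexpressionNetwork")) {
    n_nodes <- length(n_edges$nodes)
    n_edges <- nrow(n_edges$edges)
  }
  if (!is.numeric(n_edges) || !is.numeric(n_nodes) || n_nodes <= 0)
    stop("need a positive node count")
  2 * n_edges / n_nodes
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges (MR <=", x$mr_threshold, "); average degree",
      format(average_degree(x), digits = 3), "\n")
  if (nrow(x$mirna_pairs))
    cat("  +", nrow(x$mirna_pairs), "miRNA:target pairs\n")
  invisible(x)
}

#' Most positively / negatively correlated partners of a probe
#'
#' Returns the probes whose correlation with `probe` exceeds `pos_min`
#' (descending PCC) and those below `neg_max` (ascending PCC), each
#' truncated at `top_k`. Defaults match the display convention
#' PCC > 0.7 / PCC < -0.65 with at most 60 probes per list.
#'
#' @param x An `ExpressionMatrix`.
#' @param probe Probe id present in `x`.
#' @param pos_min Lower bound (exclusive) for the positive list.
#' @param neg_max Upper bound (exclusive) for the negative list.
#' @param top_k Maximum list length (default 60).
#' @return List with data frames `positive` and `negative`
#'   (columns `probe_id`, `pcc`).
#' @export
correlated_partners <- function(x, probe, pos_min = 0.7, neg_max = -0.65,
                                top_k = 60) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!probe %in% rownames(v)) stop("unknown probe: ", probe)
  if (stats::sd(v[probe, ]) == 0)
    stop("probe has zero variance: ", probe)
  others <- setdiff(rownames(v), probe)
  others <- others[apply(v[others, , drop = FALSE], 1, stats::sd) > 0]
  r <- as.vector(stats::cor(t(v[others, , drop = FALSE]), v[probe, ]))
  names(r) <- others
  pos <- r[r > pos_min]
  pos <- pos[order(-pos, names(pos))]
  neg <- r[r < neg_max]
  neg <- neg[order(neg, names(neg))]
  mk <- function(v) data.frame(probe_id = names(v), pcc = unname(v),
                               stringsAsFactors = FALSE, row.names = NULL)
  list(positive = utils::head(mk(pos), top_k),
       negative = utils::head(mk(neg), top_k))
}

# MR-ascending partner list of gene g (tie-break: lexicographic id)
.top_partners <- function(mrm, ids, g, k, exclude = character()) {
  others <- setdiff(ids, c(g, exclude))
  mr <- mrm[g, others]
  ord <- others[order(mr, others)]
  ord <- utils::head(ord, k)
  data.frame(gene = ord, mr = unname(mrm[g, ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Three-level neighborhood (ego network) around a gene
#'
#' Level 1 holds the `level1_size` (default 10) partners of the center with
#' the smallest mutual rank; level 2 holds, for each level-1 gene, its
#' `level2_size` (default 5) smallest-MR partners excluding the center; level
#' 3 collects, from each level-2 gene's own top-`level1_size` list, only the
#' edges that land on genes already displayed in levels 1-2 - genes outside
#' that set are unlikely to be closely related to the center and are dropped.
#' All lists are MR-ascending with lexicographic tie-break.
#'
#' @param x An `ExpressionMatrix`.
#' @param center Center gene id.
#' @param level1_size,level2_size Display sizes for the first two levels.
#' @return A `NeighborhoodView`: list with `center`, `level1` (data frame
#'   `gene`, `mr`), `level2` (named list of such data frames), and
#'   `level3_edges` (data frame `gene_from`, `gene_to`, `mr`).
#' @export
neighborhood <- function(x, center, level1_size = 10, level2_size = 5) {
  cr <- .cor_ranks(x)
  if (!center %in% cr$ids) {
    if (center %in% cr$skipped)
      stop("center gene has zero variance: ", center)
    stop("unknown gene: ", center)
  }
  mrm <- sqrt(cr$ranks * t(cr$ranks))
  ids <- cr$ids
  l1 <- .top_partners(mrm, ids, center, level1_size)
  l2 <- lapply(l1$gene, function(g)
    .top_partners(mrm, ids, g, level2_size, exclude = center))
  names(l2) <- l1$gene
  displayed <- union(l1$gene, unlist(lapply(l2, `[[`, "gene")))
  edges <- list()
  l2_genes <- sort(unique(unlist(lapply(l2, `[[`, "gene"))))
  for (g2 in l2_genes) {
    cand <- .top_partners(mrm, ids, g2, level1_size)
    keep <- cand[cand$gene %in% displayed, , drop = FALSE]
    if (nrow(keep))
      edges[[g2]] <- data.frame(gene_from = g2, gene_to = keep$gene,
                                mr = keep$mr, stringsAsFactors = FALSE)
  }
  l3 <- if (length(edges)) do.call(rbind, edges)
        else data.frame(gene_from = character(), gene_to = character(),
                        mr = numeric(), stringsAsFactors = FALSE)
  # deduplicate unordered pairs
  if (nrow(l3)) {
    key <- paste(pmin(l3$gene_from, l3$gene_to),
                 pmax(l3$gene_from, l3$gene_to))
    l3 <- l3[!duplicated(key), , drop = FALSE]
    l3 <- l3[order(l3$gene_from, l3$gene_to), , drop = FALSE]
    rownames(l3) <- NULL
  }
  structure(list(center = center, level1 = l1, level2 = l2,
                 level3_edges = l3),
            class = "NeighborhoodView")
}

#' @export
print.NeighborhoodView <- function(x, ...) {
  cat("NeighborhoodView of", x$center, ":", nrow(x$level1),
      "level-1 genes,", length(unique(unlist(lapply(x$level2, `[[`, "gene")))),
      "level-2 genes,", nrow(x$level3_edges), "level-3 edges\n")
  invisible(x)
}

#' Attach miRNA:target pairs to a network
#'
#' Pairs whose target gene is not a network node are skipped with a warning;
#' network edges are unchanged. The credibility `tier` label (e.g.
#' `"high"`/`"low"`) is carried through as supplied.
#'
#' @param network A `CoexpressionNetwork`.
#' @param pairs Data frame with columns `mirna_id`, `target_id`, `tier`.
#' @return The network with `mirna_pairs` extended.
#' @export
attach_mirna_pairs <- function(network, pairs) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  need <- c("mirna_id", "target_id", "tier")
  if (!all(need %in% names(pairs)))
    stop("`pairs` needs columns: ", paste(need, collapse = ", "))
  ok <- pairs$target_id %in% network$nodes
  if (any(!ok))
    warning(sum(!ok), " pair(s) with unresolvable target skipped: ",
            paste(utils::head(pairs$target_id[!ok], 5), collapse = ", "))
  network$mirna_pairs <- rbind(network$mirna_pairs,
                               pairs[ok, need, drop = FALSE])
  rownames(network$mirna_pairs) <- NULL
  network
}

#' Write the edge list of a network as TSV
#'
#' Columns: `gene_x`, `gene_y`, `pcc`, `rank_a`, `rank_b`, `mr`.
#'
#' @param network A `CoexpressionNetwork`.
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(network)
}

#' Network exchange file (JSON)
#'
#' A plain JSON representation (nodes, MR-thresholded edges, miRNA pairs
#' with tiers) consumable by generic graph viewers.
#'
#' @param network A `CoexpressionNetwork`.
#' @param path JSON path.
#' @return `network` invisibly (write); a `CoexpressionNetwork` (read).
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "CoexpressionNetwork"))
  jsonlite::write_json(
    list(mr_threshold = network$mr_threshold,
         n_nodes = length(network$nodes),
         n_edges = nrow(network$edges),
         average_degree = average_degree(network),
         nodes = network$nodes,
         edges = network$edges,
         mirna_pairs = network$mirna_pairs,
         skipped = network$skipped),
    path, auto_unbox = TRUE, digits = NA)
  invisible(network)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  pairs <- as.data.frame(obj$mirna_pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs))
    pairs <- data.frame(mirna_id = character(), target_id = character(),
                        tier = character(), stringsAsFactors = FALSE)
  structure(list(nodes = obj$nodes, edges = edges,
                 mr_threshold = obj$mr_threshold,
                 mirna_pairs = pairs,
                 skipped = obj$skipped %||% character()),
            class = "CoexpressionNetwork")
}

#' Neighborhood exchange file (JSON)
#'
#' Nodes carry a `level` tag (0 = center, 1, 2); edges carry the mutual rank
#' and the expansion level that introduced them.
#'
#' @param view A `NeighborhoodView`.
#' @param path JSON path.
#' @return `view`, invisibly.
#' @export
write_neighborhood_json <- function(view, path) {
  stopifnot(inherits(view, "NeighborhoodView"))
  lvl <- c(stats::setNames(0L, view$center),
           stats::setNames(rep(1L, nrow(view$level1)), view$level1$gene))
  for (g in unlist(lapply(view$level2, `[[`, "gene")))
    if (!g %in% names(lvl)) lvl[g] <- 2L
  nodes <- data.frame(id = names(lvl), level = unname(lvl),
                      stringsAsFactors = FALSE)
  e1 <- data.frame(source = view$center, target = view$level1$gene,
                   mr = view$level1$mr, level = 1L,
                   stringsAsFactors = FALSE)
  e2 <- do.call(rbind, lapply(names(view$level2), function(g) {
    d <- view$level2[[g]]
    if (!nrow(d)) return(NULL)
    data.frame(source = g, target = d$gene, mr = d$mr, level = 2L,
               stringsAsFactors = FALSE)
  }))
  e3 <- if (nrow(view$level3_edges))
    data.frame(source = view$level3_edges$gene_from,
               target = view$level3_edges$gene_to,
               mr = view$level3_edges$mr, level = 3L,
               stringsAsFactors = FALSE) else NULL
  edges <- rbind(e1, e2, e3)
  jsonlite::write_json(list(center = view$center, nodes = nodes,
                            edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(view)
}
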