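# Independent brute-force oracles. These deliberately use naive explicit
# loops and their own data layouts so agreement with the package functions
# is a genuine cross-check, not a tautology.

# all-pairs mutual ranks by materializing every gene's full sorted PCC list
oracle_mutual_rank <- function(v) {
  ids <- rownames(v)
  n <- length(ids)
  pc <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    pc[ids[i], ids[j]] <- cor(v[ids[i], ], v[ids[j], ])
  sorted_list <- function(a) {
    others <- setdiff(ids, a)
    others[order(-pc[a, others], others)]
  }
  lists <- lapply(ids, sorted_list)
  names(lists) <- ids
  sids <- sort(ids)
  rows <- list()
  for (i in seq_along(sids)) for (j in seq_along(sids)) if (j > i) {
    a <- sids[i]; b <- sids[j]
    ra <- match(b, lists[[a]])
    rb <- match(a, lists[[b]])
    rows[[length(rows) + 1]] <- data.frame(
      gene_x = a, gene_y = b, pcc = pc[a, b],
      rank_a = ra, rank_b = rb, mr = sqrt(ra * rb),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# three-level expansion by materializing full MR-sorted partner lists
oracle_neighborhood <- function(v, center, l1_size = 10, l2_size = 5) {
  pairs <- oracle_mutual_rank(v)
  ids <- rownames(v)
  mr <- matrix(NA_real_, length(ids), length(ids),
               dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    mr[pairs$gene_x[r], pairs$gene_y[r]] <- pairs$mr[r]
    mr[pairs$gene_y[r], pairs$gene_x[r]] <- pairs$mr[r]
  }
  sorted_mr <- function(g, exclude = character()) {
    others <- setdiff(ids, c(g, exclude))
    others[order(mr[g, others], others)]
  }
  l1 <- head(sorted_mr(center), l1_size)
  l2 <- lapply(l1, function(g) head(sorted_mr(g, exclude = center),
                                    l2_size))
  names(l2) <- l1
  displayed <- union(l1, unlist(l2))
  edges <- list()
  for (g2 in sort(unique(unlist(l2)))) {
    for (p in head(sorted_mr(g2), l1_size)) {
      if (p %in% displayed) {
        key <- paste(min(g2, p), max(g2, p))
        if (!key %in% names(edges))
          edges[[key]] <- data.frame(gene_from = g2, gene_to = p,
                                     mr = mr[g2, p],
                                     stringsAsFactors = FALSE)
      }
    }
  }
  l3 <- if (length(edges)) do.call(rbind, edges)
        else data.frame(gene_from = character(), gene_to = character(),
                        mr = numeric(), stringsAsFactors = FALSE)
  if (nrow(l3)) {
    l3 <- l3[order(l3$gene_from, l3$gene_to), , drop = FALSE]
    rownames(l3) <- NULL
  }
  list(level1 = l1, level2 = l2, level3_edges = l3)
}

# regex-free IUPAC window scan
oracle_scan <- function(seq, pattern) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                V = c("A", "C", "G"), H = c("A", "C", "T"),
                D = c("A", "G", "T"), B = c("C", "G", "T"),
                N = c("A", "C", "G", "T", "N"))
  sv <- strsplit(toupper(seq), "")[[1]]
  pv <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer(0)
  if (length(pv) > length(sv)) return(hits)
  for (s in 0:(length(sv) - length(pv))) {
    ok <- TRUE
    for (k in seq_along(pv)) {
      if (!sv[s + k] %in% iupac[[pv[k]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# naive per-position rule evaluation of one miRNA:window duplex
oracle_duplex_flags <- function(mirna, window, mfe_ratio_min = 0.75) {
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  mv <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  wv <- rev(strsplit(chartr("T", "U", toupper(window)), "")[[1]])
  L <- length(mv)
  state <- character(L)
  for (i in seq_len(L)) {
    state[i] <- if (wv[i] == comp[[mv[i]]]) "WC"
    else if ((mv[i] == "G" && wv[i] == "U") ||
             (mv[i] == "U" && wv[i] == "G")) "GU"
    else "MM"
  }
  total <- 0; fh <- 0
  for (i in seq_len(L)) {
    w <- if (state[i] == "MM") 1 else if (state[i] == "GU") 0.5 else 0
    total <- total + w
    if (i <= 10) fh <- fh + w
  }
  longest_run <- function(idx) {
    best <- 0; cur <- 0
    for (i in idx) {
      if (state[i] == "MM") { cur <- cur + 1; best <- max(best, cur) }
      else cur <- 0
    }
    best
  }
  run_all <- longest_run(seq_len(L))
  run_seed <- longest_run(2:min(12, L))
  # energy: loop over adjacent paired positions using the same embedded
  # stack parameters, with an independent mismatch-run counter
  energy <- function(states, ms, ts) {
    e <- 0
    for (i in seq_len(L - 1)) {
      if (states[i] != "MM" && states[i + 1] != "MM")
        e <- e + txmine:::.stack_energy(ms[i], ts[i], ms[i + 1], ts[i + 1])
    }
    in_run <- FALSE
    for (i in seq_len(L)) {
      if (states[i] == "MM" && !in_run) { e <- e + 1; in_run <- TRUE }
      if (states[i] != "MM") in_run <- FALSE
    }
    min(e, 0)
  }
  mfe_site <- energy(state, mv, wv)
  pv <- unname(comp[mv])
  mfe_perfect <- energy(rep("WC", L), mv, pv)
  ratio <- if (mfe_perfect < 0) min(1, max(0, mfe_site / mfe_perfect)) else 0
  a <- total <= 4 && fh <= 2.5
  b <- run_all <= 2 && run_seed <= 1
  cc <- all(state[intersect(11:12, seq_len(L))] == "WC")
  d <- ratio >= mfe_ratio_min
  c(a = a, b = b, c = cc, d = d, passes = a && b && cc && d)
}
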