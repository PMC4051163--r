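# --- RNA alphabet helpers -------------------------------------------------

RNA_COMP <- c(A = "U", U = "A", G = "C", C = "G")
# wobble partner (base on the other strand forming a G:U pair), NA if none
RNA_WOBBLE <- c(A = NA, U = "G", G = "U", C = NA)

.to_rna <- function(s, what = "sequence") {
  s <- chartr("Tt", "Uu", toupper(s))
  if (grepl("[^ACGU]", s))
    stop("invalid letter(s) in ", what, " (allowed: A,C,G,U/T)")
  s
}

# classify aligned base pairs: miRNA base m against the opposing target
# base t. WC = Watson-Crick, GU = wobble, MM = mismatch.
.classify_pairs <- function(m, t) {
  state <- rep("MM", length(m))
  state[t == unname(RNA_COMP[m])] <- "WC"
  state[(m == "G" & t == "U") | (m == "U" & t == "G")] <- "GU"
  state
}

# longest run of consecutive MM states (0 when none). G:U wobbles are
# treated as paired, so a wobble terminates a mismatch run.
.max_mm_run <- function(states) {
  r <- rle(states == "MM")
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

# --- nearest-neighbor duplex energy model ---------------------------------

# Watson-Crick stack free energies (kcal/mol at 37C, Turner-style
# parameters). Key "XY/WZ": miRNA dinucleotide 5'-XY-3' over the opposing
# target dinucleotide 3'-WZ-5'. The remaining WC stacks follow from the
# symmetry dG(X1X2/Y1Y2) = dG(Y2Y1/X2X1).
.WC_STACKS <- c(
  "AA/UU" = -0.93, "AU/UA" = -1.10, "UA/AU" = -1.33,
  "CU/GA" = -2.08, "CA/GU" = -2.11, "GU/CA" = -2.24,
  "GA/CU" = -2.35, "CG/GC" = -2.36, "GG/CC" = -3.26, "GC/CG" = -3.42)

# stacks involving G:U wobbles use a compact two-level parameterization:
# one wobble in the stack, or two
.GU_STACK_ONE <- -1.2
.GU_STACK_TWO <- -0.5
# destabilization charged once per contiguous internal mismatch run
.LOOP_PENALTY <- 1.0

.is_pair <- function(m, t) {
  t == unname(RNA_COMP[m]) | (m == "G" & t == "U") | (m == "U" & t == "G")
}

.is_wobble <- function(m, t) (m == "G" & t == "U") | (m == "U" & t == "G")

# stack energy for two adjacent paired positions (m1:t1 then m2:t2 along
# the miRNA 5'->3')
.stack_energy <- function(m1, t1, m2, t2) {
  w1 <- .is_wobble(m1, t1); w2 <- .is_wobble(m2, t2)
  if (w1 && w2) return(.GU_STACK_TWO)
  if (w1 || w2) return(.GU_STACK_ONE)
  key <- paste0(m1, m2, "/", t1, t2)
  if (!is.na(.WC_STACKS[key])) return(unname(.WC_STACKS[key]))
  sym <- paste0(t2, t1, "/", m2, m1)
  unname(.WC_STACKS[sym])
}

# --- duplex construction and scoring --------------------------------------

#' Build a miRNA:site duplex
#'
#' Aligns a miRNA (5'->3') against one candidate target site of the same
#' length (transcript window, 5'->3') in antiparallel orientation: miRNA
#' position `i` pairs with site position `L + 1 - i`. Every position is
#' classified as Watson-Crick pair (`WC`), G:U wobble (`GU`) or mismatch
#' (`MM`). T and U are treated identically.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site Target site sequence of the same length, 5'->3'.
#' @param mirna_id,target_id Identifiers carried into the result.
#' @param site_start 0-based start of the site on its transcript.
#' @return An object of class `MirnaDuplex` with the per-position `pairing`
#'   state vector (indexed from the miRNA 5' end).
#' @export
mirna_duplex <- function(mirna, site, mirna_id = "miRNA",
                         target_id = "target", site_start = 0L) {
  mv <- strsplit(.to_rna(mirna, "miRNA"), "")[[1]]
  sv <- strsplit(.to_rna(site, "site"), "")[[1]]
  if (length(mv) != length(sv))
    stop("miRNA and site must have equal length")
  if (length(mv) < 2) stop("duplex too short")
  tv <- rev(sv)  # tv[i] = target base opposite miRNA position i
  structure(list(mirna_id = mirna_id, target_id = target_id,
                 site_start = as.integer(site_start),
                 mirna = paste(mv, collapse = ""),
                 site = paste(sv, collapse = ""),
                 pairing = .classify_pairs(mv, tv)),
            class = "MirnaDuplex")
}

#' Score a duplex: wobble-weighted mismatches and mismatch runs
#'
#' Mismatches count 1 and G:U wobbles `gu_weight_total` (default 0.5)
#' toward the total score; over the first half (miRNA positions 1-10 from
#' the 5' end) wobbles always count 0.5. Run statistics consider only `MM`
#' states: a wobble is treated as paired and therefore ends a run.
#' `max_run_2_12` is the longest mismatch run within miRNA positions 2-12.
#'
#' @param duplex A [mirna_duplex()].
#' @param gu_weight_total Weight of a G:U pair in the total score. The
#'   default 0.5 applies the wobble half-weight uniformly; set to 1 to
#'   restrict the half-weight to the first-half budget only.
#' @return The duplex with `total_score`, `firsthalf_score`, `max_run`,
#'   `max_run_2_12` filled in.
#' @export
score_duplex <- function(duplex, gu_weight_total = 0.5) {
  stopifnot(inherits(duplex, "MirnaDuplex"))
  p <- duplex$pairing
  L <- length(p)
  duplex$total_score <- sum(p == "MM") + gu_weight_total * sum(p == "GU")
  half <- seq_len(min(10L, L))
  duplex$firsthalf_score <- sum(p[half] == "MM") + 0.5 * sum(p[half] == "GU")
  duplex$max_run <- .max_mm_run(p)
  duplex$max_run_2_12 <- .max_mm_run(p[2:min(12L, L)])
  duplex
}

#' Duplex hybridization free energy (nearest-neighbor stacks)
#'
#' Sums Turner-style stack free energies over every two adjacent paired
#' positions (Watson-Crick or wobble); each contiguous internal mismatch
#' run adds a fixed destabilization penalty. The result is capped at 0
#' kcal/mol - a duplex with no stabilizing stacks has no hybridization
#' energy. A compact parameter set is embedded; the pass criterion uses
#' only the ratio of two such energies, which is insensitive to the
#' absolute parameter scale.
#'
#' @param duplex A [mirna_duplex()].
#' @return The free energy in kcal/mol (<= 0).
#' @export
duplex_mfe <- function(duplex) {
  stopifnot(inherits(duplex, "MirnaDuplex"))
  mv <- strsplit(duplex$mirna, "")[[1]]
  tv <- rev(strsplit(duplex$site, "")[[1]])
  paired <- duplex$pairing != "MM"
  if (!any(paired)) {
    warning("duplex has no paired positions; energy set to 0")
    return(0)
  }
  e <- 0
  for (i in seq_len(length(mv) - 1)) {
    if (paired[i] && paired[i + 1])
      e <- e + .stack_energy(mv[i], tv[i], mv[i + 1], tv[i + 1])
  }
  r <- rle(!paired)
  e <- e + .LOOP_PENALTY * sum(r$values)
  min(e, 0)
}

#' Free energy of the perfectly complementary duplex
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @return Free energy (kcal/mol, < 0 for any miRNA of length >= 2) of the
#'   miRNA hybridized to its exact Watson-Crick complement.
#' @export
perfect_mfe <- function(mirna) {
  mv <- strsplit(.to_rna(mirna, "miRNA"), "")[[1]]
  site <- paste(rev(unname(RNA_COMP[mv])), collapse = "")
  duplex_mfe(mirna_duplex(mirna, site))
}

#' Apply the four target-site criteria
#'
#' (a) total mismatch score <= `max_total_score` (default 4) and first-half
#' (miRNA positions 1-10) score <= `max_firsthalf_score` (default 2.5, G:U
#' counting 0.5); (b) longest consecutive mismatch run <= `max_mm_run`
#' (default 2) and longest run within positions 2-12 <= `max_mm_run_2_12`
#' (default 1); (c) miRNA positions 11 and 12 are perfect Watson-Crick
#' pairs (positions beyond a short duplex are vacuously satisfied); (d) the
#' site duplex retains at least `mfe_ratio_min` (default 0.75) of the
#' perfect-duplex hybridization energy, i.e. `mfe_site / mfe_perfect >=
#' 0.75` with both energies negative.
#'
#' @param duplex A [mirna_duplex()], scored or not.
#' @param max_total_score,max_firsthalf_score,max_mm_run,max_mm_run_2_12
#'   Criterion thresholds.
#' @param mfe_ratio_min Minimum retained energy fraction.
#' @param gu_weight_total Passed to [score_duplex()] if scores are missing.
#' @return The duplex with `mfe_site`, `mfe_perfect`, `mfe_ratio`,
#'   `criteria` (named logical vector `a`-`d`) and `passes` filled in.
#' @export
apply_criteria <- function(duplex, max_total_score = 4,
                           max_firsthalf_score = 2.5, max_mm_run = 2,
                           max_mm_run_2_12 = 1, mfe_ratio_min = 0.75,
                           gu_weight_total = 0.5) {
  stopifnot(inherits(duplex, "MirnaDuplex"))
  if (is.null(duplex$total_score))
    duplex <- score_duplex(duplex, gu_weight_total)
  L <- length(duplex$pairing)
  duplex$mfe_site <- duplex_mfe(duplex)
  duplex$mfe_perfect <- perfect_mfe(duplex$mirna)
  duplex$mfe_ratio <-
    if (duplex$mfe_perfect < 0)
      min(1, max(0, duplex$mfe_site / duplex$mfe_perfect))
    else 0
  crit <- c(
    a = duplex$total_score <= max_total_score &&
      duplex$firsthalf_score <= max_firsthalf_score,
    b = duplex$max_run <= max_mm_run &&
      duplex$max_run_2_12 <= max_mm_run_2_12,
    c = all(duplex$pairing[intersect(11:12, seq_len(L))] == "WC"),
    d = duplex$mfe_ratio >= mfe_ratio_min)
  duplex$criteria <- crit
  duplex$passes <- all(crit)
  duplex
}

#' @export
print.MirnaDuplex <- function(x, ...) {
  cat("MirnaDuplex", x$mirna_id, "->", x$target_id, "@", x$site_start, "\n")
  cat("  miRNA 5'-", x$mirna, "-3'\n", sep = "")
  cat("  pairing  ", paste(substr(x$pairing, 1, 1), collapse = ""), "\n")
  if (!is.null(x$passes))
    cat("  passes:", x$passes, " [",
        paste(names(x$criteria)[x$criteria], collapse = ""), "]\n")
  invisible(x)
}

#' Enumerate candidate sites of a miRNA on a transcript
#'
#' Scores every ungapped transcript window of miRNA length as an
#' antiparallel duplex and applies the four criteria.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript Transcript sequence (RNA or DNA letters), at least as
#'   long as the miRNA.
#' @param mirna_id,target_id Identifiers.
#' @param ... Passed to [apply_criteria()].
#' @return List of evaluated `MirnaDuplex` objects, one per window, in
#'   transcript order.
#' @export
candidate_sites <- function(mirna, transcript, mirna_id = "miRNA",
                            target_id = "target", ...) {
  mirna <- .to_rna(mirna, "miRNA")
  transcript <- .to_rna(transcript, "transcript")
  L <- nchar(mirna)
  Lt <- nchar(transcript)
  if (Lt < L) stop("transcript shorter than miRNA")
  lapply(seq_len(Lt - L + 1), function(i) {
    d <- mirna_duplex(mirna, substr(transcript, i, i + L - 1),
                      mirna_id = mirna_id, target_id = target_id,
                      site_start = i - 1L)
    apply_criteria(d, ...)
  })
}

.duplex_row <- function(d) {
  data.frame(mirna_id = d$mirna_id, target_id = d$target_id,
             site_start = d$site_start,
             site_end = d$site_start + length(d$pairing),
             total_score = d$total_score,
             firsthalf_score = d$firsthalf_score,
             max_run = d$max_run, max_run_2_12 = d$max_run_2_12,
             mfe_site = d$mfe_site, mfe_perfect = d$mfe_perfect,
             mfe_ratio = d$mfe_ratio,
             crit_a = d$criteria[["a"]], crit_b = d$criteria[["b"]],
             crit_c = d$criteria[["c"]], crit_d = d$criteria[["d"]],
             passes = d$passes, stringsAsFactors = FALSE)
}

#' Predict miRNA targets over sequence collections
#'
#' Evaluates every miRNA against every window of every transcript and
#' returns the sites passing all four criteria (or all evaluated sites with
#' `all_sites = TRUE`), in deterministic (miRNA id, transcript id,
#' position) order, independent of input record order.
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3').
#' @param transcripts Named character vector of transcript sequences.
#' @param all_sites Return failing sites too? Default `FALSE`.
#' @param ... Criterion thresholds, passed to [apply_criteria()].
#' @return Data frame, one row per (miRNA, transcript, site) with scores,
#'   energies and per-criterion flags.
#' @export
predict_targets <- function(mirnas, transcripts, all_sites = FALSE, ...) {
  if (!length(mirnas) || !length(transcripts))
    stop("empty input")
  if (is.null(names(mirnas)) || is.null(names(transcripts)))
    stop("`mirnas` and `transcripts` must be named")
  rows <- list()
  for (mi in sort(names(mirnas))) {
    for (tx in sort(names(transcripts))) {
      if (nchar(transcripts[[tx]]) < nchar(mirnas[[mi]])) next
      for (d in candidate_sites(mirnas[[mi]], transcripts[[tx]],
                                mirna_id = mi, target_id = tx, ...)) {
        if (all_sites || d$passes) rows[[length(rows) + 1]] <- .duplex_row(d)
      }
    }
  }
  if (!length(rows)) {
    out <- .duplex_row(apply_criteria(mirna_duplex("AA", "UU")))[0, ]
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$mirna_id, out$target_id, out$site_start), ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read / write sequence collections as FASTA
#'
#' Thin wrappers used for miRNA, transcript and promoter files; sequences
#' are returned as a named character vector with the first whitespace-
#' delimited token of each header as the name.
#'
#' @param path FASTA path.
#' @return Named character vector (read); the input invisibly (write).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' @rdname read_fasta
#' @param x Named character vector of sequences.
#' @export
write_fasta <- function(x, path) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path)
  invisible(x)
}
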