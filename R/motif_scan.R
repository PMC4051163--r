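# IUPAC degenerate DNA alphabet: code -> set of concrete bases it matches.
# In the scanned sequence only A, C, G, T and N are allowed; a sequence N is
# matched by nothing except the pattern letter N.
IUPAC_DNA <- c(A = "A", C = "C", G = "G", T = "T",
               M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT",
               V = "ACG", H = "ACT", D = "AGT", B = "CGT", N = "ACGT")

# complement of each IUPAC code (for reverse-complementing patterns)
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
                      V = "B", H = "D", D = "H", B = "V", N = "N")

#' Promoter length bins
#'
#' Labels of the promoter-length strata used for surrogate sampling:
#' `<500`, `500-1000`, `1000-2000`, `2000-3000` and `>=3000` bp. The last,
#' open-ended bin completes the partition so every promoter falls in exactly
#' one stratum.
#' @export
PROMOTER_BINS <- c("<500", "500-1000", "1000-2000", "2000-3000", ">=3000")

.bin_lengths <- function(len) {
  cut(len, breaks = c(0, 500, 1000, 2000, 3000, Inf),
      labels = PROMOTER_BINS, right = FALSE)
}

.check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid letter(s) in ", what, " (allowed: A,C,G,T,N): entry ",
         which(bad)[1])
  invisible(seqs)
}

#' Construct an IUPAC motif
#'
#' @param motif_id Motif identifier (the factor/element name).
#' @param pattern Non-empty IUPAC DNA string (A, C, G, T plus the degenerate
#'   codes M, R, W, S, Y, K, V, H, D, B, N).
#' @param keywords Free-text annotation keywords.
#' @return An object of class `Motif`.
#' @export
motif <- function(motif_id, pattern, keywords = "") {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stop("empty motif pattern")
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(IUPAC_DNA))
  if (length(bad))
    stop("invalid IUPAC letter(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  structure(list(motif_id = as.character(motif_id), pattern = pattern,
                 keywords = as.character(keywords)),
            class = "Motif")
}

# normalize motif input (Motif, pattern string(s), or library data frame)
# to a data frame motif_id / pattern / keywords
.as_motif_table <- function(motifs) {
  if (inherits(motifs, "Motif"))
    motifs <- list(motifs)
  if (is.character(motifs))
    motifs <- lapply(seq_along(motifs), function(i)
      motif(names(motifs)[i] %||% motifs[i], motifs[i]))
  if (is.list(motifs) && !is.data.frame(motifs)) {
    motifs <- do.call(rbind, lapply(motifs, function(m) {
      stopifnot(inherits(m, "Motif"))
      data.frame(motif_id = m$motif_id, pattern = m$pattern,
                 keywords = m$keywords, stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(motifs),
            all(c("motif_id", "pattern") %in% names(motifs)))
  if (is.null(motifs$keywords)) motifs$keywords <- ""
  if (anyDuplicated(motifs$motif_id))
    stop("duplicate motif ids in library")
  for (p in motifs$pattern) motif("x", p)  # validates letters
  motifs[, c("motif_id", "pattern", "keywords")]
}

#' Read a PLACE-style motif library
#'
#' Tab-separated file with a header and columns `motif_id`, `pattern`
#' (IUPAC), `keywords`.
#'
#' @param path TSV path.
#' @return Data frame `motif_id` / `pattern` / `keywords`.
#' @export
read_motif_library <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed motif library: ", path)
  names(df)[1:2] <- c("motif_id", "pattern")
  if (ncol(df) >= 3) names(df)[3] <- "keywords"
  .as_motif_table(df)
}

#' Promoter set with length stratification
#'
#' @param sequences Named character vector of promoter DNA sequences
#'   (A, C, G, T, N; lower case accepted). Names must be unique.
#' @return A `PromoterSet`: list with `records` (named upper-case sequences)
#'   and `length_bin` (named factor over [PROMOTER_BINS]).
#' @export
promoter_set <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("promoter sequences need unique names")
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("empty promoter sequence")
  .check_dna(sequences, "promoter")
  bins <- .bin_lengths(nchar(sequences))
  names(bins) <- names(sequences)
  structure(list(records = sequences, length_bin = bins),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat("PromoterSet:", length(x$records), "promoters; bins:",
      paste(sprintf("%s=%d", levels(x$length_bin), table(x$length_bin)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write promoters as FASTA
#'
#' @param path FASTA path.
#' @return A `PromoterSet` (read); the input invisibly (write).
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  promoter_set(seqs)
}

#' @rdname read_promoters
#' @param x A `PromoterSet`.
#' @export
write_promoters <- function(x, path) {
  stopifnot(inherits(x, "PromoterSet"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x$records), path)
  invisible(x)
}

# IUPAC pattern -> perl regex; sequence N is matched only by pattern N
.iupac_regex <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste0(vapply(letters, function(l) {
    set <- IUPAC_DNA[[l]]
    if (l == "N") "[ACGTN]"
    else if (nchar(set) == 1) set
    else paste0("[", set, "]")
  }, character(1)), collapse = "")
}

.revcomp_pattern <- function(pattern) {
  letters <- rev(strsplit(toupper(pattern), "")[[1]])
  paste0(unname(IUPAC_COMPLEMENT[letters]), collapse = "")
}

.scan_starts0 <- function(seq, pattern) {
  # zero-width lookahead reports every overlapping match position
  m <- gregexpr(paste0("(?=", .iupac_regex(pattern), ")"), seq,
                perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports the 0-based start of every (possibly overlapping) window matching
#' the pattern. An `N` in the sequence is matched by nothing except the
#' pattern letter `N`. With `both_strands = TRUE` the reverse-complement of
#' the pattern is also scanned and its matches reported on the forward
#' coordinate system with strand `"-"`.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param motif A `Motif`, or an IUPAC pattern string.
#' @param both_strands Scan the reverse strand too? Default `FALSE`
#'   (plain PLACE-style forward scan).
#' @return Data frame with columns `start` (0-based) and `strand`, ordered by
#'   start then strand.
#' @export
scan_sequence <- function(seq, motif, both_strands = FALSE) {
  if (inherits(motif, "Motif")) motif <- motif$pattern
  motif(motif_id = "x", pattern = motif) -> m  # validates the pattern
  seq <- toupper(seq)
  .check_dna(seq, "sequence")
  fw <- .scan_starts0(seq, m$pattern)
  out <- data.frame(start = fw, strand = rep("+", length(fw)),
                    stringsAsFactors = FALSE)
  if (both_strands) {
    rv <- .scan_starts0(seq, .revcomp_pattern(m$pattern))
    out <- rbind(out, data.frame(start = rv,
                                 strand = rep("-", length(rv)),
                                 stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-promoter motif occurrence matrix
#'
#' Occurrences are counted per promoter with overlaps included; this matrix
#' is the unit the surrogate-resampling enrichment sums over, and can be
#' precomputed once and passed to [zfm_enrichment()] when many foreground
#' sets are tested against the same genome set.
#'
#' @param promoters A `PromoterSet`.
#' @param motifs Motif library (data frame / `Motif` / pattern strings).
#' @param both_strands Count reverse-strand matches too?
#' @return Integer matrix, promoters x motifs.
#' @export
promoter_motif_count_matrix <- function(promoters, motifs,
                                        both_strands = FALSE) {
  stopifnot(inherits(promoters, "PromoterSet"))
  motifs <- .as_motif_table(motifs)
  out <- vapply(motifs$pattern, function(p) {
    vapply(promoters$records, function(s) {
      n <- length(.scan_starts0(s, p))
      if (both_strands) n <- n + length(.scan_starts0(s, .revcomp_pattern(p)))
      as.integer(n)
    }, integer(1))
  }, integer(length(promoters$records)))
  out <- matrix(out, nrow = length(promoters$records),
                dimnames = list(names(promoters$records), motifs$motif_id))
  out
}

#' Total motif occurrence counts over a promoter set
#'
#' `N_motif` = total number of occurrences summed over all promoters
#' (overlapping occurrences all counted).
#'
#' @inheritParams promoter_motif_count_matrix
#' @return Named integer vector, one entry per motif.
#' @export
motif_counts <- function(promoters, motifs, both_strands = FALSE) {
  if (!length(promoters$records)) {
    motifs <- .as_motif_table(motifs)
    return(stats::setNames(integer(nrow(motifs)), motifs$motif_id))
  }
  colSums(promoter_motif_count_matrix(promoters, motifs, both_strands))
}
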