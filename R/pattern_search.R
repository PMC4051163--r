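#' Qualitative expression pattern query
#'
#' Encodes a user-described pattern over ordered conditions: high
#' (up-regulated) = +1, even = 0, low (down-regulated) = -1. At least two
#' conditions are required and the levels must not all be equal (a constant
#' pattern has no defined correlation with anything).
#'
#' @param levels Named numeric vector (or named character with values
#'   `"high"`/`"even"`/`"low"`) over condition labels.
#' @return A named numeric vector of class `PatternQuery`.
#' @export
pattern_query <- function(levels) {
  if (is.character(levels)) {
    map <- c(high = 1, even = 0, low = -1, `1` = 1, `0` = 0, `-1` = -1)
    bad <- setdiff(tolower(levels), names(map))
    if (length(bad)) stop("unknown pattern level(s): ",
                          paste(unique(bad), collapse = ", "))
    levels <- stats::setNames(unname(map[tolower(levels)]), names(levels))
  }
  if (is.null(names(levels)) || anyDuplicated(names(levels)))
    stop("pattern query needs unique condition names")
  if (!all(levels %in% c(-1, 0, 1)))
    stop("pattern levels must be -1 (low), 0 (even) or +1 (high)")
  if (length(levels) < 2) stop("pattern query needs >= 2 conditions")
  if (length(unique(levels)) == 1)
    stop("all-equal pattern levels: correlation undefined")
  structure(as.numeric(levels), names = names(levels),
            class = "PatternQuery")
}

#' Search ZFE profiles by expression pattern
#'
#' Correlates the query vector with each eligible probe's ZFE over the
#' query's conditions (conditions absent from the query are ignored, not
#' imputed) and returns the probes with Pearson correlation at least
#' `r_min` (default 0.7), sorted by descending correlation with a
#' lexicographic tie-break. Ineligible (all-zero) probes and probes with a
#' constant ZFE over the selected conditions are skipped.
#'
#' @param profile A `ZfeProfile`.
#' @param query A [pattern_query()] (or a named vector coercible to one).
#' @param r_min Minimum correlation to report.
#' @return Data frame `probe_id`, `pcc`.
#' @export
pattern_search <- function(profile, query, r_min = 0.7) {
  stopifnot(inherits(profile, "ZfeProfile"))
  if (!inherits(query, "PatternQuery")) query <- pattern_query(query)
  conds <- names(query)
  miss <- setdiff(conds, profile$conditions)
  if (length(miss))
    stop("query conditions absent from profile: ",
         paste(miss, collapse = ", "))
  z <- profile$zfe[profile$eligible, conds, drop = FALSE]
  if (!nrow(z))
    return(data.frame(probe_id = character(), pcc = numeric(),
                      stringsAsFactors = FALSE))
  ok <- apply(z, 1, stats::sd) > 0
  z <- z[ok, , drop = FALSE]
  q <- as.numeric(query)
  r <- as.vector(stats::cor(t(z), q))
  names(r) <- rownames(z)
  r <- r[r >= r_min]
  r <- r[order(-r, names(r))]
  data.frame(probe_id = names(r), pcc = unname(r),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tissue/time-specific probe retrieval
#'
#' Returns the eligible probes whose ZFE in the given condition is at least
#' `z_min`, sorted by descending ZFE (lexicographic tie-break).
#'
#' @param profile A `ZfeProfile`.
#' @param condition Condition label present in the profile.
#' @param z_min Minimum ZFE.
#' @return Data frame `probe_id`, `zfe`.
#' @export
tissue_specific <- function(profile, condition, z_min) {
  stopifnot(inherits(profile, "ZfeProfile"))
  if (!condition %in% profile$conditions)
    stop("unknown condition: ", condition)
  z <- profile$zfe[profile$eligible, condition]
  z <- z[z >= z_min]
  z <- z[order(-z, names(z))]
  data.frame(probe_id = names(z), zfe = unname(z),
             stringsAsFactors = FALSE, row.names = NULL)
}
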