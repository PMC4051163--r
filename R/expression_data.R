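#' Expression matrix with replicate grouping
#'
#' Container for a probe-by-sample table of non-negative intensities or read
#' counts, together with the sample-to-condition grouping, the experiment
#' design mode and the per-experiment Average Signal `A` used downstream by
#' the ZFE eligibility filter.
#'
#' @param values Numeric matrix, probes in rows (unique row names), samples in
#'   columns (unique column names). All values must be finite and >= 0.
#' @param grouping Named character vector mapping sample id to condition
#'   label. Every column of `values` must appear in `names(grouping)`.
#' @param mode `"profile"` for multi-condition profiling designs (ZFE
#'   formula standardizes across conditions) or `"treatment_control"` for
#'   paired designs (ZFE is a log2 treatment/control ratio).
#' @param average_signal_A Non-negative scalar: the per-experiment Average
#'   Signal produced by the array scaling software, used as the intensity
#'   eligibility threshold.
#' @param control_labels Character vector of condition labels that are
#'   controls. Required (non-empty) iff `mode = "treatment_control"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `grouping`, `mode`, `average_signal_A`, `control_labels`.
#' @export
expression_matrix <- function(values, grouping,
                              mode = c("profile", "treatment_control"),
                              average_signal_A = 0,
                              control_labels = character()) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate probe ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("non-finite expression values")
  if (any(values < 0))
    stop("negative expression values are not allowed")
  samples <- colnames(values)
  miss <- setdiff(samples, names(grouping))
  if (length(miss))
    stop("samples missing from grouping: ", paste(miss, collapse = ", "))
  grouping <- grouping[samples]
  if (mode == "treatment_control") {
    if (!length(control_labels))
      stop("treatment_control mode requires non-empty `control_labels`")
    bad <- setdiff(control_labels, grouping)
    if (length(bad))
      stop("control_labels not present in grouping: ",
           paste(bad, collapse = ", "))
  } else if (length(control_labels)) {
    stop("`control_labels` only apply in treatment_control mode")
  }
  if (!is.numeric(average_signal_A) || length(average_signal_A) != 1 ||
      !is.finite(average_signal_A) || average_signal_A < 0)
    stop("`average_signal_A` must be a single non-negative number")
  structure(
    list(values = values, grouping = grouping, mode = mode,
         average_signal_A = average_signal_A,
         control_labels = as.character(control_labels)),
    class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples;", length(unique(x$grouping)), "conditions; mode =",
      x$mode, "\n")
  invisible(x)
}

#' Read an expression matrix and its replicate-grouping sidecar
#'
#' The matrix is a tab-separated file whose first column holds probe/gene ids
#' and whose header row holds sample ids. The sidecar is a tab-separated file
#' with a header and columns `sample`, `condition` and optionally `control`
#' (truthy values mark control conditions).
#'
#' @param path Path to the expression TSV.
#' @param grouping_path Path to the grouping sidecar TSV.
#' @inheritParams expression_matrix
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, grouping_path,
                                   mode = c("profile", "treatment_control"),
                                   average_signal_A = 0) {
  mode <- match.arg(mode)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2)
    stop("malformed expression TSV (need a probe column and >= 1 sample): ",
         path)
  probes <- raw[[1]]
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    stop("duplicate probe ids in ", path, ": ", paste(dup, collapse = ", "))
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(probes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & nzchar(col))
    if (length(bad))
      stop("non-numeric value '", col[bad[1]], "' at probe '",
           probes[bad[1]], "', sample '", samples[j], "'")
    if (anyNA(num))
      stop("missing value at probe '", probes[which(is.na(num))[1]],
           "', sample '", samples[j], "'")
    vals[, j] <- num
  }
  grp <- utils::read.delim(grouping_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(grp) < 2)
    stop("malformed grouping sidecar (need sample and condition columns): ",
         grouping_path)
  grouping <- stats::setNames(grp[[2]], grp[[1]])
  control_labels <- character()
  if (ncol(grp) >= 3) {
    flag <- tolower(grp[[3]]) %in% c("1", "true", "yes", "control")
    control_labels <- unique(grp[[2]][flag])
  }
  if (mode == "profile") control_labels <- character()
  expression_matrix(vals, grouping, mode = mode,
                    average_signal_A = average_signal_A,
                    control_labels = control_labels)
}

#' Write an expression matrix (and optionally its grouping sidecar)
#'
#' Values are written in full double precision (up to 15 significant digits)
#' so that a write/read round trip reproduces them to that precision.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param grouping_path Optional sidecar path; written when non-`NULL`.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, path, grouping_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(probe_id = rownames(x$values),
                   format(x$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(grouping_path)) {
    gdf <- data.frame(sample = names(x$grouping),
                      condition = unname(x$grouping),
                      control = as.integer(unname(x$grouping) %in%
                                             x$control_labels))
    utils::write.table(gdf, grouping_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Summarize replicates per condition
#'
#' For every probe and condition computes the arithmetic mean of the
#' replicate intensities, the sample standard deviation (divisor `n - 1`,
#' defined as 0 when a condition has a single replicate) and the standard
#' error `stdev / sqrt(n)`.
#'
#' @param x An `ExpressionMatrix`.
#' @return An object of class `ReplicateSummary`: list with probe-by-condition
#'   matrices `mean`, `stdev`, `stderr`, the per-condition replicate counts
#'   `n`, the condition order, and the experiment metadata carried over from
#'   `x` (`mode`, `average_signal_A`, `control_labels`).
#' @export
summarize_replicates <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  conds <- unique(unname(x$grouping))
  if (!length(conds)) stop("no conditions in grouping")
  v <- x$values
  n <- vapply(conds, function(cc) sum(x$grouping == cc), integer(1))
  if (any(n < 1)) stop("condition without samples: ",
                       paste(conds[n < 1], collapse = ", "))
  mean_m <- matrix(vapply(conds, function(cc) {
    rowMeans(v[, names(x$grouping)[x$grouping == cc], drop = FALSE])
  }, numeric(nrow(v))), nrow(v), length(conds))
  sd_m <- matrix(vapply(conds, function(cc) {
    cols <- names(x$grouping)[x$grouping == cc]
    if (length(cols) == 1) rep(0, nrow(v))
    else apply(v[, cols, drop = FALSE], 1, stats::sd)
  }, numeric(nrow(v))), nrow(v), length(conds))
  dimnames(mean_m) <- dimnames(sd_m) <- list(rownames(v), conds)
  se_m <- sweep(sd_m, 2, sqrt(n), "/")
  structure(
    list(mean = mean_m, stdev = sd_m, stderr = se_m,
         n = stats::setNames(n, conds), conditions = conds,
         mode = x$mode, average_signal_A = x$average_signal_A,
         control_labels = x$control_labels),
    class = "ReplicateSummary")
}

#' @export
print.ReplicateSummary <- function(x, ...) {
  cat("ReplicateSummary:", nrow(x$mean), "probes x", length(x$conditions),
      "conditions (replicates:", paste(x$n, collapse = ", "), ")\n")
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of gene model per million mapped reads:
#' `RPKM = 1e9 * C / (N * L)`.
#'
#' @param C Mappable reads falling in the gene (>= 0). Vectorized.
#' @param N Total mappable reads in the experiment (> 0).
#' @param L Gene length in base pairs (> 0).
#' @return Numeric vector of RPKM values.
#' @export
rpkm <- function(C, N, L) {
  if (any(!is.finite(C)) || any(C < 0)) stop("`C` must be >= 0")
  if (any(!is.finite(N)) || any(N <= 0)) stop("`N` must be > 0")
  if (any(!is.finite(L)) || any(L <= 0)) stop("`L` must be > 0")
  1e9 * C / (N * L)
}

#' Log2 display transform for raw mapped-read counts
#'
#' `n = log2(N + 1)`, the transform applied to per-position read counts
#' before display.
#'
#' @param N Raw mapped-read count(s), >= 0.
#' @return `log2(N + 1)`.
#' @export
read_display_transform <- function(N) {
  if (any(!is.finite(N)) || any(N < 0)) stop("`N` must be >= 0")
  log2(N + 1)
}
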