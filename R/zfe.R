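#' ZFE eligibility filter
#'
#' A probe is eligible for ZFE computation when at least one of its condition
#' means exceeds the experiment's Average Signal `A` and the ratio of its
#' largest to smallest condition mean is at least `ratio_min`. To keep the
#' ratio defined when the smallest mean is (near) zero, the denominator is
#' floored at `intensity_floor`; scaled intensities that close to zero are
#' background noise. Ineligible probes receive ZFE = 0 everywhere.
#'
#' @param summary A [summarize_replicates()] result.
#' @param A Average Signal threshold; defaults to the value carried in
#'   `summary`.
#' @param ratio_min Minimum max/min ratio of condition means (default 2).
#' @param intensity_floor Floor applied to the smallest mean in the ratio
#'   (default 1).
#' @return Named logical vector, one entry per probe.
#' @export
zfe_eligibility <- function(summary, A = summary$average_signal_A,
                            ratio_min = 2, intensity_floor = 1) {
  stopifnot(inherits(summary, "ReplicateSummary"))
  if (!nrow(summary$mean)) stop("empty summary")
  mx <- apply(summary$mean, 1, max)
  mn <- pmax(apply(summary$mean, 1, min), intensity_floor)
  mx > A & (mx / mn) >= ratio_min
}

.new_zfe_profile <- function(zfe, eligible) {
  structure(list(zfe = zfe, eligible = eligible,
                 conditions = colnames(zfe)),
            class = "ZfeProfile")
}

#' @export
print.ZfeProfile <- function(x, ...) {
  cat("ZfeProfile:", nrow(x$zfe), "probes x", length(x$conditions),
      "conditions;", sum(x$eligible), "eligible\n")
  invisible(x)
}

#' ZFE for profiling experiments (across-condition standardization)
#'
#' For each eligible probe the condition means are standardized:
#' `ZFE_c = (xbar_c - mean(xbar)) / sd(xbar)`, where the mean and standard
#' deviation (divisor `n - 1`) are taken across the condition means of that
#' probe. Ineligible probes get an all-zero row.
#'
#' @inheritParams zfe_eligibility
#' @return A `ZfeProfile`: list with probe-by-condition matrix `zfe`, logical
#'   vector `eligible` and the condition order.
#' @export
zfe_profile <- function(summary, A = summary$average_signal_A,
                        ratio_min = 2, intensity_floor = 1) {
  stopifnot(inherits(summary, "ReplicateSummary"))
  if (length(summary$conditions) < 2)
    stop("ZFE profile standardization needs >= 2 conditions")
  elig <- zfe_eligibility(summary, A, ratio_min, intensity_floor)
  z <- matrix(0, nrow(summary$mean), ncol(summary$mean),
              dimnames = dimnames(summary$mean))
  if (any(elig)) {
    m <- summary$mean[elig, , drop = FALSE]
    rm <- rowMeans(m)
    rs <- apply(m, 1, stats::sd)
    # the >= 2 fold-change clause guarantees variation across conditions
    stopifnot(all(rs > 0))
    z[elig, ] <- (m - rm) / rs
  }
  .new_zfe_profile(z, elig)
}

#' ZFE for treatment/control experiments (log2 fold change)
#'
#' For each eligible probe and each treatment condition,
#' `ZFE = log2(xbar_T / xbar_C)` against the paired control condition.
#' A zero control mean for an eligible probe is substituted with
#' `intensity_floor` and recorded (attribute `"floor_substitutions"`),
#' with a warning.
#'
#' @inheritParams zfe_eligibility
#' @param control_map Named character vector pairing each treatment condition
#'   (names) with its control condition (values). Both must be conditions of
#'   `summary`.
#' @return A `ZfeProfile` whose columns are the treatment conditions.
#' @export
zfe_treatment_control <- function(summary, control_map,
                                  A = summary$average_signal_A,
                                  ratio_min = 2, intensity_floor = 1) {
  stopifnot(inherits(summary, "ReplicateSummary"))
  if (!length(control_map) || is.null(names(control_map)))
    stop("`control_map` must be a named vector treatment -> control")
  bad <- setdiff(c(names(control_map), unname(control_map)),
                 summary$conditions)
  if (length(bad))
    stop("conditions absent from summary: ", paste(bad, collapse = ", "))
  elig <- zfe_eligibility(summary, A, ratio_min, intensity_floor)
  trts <- names(control_map)
  z <- matrix(0, nrow(summary$mean), length(trts),
              dimnames = list(rownames(summary$mean), trts))
  subs <- data.frame(probe_id = character(), condition = character(),
                     stringsAsFactors = FALSE)
  for (t in trts) {
    mT <- summary$mean[, t]
    mC <- summary$mean[, control_map[[t]]]
    zero <- elig & mC == 0
    if (any(zero)) {
      subs <- rbind(subs, data.frame(probe_id = names(which(zero)),
                                     condition = t,
                                     stringsAsFactors = FALSE))
      mC[zero] <- intensity_floor
    }
    z[elig, t] <- log2(mT[elig] / mC[elig])
  }
  if (nrow(subs))
    warning(nrow(subs), " zero control mean(s) replaced by the intensity ",
            "floor; see attr(., 'floor_substitutions')")
  out <- .new_zfe_profile(z, elig)
  attr(out, "floor_substitutions") <- subs
  out
}

#' Write / read a ZFE profile as TSV
#'
#' Columns: `probe_id`, `eligible` (0/1), then one column per condition.
#'
#' @param profile A `ZfeProfile`.
#' @param path TSV path.
#' @return `profile` invisibly (write); a `ZfeProfile` (read).
#' @export
write_zfe_profile <- function(profile, path) {
  stopifnot(inherits(profile, "ZfeProfile"))
  df <- data.frame(probe_id = rownames(profile$zfe),
                   eligible = as.integer(profile$eligible),
                   format(profile$zfe, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' @rdname write_zfe_profile
#' @export
read_zfe_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("malformed ZFE profile TSV: ", path)
  z <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(z) <- df[[1]]
  storage.mode(z) <- "double"
  .new_zfe_profile(z, stats::setNames(df[[2]] != 0, df[[1]]))
}
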