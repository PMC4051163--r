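#' Simulation configuration
#'
#' One validated configuration object drives all three generators
#' ([simulate_expression()], [simulate_promoters()],
#' [simulate_mirna_duplexes()]). Every generator is bit-reproducible from
#' `(seed, config)`: each call seeds a local RNG and restores the caller's
#' RNG state afterwards.
#'
#' Expression fields: `n_genes`, `n_conditions`, `n_replicates`,
#' `noise_sigma` (log-scale replicate noise, default 0.2), `baseline_sigma`
#' (log-scale between-gene spread), `intensity_scale` (median intensity,
#' default 500 matching a TGT-500 scaled array), `average_signal_A`,
#' `module_specs` (list of `list(size, loading)` co-expression modules
#' driven by shared per-condition latent factors), `pattern_spec`
#' (`list(levels, n_probes, amplitude)` probes following a qualitative
#' pattern), `mode` and, for treatment/control designs,
#' `n_treatment_conditions` and `treatment_spec` (`list(n_probes, fold)`).
#'
#' Promoter fields: `n_promoters`, `bin_proportions` (over the five length
#' bins, summing to 1; per-bin counts are deterministic largest-remainder
#' rounding), `base_probs` (background composition), `plant_pattern`
#' (IUPAC), `plant_rate` and `plant_rate_unit` (`"per_promoter"`:
#' `floor(rate)` instances plus a Bernoulli fractional instance;
#' `"per_bp"`: Poisson with mean `rate * length`).
#'
#' Duplex fields: `mirna_length` (default 21), `flank_length`,
#' `duplex_specs` (list of `list(defects = data.frame(position, state))`
#' with states `"MM"`/`"GU"`).
#'
#' @param seed Integer seed.
#' @param ... Fields overriding the defaults listed above.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # expression
    n_genes = 200, n_conditions = 8, n_replicates = 3,
    noise_sigma = 0.2, baseline_sigma = 0.5,
    intensity_scale = 500, average_signal_A = 100,
    module_specs = list(), pattern_spec = NULL,
    mode = "profile", n_treatment_conditions = 4,
    treatment_spec = NULL,
    # promoters
    n_promoters = 200,
    bin_proportions = c(0.1, 0.25, 0.3, 0.25, 0.1),
    base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    plant_pattern = NULL, plant_rate = 0,
    plant_rate_unit = "per_promoter",
    # duplexes
    mirna_length = 21, flank_length = 20, duplex_specs = list())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  with(cfg, {
    stopifnot(length(seed) == 1, is.finite(seed),
              n_genes >= 1, n_conditions >= 1, n_replicates >= 1,
              noise_sigma >= 0, baseline_sigma >= 0, intensity_scale > 0,
              average_signal_A >= 0, n_promoters >= 0,
              length(bin_proportions) == 5, all(bin_proportions >= 0),
              abs(sum(bin_proportions) - 1) < 1e-8,
              all(base_probs >= 0), abs(sum(base_probs) - 1) < 1e-8,
              plant_rate >= 0, mirna_length >= 2, flank_length >= 0)
    if (!mode %in% c("profile", "treatment_control"))
      stop("mode must be 'profile' or 'treatment_control'")
    if (plant_rate > 0 && is.null(plant_pattern))
      stop("plant_rate > 0 requires plant_pattern")
    if (!plant_rate_unit %in% c("per_promoter", "per_bp"))
      stop("plant_rate_unit must be 'per_promoter' or 'per_bp'")
    for (m in module_specs)
      stopifnot(m$size >= 0, is.numeric(m$loading))
  })
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a replicated expression matrix
#'
#' Log-normal background intensities centered on `intensity_scale`;
#' co-expression modules are planted through shared per-condition latent
#' factors, pattern-following probes through an additive log-scale term
#' proportional to the query levels, and treatment effects (in
#' treatment/control mode) as a multiplicative fold change on the
#' treatment conditions. Gene ids are `g0001`, ... with modules first, then
#' pattern probes, then null genes; the planted assignments are recorded in
#' the `"truth"` attribute. In treatment/control mode a `"control_map"`
#' attribute pairs each treatment condition with its matched control.
#'
#' @param config A [simulation_config()].
#' @return An [expression_matrix()].
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    tc <- config$mode == "treatment_control"
    if (tc) {
      k <- config$n_treatment_conditions
      conds <- c(sprintf("trt%02d", seq_len(k)),
                 sprintf("ctl%02d", seq_len(k)))
      control_labels <- sprintf("ctl%02d", seq_len(k))
      control_map <- stats::setNames(control_labels,
                                     sprintf("trt%02d", seq_len(k)))
    } else {
      conds <- sprintf("cond%02d", seq_len(config$n_conditions))
      control_labels <- character()
      control_map <- NULL
    }
    C <- length(conds)
    samples <- as.vector(t(outer(conds, seq_len(config$n_replicates),
                                 function(a, b) paste0(a, "_r", b))))
    grouping <- stats::setNames(rep(conds, each = config$n_replicates),
                                samples)
    G <- config$n_genes
    ids <- sprintf("g%04d", seq_len(G))
    base <- stats::rnorm(G, log(config$intensity_scale),
                         config$baseline_sigma)
    li <- matrix(base, G, length(samples)) +
      matrix(stats::rnorm(G * length(samples), 0, config$noise_sigma),
             G, length(samples))
    dimnames(li) <- list(ids, samples)

    next_gene <- 1L
    truth <- list(modules = list(), pattern_probes = character(),
                  treatment_probes = character())
    for (m in config$module_specs) {
      if (m$size < 1) next
      gi <- next_gene:(next_gene + m$size - 1)
      if (max(gi) > G) stop("module_specs exceed n_genes")
      f <- stats::rnorm(C)
      for (ci in seq_len(C)) {
        cols <- which(grouping == conds[ci])
        li[gi, cols] <- li[gi, cols] + m$loading * f[ci]
      }
      truth$modules <- c(truth$modules, list(ids[gi]))
      next_gene <- next_gene + m$size
    }
    ps <- config$pattern_spec
    if (!is.null(ps) && ps$n_probes > 0) {
      stopifnot(length(ps$levels) == C)
      amp <- ps$amplitude %||% 0.7
      gi <- next_gene:(next_gene + ps$n_probes - 1)
      if (max(gi) > G) stop("pattern_spec exceeds n_genes")
      for (ci in seq_len(C)) {
        cols <- which(grouping == conds[ci])
        li[gi, cols] <- li[gi, cols] + amp * ps$levels[ci]
      }
      truth$pattern_probes <- ids[gi]
      next_gene <- next_gene + ps$n_probes
    }
    ts <- config$treatment_spec
    if (tc && !is.null(ts) && ts$n_probes > 0) {
      gi <- next_gene:(next_gene + ts$n_probes - 1)
      if (max(gi) > G) stop("treatment_spec exceeds n_genes")
      cols <- which(grouping %in% names(control_map))
      li[gi, cols] <- li[gi, cols] + log(ts$fold %||% 4)
      truth$treatment_probes <- ids[gi]
    }
    x <- expression_matrix(exp(li), grouping,
                           mode = config$mode,
                           average_signal_A = config$average_signal_A,
                           control_labels = control_labels)
    attr(x, "truth") <- truth
    attr(x, "control_map") <- control_map
    x
  })
}

# deterministic largest-remainder apportionment of n into proportions
.apportion <- function(n, props) {
  raw <- props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(-(raw - cnt), seq_along(props))[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  as.integer(cnt)
}

# one concrete instantiation of an IUPAC pattern
.instantiate_pattern <- function(pattern) {
  letters <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(letters, function(l) {
    set <- strsplit(IUPAC_DNA[[l]], "")[[1]]
    set[sample.int(length(set), 1)]
  }, character(1)), collapse = "")
}

#' Simulate a promoter set with planted motifs
#'
#' Lengths are stratified deterministically over the five length bins
#' (largest-remainder counts, uniform length within each bin, with the
#' open-ended bin drawn from 3000-3999 bp); bases are i.i.d. from
#' `base_probs`. Motif instances (concrete realizations of the IUPAC
#' pattern) are planted at uniform positions without overlapping earlier
#' plants; a motif longer than its promoter is skipped with a warning.
#' Planted positions are recorded in the `"planted"` attribute.
#'
#' @param config A [simulation_config()].
#' @return A [promoter_set()].
#' @export
simulate_promoters <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withr::with_seed(config$seed, {
    n <- config$n_promoters
    cnt <- .apportion(n, config$bin_proportions)
    ranges <- list(c(100, 499), c(500, 999), c(1000, 1999),
                   c(2000, 2999), c(3000, 3999))
    lens <- unlist(lapply(seq_along(cnt), function(b) {
      if (cnt[b] == 0) return(integer(0))
      sample(ranges[[b]][1]:ranges[[b]][2], cnt[b], replace = TRUE)
    }))
    bases <- names(config$base_probs)
    seqs <- vapply(lens, function(L)
      paste(sample(bases, L, replace = TRUE, prob = config$base_probs),
            collapse = ""), character(1))
    names(seqs) <- sprintf("prom%04d", seq_along(seqs))
    planted <- data.frame(promoter = character(), start = integer(),
                          stringsAsFactors = FALSE)
    pat <- config$plant_pattern
    if (!is.null(pat) && config$plant_rate > 0) {
      plen <- nchar(pat)
      for (i in seq_along(seqs)) {
        L <- lens[i]
        k <- if (config$plant_rate_unit == "per_bp")
          stats::rpois(1, config$plant_rate * L)
        else
          floor(config$plant_rate) +
            stats::rbinom(1, 1, config$plant_rate %% 1)
        if (k == 0) next
        if (plen > L) {
          warning("motif longer than promoter ", names(seqs)[i],
                  "; skipped")
          next
        }
        occupied <- logical(L)
        for (j in seq_len(k)) {
          for (try in 1:100) {
            s <- sample.int(L - plen + 1, 1)
            if (!any(occupied[s:(s + plen - 1)])) {
              substr(seqs[i], s, s + plen - 1) <- .instantiate_pattern(pat)
              occupied[s:(s + plen - 1)] <- TRUE
              planted <- rbind(planted,
                               data.frame(promoter = names(seqs)[i],
                                          start = s - 1L,
                                          stringsAsFactors = FALSE))
              break
            }
          }
        }
      }
    }
    out <- promoter_set(seqs)
    attr(out, "planted") <- planted
    out
  })
}

#' Simulate miRNA:target duplex fixtures with known defects
#'
#' For each defect specification one miRNA and one transcript are
#' generated: the transcript embeds (between random flanks) the site that
#' is the exact antiparallel complement of the miRNA modified by the
#' stated defects (`"MM"` mismatch or `"GU"` wobble at a miRNA position;
#' wobble positions force the miRNA base to G or U). The truth table
#' records the intended per-criterion outcome derived from the defect
#' geometry alone; the energy criterion (d) is only determined for
#' defect-free sites and is `NA` otherwise (unless another criterion
#' already fails the site).
#'
#' @param config A [simulation_config()] with `duplex_specs`.
#' @return List with `mirnas` and `transcripts` (named character vectors)
#'   and `truth` (data frame with per-criterion logical columns and
#'   `passes`).
#' @export
simulate_mirna_duplexes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  L <- config$mirna_length
  specs <- config$duplex_specs
  for (s in specs) {
    d <- s$defects
    if (is.null(d)) next
    stopifnot(is.data.frame(d), all(c("position", "state") %in% names(d)))
    if (any(d$position < 1 | d$position > L) ||
        anyDuplicated(d$position) ||
        !all(d$state %in% c("MM", "GU")))
      stop("contradictory duplex defect spec")
  }
  withr::with_seed(config$seed, {
    mirnas <- character(0); transcripts <- character(0)
    truth <- list()
    for (si in seq_along(specs)) {
      d <- specs[[si]]$defects %||%
        data.frame(position = integer(), state = character())
      mv <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      gu_pos <- d$position[d$state == "GU"]
      mv[gu_pos] <- sample(c("G", "U"), length(gu_pos), replace = TRUE)
      tv <- unname(RNA_COMP[mv])  # tv[i] opposite miRNA position i
      for (r in seq_len(nrow(d))) {
        pos <- d$position[r]
        if (d$state[r] == "GU") {
          tv[pos] <- unname(RNA_WOBBLE[mv[pos]])
        } else {
          forbid <- c(RNA_COMP[mv[pos]], RNA_WOBBLE[mv[pos]])
          choices <- setdiff(c("A", "C", "G", "U"), forbid[!is.na(forbid)])
          tv[pos] <- choices[sample.int(length(choices), 1)]
        }
      }
      site <- paste(rev(tv), collapse = "")
      fl <- function() paste(sample(c("A", "C", "G", "U"),
                                    config$flank_length, replace = TRUE),
                             collapse = "")
      mid <- sprintf("mir%03d", si)
      tid <- sprintf("tx%03d", si)
      mirnas[mid] <- paste(mv, collapse = "")
      transcripts[tid] <- paste0(fl(), site, fl())

      n_mm <- sum(d$state == "MM"); n_gu <- sum(d$state == "GU")
      half <- d$position <= 10
      tot <- n_mm + 0.5 * n_gu
      fh <- sum(d$state == "MM" & half) + 0.5 * sum(d$state == "GU" & half)
      states <- rep("WC", L)
      states[d$position] <- d$state
      run_all <- .max_mm_run(states)
      run_seed <- .max_mm_run(states[2:min(12, L)])
      a <- tot <= 4 && fh <= 2.5
      b <- run_all <= 2 && run_seed <= 1
      cc <- !any(d$position %in% intersect(11:12, seq_len(L)))
      dd <- if (nrow(d) == 0) TRUE else NA
      passes <- if (isFALSE(a) || isFALSE(b) || isFALSE(cc)) FALSE
                else if (is.na(dd)) NA else a && b && cc && dd
      truth[[si]] <- data.frame(
        mirna_id = mid, target_id = tid,
        site_start = config$flank_length,
        crit_a = a, crit_b = b, crit_c = cc, crit_d = dd,
        passes = passes, stringsAsFactors = FALSE)
    }
    list(mirnas = mirnas, transcripts = transcripts,
         truth = do.call(rbind, truth))
  })
}
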