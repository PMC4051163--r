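test_that("the upper-tail conversion behaves like 1 - pnorm", {
  expect_equal(zfm_pvalue(0), 0.5)
  expect_equal(zfm_pvalue(1.6449), 0.05, tolerance = 2e-3)
  # strictly decreasing and symmetric
  z <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(zfm_pvalue(z)) < 0))
  expect_true(all(abs(zfm_pvalue(z) + zfm_pvalue(-z) - 1) < 1e-12))
})

test_that("enrichment is seeded-deterministic and sorted by P", {
  genome <- simulate_promoters(simulation_config(seed = 300,
                                                 n_promoters = 120))
  motifs <- data.frame(motif_id = c("m1", "m2", "m3"),
                       pattern = c("ACGTCA", "CCWWGG", "TGACGY"),
                       keywords = "", stringsAsFactors = FALSE)
  fg <- names(genome$records)[seq(1, 120, by = 4)]
  r1 <- zfm_enrichment(fg, genome, motifs, k_sets = 100, seed = 4)
  r2 <- zfm_enrichment(fg, genome, motifs, k_sets = 100, seed = 4)
  expect_identical(r1, r2)
  expect_false(is.unsorted(r1$p_value))
  r3 <- zfm_enrichment(fg, genome, motifs, k_sets = 100, seed = 5)
  expect_false(identical(r1$surrogate_mean, r3$surrogate_mean))
})

test_that("foreground ids and an explicit PromoterSet agree on counts", {
  genome <- simulate_promoters(simulation_config(seed = 301,
                                                 n_promoters = 80))
  ids <- names(genome$records)[1:20]
  fg_set <- promoter_set(genome$records[ids])
  motifs <- c(m1 = "ACGTCA")
  ra <- zfm_enrichment(ids, genome, motifs, k_sets = 50, seed = 1)
  rb <- zfm_enrichment(fg_set, genome, motifs, k_sets = 50, seed = 1)
  expect_equal(ra$count, rb$count)
  expect_equal(ra$surrogate_mean, rb$surrogate_mean)
})

test_that("foreground equal to the genome flags nothing", {
  genome <- simulate_promoters(simulation_config(seed = 302,
                                                 n_promoters = 40))
  res <- zfm_enrichment(names(genome$records), genome,
                        c(m1 = "ACGTCA", m2 = "CACGTG"),
                        k_sets = 20, seed = 2)
  # every surrogate set is the same multiset: stdev 0 and N = mean
  expect_true(all(!res$enriched))
  expect_true(all(res$p_value == 1))
  expect_true(all(is.na(res$zfm)))
})

test_that("an undersized genome bin is reported by name", {
  small <- promoter_set(c(a = paste(rep("A", 200), collapse = ""),
                          b = paste(rep("A", 700), collapse = "")))
  fg <- promoter_set(c(x = paste(rep("A", 210), collapse = ""),
                       y = paste(rep("A", 220), collapse = "")))
  expect_error(zfm_enrichment(fg, small, c(m = "ACGT"), k_sets = 10,
                              seed = 1),
               "<500")
})

test_that("a planted 3x foreground rate is detected", {
  base <- list(n_promoters = 400, plant_pattern = "GTACGTAC",
               plant_rate = 5e-4, plant_rate_unit = "per_bp")
  genome <- simulate_promoters(do.call(simulation_config,
                                       c(list(seed = 50), base)))
  fg_cfg <- do.call(simulation_config,
                    c(list(seed = 51),
                      modifyList(base, list(n_promoters = 50,
                                            plant_rate = 1.5e-3))))
  fg <- simulate_promoters(fg_cfg)
  res <- zfm_enrichment(fg, genome, c(m = "GTACGTAC"), k_sets = 200,
                        seed = 52)
  expect_true(res$enriched[1])
  expect_lt(res$p_value[1], 0.01)
})

test_that("significance filtering keeps enriched motifs under the cutoff", {
  res <- data.frame(motif_id = c("a", "b", "c"), pattern = "ACGT",
                    keywords = "", count = 5L, surrogate_mean = 2,
                    surrogate_stdev = 1, zfm = 3,
                    p_value = c(0.2, 0.04, 0.11),
                    enriched = TRUE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(significance_filter(res, 0.1)$motif_id, "b")
  expect_equal(nrow(significance_filter(res, 1.0)), 3)
  expect_error(significance_filter(res, 0), "0, 1")
  expect_error(significance_filter(res, 1.5), "0, 1")
})

test_that("reports print P at six decimals in Table-style columns", {
  res <- data.frame(motif_id = "ABRE", pattern = "YACGTGGC",
                    keywords = "ABA; seed", count = 11L,
                    surrogate_mean = 3.2, surrogate_stdev = 1.78,
                    zfm = 4.38, p_value = zfm_pvalue(4.38),
                    enriched = TRUE, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_report(res, f)
  lines <- readLines(f)
  expect_equal(lines[1], "Motif\tFactor\tCount\tZFM\tP-value\tKeywords")
  expect_match(lines[2], "\t0\\.000006\t")
})
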