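test_that("pcc matches hand-computed and degenerate inputs are refused", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, x), 1)
  expect_equal(pcc(x, -x), -1)
  # covariance 3.5, sd products sqrt(5 * 4.75)
  expect_equal(pcc(x, c(2, 4, 5, 4)), 3.5 / sqrt(5 * 4.75),
               tolerance = 1e-12)
  expect_equal(pcc(x, c(2, 4, 5, 4)), cor(x, c(2, 4, 5, 4)))
  expect_error(pcc(x, c(1, 1, 1, 1)), "zero-variance")
  expect_error(pcc(1:2, 1:2), ">= 3")
})

test_that("mutual ranks are symmetric, >= 1, and 1 iff mutually rank-1", {
  x <- rand_expression(15, 8, seed = 3)
  rp <- mutual_rank(x)
  expect_true(all(rp$mr >= 1))
  expect_equal(rp$mr, sqrt(rp$rank_a * rp$rank_b))
  ones <- rp[rp$mr == 1, ]
  expect_true(all(ones$rank_a == 1 & ones$rank_b == 1))
  # a planted near-duplicate pair must be mutually rank 1
  v <- x$values
  v["g002", ] <- v["g001", ] * 1.01
  x2 <- expression_matrix(v, x$grouping)
  rp2 <- mutual_rank(x2)
  row <- rp2[rp2$gene_x == "g001" & rp2$gene_y == "g002", ]
  expect_equal(row$mr, 1)
})

test_that("mutual_rank matches the brute-force oracle on random matrices", {
  for (rep in 1:10) {
    x <- rand_expression(sample(5:20, 1), sample(4:10, 1),
                         seed = 8000 + rep)
    got <- mutual_rank(x)
    attr(got, "ids") <- NULL
    attr(got, "skipped") <- NULL
    expect_equal(got, oracle_mutual_rank(x$values), tolerance = 1e-12)
  }
})

test_that("zero-variance genes are excluded and reported", {
  x <- rand_expression(6, 6, seed = 12)
  v <- x$values
  v["g004", ] <- 7
  x2 <- expression_matrix(v, x$grouping)
  rp <- mutual_rank(x2)
  expect_identical(attr(rp, "skipped"), "g004")
  expect_false("g004" %in% c(rp$gene_x, rp$gene_y))
  # fully constant matrix: nothing left to rank
  flat <- expression_matrix(
    matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6))),
    setNames(paste0("c", 1:6), paste0("s", 1:6)))
  expect_error(mutual_rank(flat), "non-zero variance")
})

test_that("network thresholding and bookkeeping are consistent", {
  x <- rand_expression(12, 8, seed = 21)
  # MR >= 1 always, so a sub-1 threshold gives an empty edge set
  empty <- build_network(x, mr_threshold = 0.5)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$nodes), 12)
  net <- build_network(x, mr_threshold = 5)
  expect_true(all(net$edges$mr <= 5))
  expect_equal(average_degree(net),
               2 * nrow(net$edges) / length(net$nodes))
  expect_equal(average_degree(10, 4), 5)
})

test_that("planted modules separate cleanly from between-module pairs", {
  cfg <- simulation_config(seed = 7, n_genes = 12, n_conditions = 10,
                           n_replicates = 1, noise_sigma = 0.15,
                           module_specs = list(list(size = 6, loading = 1),
                                               list(size = 6, loading = 1)))
  x <- simulate_expression(cfg)
  rp <- mutual_rank(x)
  truth <- attr(x, "truth")$modules
  same <- mapply(function(a, b)
    (a %in% truth[[1]] & b %in% truth[[1]]) |
    (a %in% truth[[2]] & b %in% truth[[2]]),
    rp$gene_x, rp$gene_y)
  expect_lt(max(rp$mr[same]), min(rp$mr[!same]))
})

test_that("neighborhood sizes truncate to the available genes", {
  expect_equal(nrow(neighborhood(rand_expression(11, 8, seed = 2),
                                 "g001")$level1), 10)
  expect_equal(nrow(neighborhood(rand_expression(6, 8, seed = 2),
                                 "g001")$level1), 5)
  expect_error(neighborhood(rand_expression(6, 8, seed = 2), "nope"),
               "unknown gene")
})

test_that("neighborhood matches the brute-force expansion oracle", {
  for (rep in 1:5) {
    x <- rand_expression(sample(12:20, 1), 8, seed = 4200 + rep)
    center <- sample(rownames(x$values), 1)
    got <- neighborhood(x, center)
    want <- oracle_neighborhood(x$values, center)
    expect_identical(got$level1$gene, want$level1)
    expect_identical(lapply(got$level2, `[[`, "gene"),
                     as.list(want$level2)[got$level1$gene])
    expect_equal(got$level3_edges, want$level3_edges, tolerance = 1e-12)
  }
})

test_that("correlated partner lists honor thresholds and truncation", {
  # plant a module of 5 probes with identical profiles
  x <- rand_expression(20, 10, seed = 31)
  v <- x$values
  for (g in c("g002", "g003", "g004", "g005")) v[g, ] <- v["g001", ]
  x2 <- expression_matrix(v, x$grouping)
  cp <- correlated_partners(x2, "g001")
  expect_true(all(c("g002", "g003", "g004", "g005") %in%
                    cp$positive$probe_id))
  expect_equal(cp$positive$pcc[1:4], rep(1, 4))
  # a vacuous threshold returns everything, bounded by top_k
  all_cp <- correlated_partners(x2, "g001", pos_min = -1.01, top_k = 7)
  expect_equal(nrow(all_cp$positive), 7)
  expect_error(correlated_partners(x2, "nope"), "unknown probe")
})

test_that("independent probes produce empty correlate lists at 0.7", {
  x <- rand_expression(20, 200, seed = 99)
  cp <- correlated_partners(x, "g001")
  expect_equal(nrow(cp$positive), 0)
  expect_equal(nrow(cp$negative), 0)
})

test_that("miRNA pairs attach to resolvable targets and round-trip", {
  net <- build_network(rand_expression(10, 8, seed = 55), mr_threshold = 10)
  pairs <- data.frame(
    mirna_id = c("mir1", "mir1", "mir2", "mir3"),
    target_id = c("g001", "g002", "g003", "not_a_gene"),
    tier = c("high", "low", "high", "high"),
    stringsAsFactors = FALSE)
  expect_warning(net2 <- attach_mirna_pairs(net, pairs), "unresolvable")
  expect_equal(nrow(net2$mirna_pairs), 3)
  p <- withr::local_tempfile(fileext = ".json")
  write_network_json(net2, p)
  back <- read_network_json(p)
  expect_equal(back$mirna_pairs, net2$mirna_pairs)
  expect_equal(back$edges$mr, net2$edges$mr, tolerance = 1e-12)
  expect_equal(back$mr_threshold, 10)
})

test_that("neighborhood JSON tags levels and keeps MR values", {
  x <- rand_expression(15, 8, seed = 61)
  view <- neighborhood(x, "g001")
  p <- withr::local_tempfile(fileext = ".json")
  write_neighborhood_json(view, p)
  obj <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(obj$center, "g001")
  expect_equal(obj$nodes$level[obj$nodes$id == "g001"], 0)
  expect_setequal(obj$nodes$id[obj$nodes$level == 1], view$level1$gene)
})
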