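mir21 <- "UGGAGCUCCCUUCAUUCCAAU"  # fixed 21-nt miRNA used across cases

test_that("window enumeration and antiparallel pairing are correct", {
  site <- rna_complement_of(mir21)
  sites <- candidate_sites(mir21, site)
  expect_length(sites, 1)
  expect_true(all(sites[[1]]$pairing == "WC"))
  expect_true(sites[[1]]$passes)
  expect_error(candidate_sites(mir21, "ACGU"), "shorter")
  tx <- paste(rep("A", 60), collapse = "")
  expect_length(candidate_sites(mir21, tx), 40)  # 60 - 21 + 1
})

test_that("scores weight wobbles 0.5 and track mismatch runs", {
  perfect <- rna_complement_of(mir21)
  d0 <- score_duplex(mirna_duplex(mir21, perfect))
  expect_equal(d0$total_score, 0)
  expect_equal(d0$max_run, 0)

  # one G:U at miRNA position 3 (miRNA G opposite target U)
  mv <- strsplit(mir21, "")[[1]]
  stopifnot(mv[3] == "G")
  tv <- strsplit(perfect, "")[[1]]
  tv[21 + 1 - 3] <- "U"
  d1 <- score_duplex(mirna_duplex(mir21, paste(tv, collapse = "")))
  expect_equal(d1$pairing[3], "GU")
  expect_equal(d1$total_score, 0.5)
  expect_equal(d1$firsthalf_score, 0.5)
  expect_equal(d1$max_run, 0)

  # mismatches at positions 5, 6, 7 form one run of 3
  tv <- strsplit(perfect, "")[[1]]
  for (p in 5:7) tv[21 + 1 - p] <- mv[p]  # same base never pairs
  d3 <- score_duplex(mirna_duplex(mir21, paste(tv, collapse = "")))
  expect_equal(d3$total_score, 3)
  expect_equal(d3$max_run, 3)
  expect_equal(d3$max_run_2_12, 3)

  # a wobble is paired: MM-GU-MM is two runs of one
  tv <- strsplit(perfect, "")[[1]]
  stopifnot(mv[6] == "C")
  mv2 <- mv; mv2[6] <- "G"; tv[21 + 1 - 6] <- "U"   # GU at 6
  for (p in c(5, 7)) tv[21 + 1 - p] <- mv[p]        # MM at 5 and 7
  d4 <- score_duplex(mirna_duplex(paste(mv2, collapse = ""),
                                  paste(tv, collapse = "")))
  expect_equal(unname(d4$pairing[5:7]), c("MM", "GU", "MM"))
  expect_equal(d4$max_run, 1)
})

test_that("duplex energies follow the embedded stack table", {
  # perfect duplex: energy is the plain sum of Watson-Crick stacks
  m <- "GCGCGCGCGCGCGCGCGCGCG"
  d <- mirna_duplex(m, rna_complement_of(m))
  stacks <- rep(c(txmine:::.WC_STACKS[["GC/CG"]],
                  txmine:::.WC_STACKS[["CG/GC"]]), 10)
  expect_equal(duplex_mfe(d), sum(stacks))
  expect_equal(perfect_mfe(m), sum(stacks))

  # two central mismatches remove three stacks and add one loop penalty
  tv <- strsplit(rna_complement_of(m), "")[[1]]
  tv[21 + 1 - 10] <- "C"; tv[21 + 1 - 11] <- "G"   # same-base mismatches
  d2 <- apply_criteria(mirna_duplex(m, paste(tv, collapse = "")))
  expect_equal(d2$mfe_site, sum(stacks[-(9:11)]) + 1)
  expect_equal(d2$mfe_ratio, d2$mfe_site / d2$mfe_perfect)

  # every position mismatched: no stacks, zero energy, ratio 0
  all_mm <- paste(strsplit(m, "")[[1]], collapse = "")  # site = miRNA itself
  d3 <- mirna_duplex(m, all_mm)
  expect_true(all(d3$pairing == "MM"))
  expect_warning(e <- duplex_mfe(d3), "no paired")
  expect_equal(e, 0)
  expect_equal(suppressWarnings(apply_criteria(d3))$mfe_ratio, 0)
})

test_that("the four criteria gate as specified", {
  perfect <- rna_complement_of(mir21)
  expect_true(apply_criteria(mirna_duplex(mir21, perfect))$passes)
  mv <- strsplit(mir21, "")[[1]]

  # a mismatch at position 11 fails (c) no matter how mild
  tv <- strsplit(perfect, "")[[1]]
  tv[21 + 1 - 11] <- mv[11]
  d11 <- apply_criteria(mirna_duplex(mir21, paste(tv, collapse = "")))
  expect_false(d11$criteria[["c"]])
  expect_false(d11$passes)

  # five scattered mismatches exceed the total budget of 4
  tv <- strsplit(perfect, "")[[1]]
  for (p in c(1, 4, 7, 15, 19)) tv[21 + 1 - p] <- mv[p]
  d5 <- apply_criteria(mirna_duplex(mir21, paste(tv, collapse = "")))
  expect_equal(d5$total_score, 5)
  expect_false(d5$criteria[["a"]])
})

test_that("adding a mismatch never helps a duplex", {
  withr::with_seed(88, {
    for (rep in 1:15) {
      mv <- sample(c("A", "C", "G", "U"), 21, replace = TRUE)
      m <- paste(mv, collapse = "")
      tv <- strsplit(rna_complement_of(m), "")[[1]]
      base <- apply_criteria(mirna_duplex(m, paste(tv, collapse = "")))
      pos <- sample(2:20, 1)
      tv[21 + 1 - pos] <- mv[pos]
      worse <- apply_criteria(mirna_duplex(m, paste(tv, collapse = "")))
      expect_lte(worse$mfe_ratio, base$mfe_ratio)
      expect_gte(worse$total_score, base$total_score)
    }
  })
})

test_that("prediction finds planted sites and is order-invariant", {
  withr::with_seed(9, {
    flank <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")
    tx <- paste0(flank(30), rna_complement_of(mir21), flank(30))
    mirnas <- c(mirA = mir21)
    txs <- c(t1 = tx, t2 = flank(80))
    hits <- predict_targets(mirnas, txs)
    expect_true(any(hits$target_id == "t1" & hits$site_start == 30))
    shuffled <- predict_targets(mirnas, txs[c(2, 1)])
    expect_identical(hits, shuffled)
  })
})

test_that("random transcripts essentially never pass the rules", {
  n_hits <- 0
  for (s in 1:30) {
    withr::with_seed(9000 + s, {
      tx <- paste(sample(c("A", "C", "G", "U"), 500, replace = TRUE),
                  collapse = "")
      n_hits <- n_hits + nrow(predict_targets(c(m = mir21), c(t = tx)))
    })
  }
  expect_lte(n_hits / 30, 0.05)
})

test_that("rule engine agrees with the naive oracle on random windows", {
  withr::with_seed(123, {
    m10 <- paste(sample(c("A", "C", "G", "U"), 10, replace = TRUE),
                 collapse = "")
    for (rep in 1:200) {
      w <- paste(sample(c("A", "C", "G", "U"), 10, replace = TRUE),
                 collapse = "")
      d <- apply_criteria(suppressWarnings(mirna_duplex(m10, w)))
      o <- oracle_duplex_flags(m10, w)
      expect_equal(unname(d$criteria), unname(o[c("a", "b", "c", "d")]) == 1,
                   info = w)
      expect_equal(d$passes, o[["passes"]] == 1, info = w)
    }
  })
})
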