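test_that("predict_sites finds perfect and near sites, rejects distant ones", {
  piRNAspread:::with_seed(51, {
    tseq <- rand_seq(400)
  })
  t <- transcript_model("tx", tseq)
  # a perfect site: piRNA = revcomp of the window at [100, 121)
  win <- substr(tseq, 101, 121)
  pir <- oracle_revcomp(win)
  substr(pir, 1, 1) <- "T"  # enforce 5' U; at most 1 mismatch introduced
  hits <- predict_sites(c(p1 = pir), t, max_mm = 3)
  h100 <- hits[hits$start == 100L, ]
  expect_equal(nrow(h100), 1L)
  expect_lte(h100$mismatches, 1L)
  # mismatch counts agree with direct Hamming distance (strand correctness)
  for (r in seq_len(nrow(hits))) {
    w <- substr(tseq, hits$start[r] + 1, hits$start[r] + 21)
    d <- sum(strsplit(w, "")[[1]] != strsplit(oracle_revcomp(pir), "")[[1]])
    expect_equal(hits$mismatches[r], d)
  }
  # a window altered at 4 positions is no longer hit at max_mm = 3
  far <- win
  for (i in c(3, 8, 13, 18)) {
    cur <- substr(far, i, i)
    substr(far, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  t2 <- transcript_model("tx2", paste0(substr(tseq, 1, 100), far,
                                       substr(tseq, 122, 400)))
  pir2 <- oracle_revcomp(win)
  hits2 <- predict_sites(c(p2 = pir2), t2, max_mm = 3, strict = FALSE)
  expect_false(100L %in% hits2$start)
})

test_that("predict_sites equals the naive Hamming oracle on random input", {
  piRNAspread:::with_seed(52, {
    txs <- lapply(1:10, function(i) transcript_model(paste0("t", i), rand_seq(300)))
    names(txs) <- paste0("t", 1:10)
    # half random piRNAs (no hits expected), half derived from transcript
    # windows with the 5' nt forced to U (guaranteed near-perfect hits)
    planted <- vapply(1:5, function(i) {
      w <- substr(txs[[i]]$sequence, 50 + i, 70 + i)
      p <- oracle_revcomp(w); substr(p, 1, 1) <- "T"; p
    }, character(1))
    pirnas <- c(planted, vapply(1:5, function(i) paste0("T", rand_seq(20)),
                                character(1)))
    names(pirnas) <- paste0("p", 1:10)
  })
  hits <- predict_sites(pirnas, txs, max_mm = 3)
  expect_gt(nrow(hits), 0)
  for (pi in names(pirnas)) {
    for (ti in names(txs)) {
      mism <- oracle_hamming_scan(pirnas[[pi]], txs[[ti]]$sequence)
      want <- which(mism <= 3) - 1L
      got <- sort(hits$start[hits$pirna_id == pi & hits$transcript_id == ti])
      expect_equal(got, want, info = paste(pi, ti))
      if (length(want)) {
        got_mm <- hits$mismatches[hits$pirna_id == pi & hits$transcript_id == ti]
        expect_equal(got_mm[order(got)], mism[want + 1L], ignore_attr = TRUE)
      }
    }
  }
  # monotone in max_mm
  n_by_mm <- vapply(0:3, function(mm) nrow(predict_sites(pirnas, txs, mm)), 1L)
  expect_true(all(diff(n_by_mm) >= 0))
  # half assignment is consistent with the midpoint rule
  mid_half <- position_in_half(300L, pmin(hits$start + 10L, 299L))
  expect_identical(hits$half, mid_half)
})

test_that("predict_sites validates piRNA length per strict mode", {
  t <- tiny_refs(1, len = 100, seed = 53)$t1
  expect_error(predict_sites(c(bad = "TACGT"), t), "not 21 nt")
  expect_warning(predict_sites(c(bad = "TACGT"), t, strict = FALSE), "not 21 nt")
})

test_that("half_enrichment builds the 2x2 table and runs the one-sided test", {
  preds <- data.frame(
    pirna_id = "p", transcript_id = c(rep("c1", 8), rep("b1", 8)),
    start = 0L, mismatches = 0L,
    half = c(rep("three_prime", 7), "five_prime",      # cluster: 7 vs 1
             rep("three_prime", 4), rep("five_prime", 4)),  # background: 4 vs 4
    stringsAsFactors = FALSE)
  he <- half_enrichment(preds, "c1", "b1")
  expect_equal(unname(he$table), c(7, 1, 4, 4))
  expect_equal(he$p, fisher_exact(7, 1, 4, 4, alternative = "greater"))
  expect_gt(he$log2_enrichment, 0)
  # identical ratios: null-ish (log2 ~ 0, p large)
  preds2 <- preds
  preds2$half <- rep(c("three_prime", "five_prime"), 8)
  he2 <- half_enrichment(preds2, "c1", "b1")
  expect_equal(he2$log2_enrichment, 0)
  expect_gte(he2$p, 0.5)
  # zero margin: pseudocount keeps the display finite, test uses raw counts
  preds3 <- preds[preds$half == "three_prime", ]
  he3 <- half_enrichment(preds3, "c1", "b1")
  expect_true(is.finite(he3$log2_enrichment))
  expect_error(half_enrichment(preds, character(0), "b1"), "empty")
  expect_error(half_enrichment(preds, "c1", c("c1", "b1")), "overlap")
})

test_that("per_gene_level_change ratios, tests and invariances", {
  genes <- paste0("g", 1:20)
  piRNAspread:::with_seed(54, {
    wt <- stats::setNames(rpois(20, 50) + 1, genes)
  })
  # mutant identical to wild type: all ratios 0, degenerate test p = 1
  same <- per_gene_level_change(wt, wt, library_sizes = c(1e5, 1e5))
  expect_true(all(same$ratios == 0))
  expect_equal(same$tests$p, 1)
  expect_identical(same$tests$method, "degenerate")
  # halving the mutant library size with halved counts leaves ratios unchanged
  lc1 <- per_gene_level_change(wt, wt, library_sizes = c(1e5, 1e5))
  lc2 <- per_gene_level_change(wt / 2, wt, library_sizes = c(5e4, 1e5))
  expect_equal(lc2$ratios, lc1$ratios)
  # depleted mutant: negative median, small one-sided p
  dep <- per_gene_level_change(stats::setNames(rep(0, 20), genes), wt,
                               library_sizes = c(1e5, 1e5))
  expect_lt(dep$tests$median_log2, 0)
  expect_lt(dep$tests$p, 1e-4)
  expect_error(per_gene_level_change(wt[-1], wt, c(1, 1)), "universes differ")
  # boxplot stats columns are ordered
  expect_true(all(dep$box$q1 <= dep$box$median & dep$box$median <= dep$box$q3))
})
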