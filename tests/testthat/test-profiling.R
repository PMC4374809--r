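mk_hits <- function(t, start, end, orientation = "antisense") {
  data.frame(read_id = paste0("r", seq_along(start)),
             sequence = "G", transcript_id = t$id,
             start = start, end = end, orientation = orientation,
             n_loci = 1L, stringsAsFactors = FALSE)
}

test_that("positional_profile counting rules place reads as defined", {
  t <- tiny_refs(1, len = 200, seed = 41)$t1
  h <- mk_hits(t, 100L, 122L)
  p5 <- positional_profile(h, t, mode = "raw")
  expect_equal(sum(p5$values), 1)
  expect_equal(which(p5$values == 1) - 1L, 121L)  # antisense 5' end = end - 1
  pc <- positional_profile(h, t, mode = "raw", counting_rule = "full_coverage")
  expect_equal(which(pc$values == 1) - 1L, 100:121)
  # sense hit contributes at its own 5' end (= start)
  hs <- mk_hits(t, 30L, 52L, orientation = "sense")
  ps <- positional_profile(hs, t, mode = "raw")
  expect_equal(which(ps$values == 1) - 1L, 30L)
  # empty hits give an all-zero profile; out-of-range hits error
  expect_equal(sum(positional_profile(h[0, ], t, mode = "raw")$values), 0)
  expect_error(positional_profile(mk_hits(t, 190L, 212L), t), "outside")
})

test_that("count conservation holds on simulated libraries", {
  cons <- sensor_construct()
  for (gt in c("wild_type", "nrde-4")) {
    sim <- simulate_sensor_scenario(sim_config(seed = 5, depth = 3e4), gt, cons)
    f <- filter_hits(align_exact(sim$reads, cons))
    raw <- positional_profile(f, cons, mode = "raw")
    expect_identical(sum(raw$values), as.numeric(nrow(f)))
    bv <- bin_profile(raw)
    expect_identical(sum(bv$bins), sum(raw$values))
    pd <- proximal_distal(raw, cons$target_site_interval)
    expect_identical(pd$proximal + pd$distal, sum(raw$values))
  }
})

test_that("proximal/distal partition uses the 200-nt window definition", {
  t <- tiny_refs(1, len = 1000, seed = 42)$t1
  site <- c(600L, 621L)
  # 5' end 150 nt upstream of the site: proximal
  h_prox <- mk_hits(t, 428L, 450L)   # 5' end at 449 = 600 - 151
  # 5' end 250 nt upstream: distal
  h_dist <- mk_hits(t, 328L, 350L)
  p <- positional_profile(rbind(h_prox, h_dist), t, mode = "raw")
  pd <- proximal_distal(p, site, 200L)
  expect_equal(pd$proximal, 1)
  expect_equal(pd$distal, 1)
  # empty profile -> (0, 0); negative window errors
  pe <- positional_profile(h_prox[0, ], t, mode = "raw")
  pde <- proximal_distal(pe, site)
  expect_equal(pde$proximal + pde$distal, 0)
  expect_error(proximal_distal(p, site, -1), ">= 0")
})

test_that("bin_profile matches the position-enumeration oracle for all L", {
  # uniform unit profile: every bin holds width * 1
  expect_equal(bin_profile(rep(1, 100))$bins, rep(10, 100 / 10))
  # floor-rule widths for L = 25
  expect_equal(bin_profile(rep(1, 25))$bins, c(2, 3, 2, 3, 2, 3, 2, 3, 2, 3))
  expect_equal(sum(bin_profile(rep(0, 50))$bins), 0)
  expect_error(bin_profile(rep(1, 9)), "shorter")
  set.seed(43)
  for (L in 10:500) {
    v <- rpois(L, 0.5)
    expect_identical(bin_profile(v)$bins, oracle_bin(v, 10), info = paste("L =", L))
  }
})

test_that("normalization modes scale correctly and are scale-invariant", {
  t <- tiny_refs(1, len = 100, seed = 44)$t1
  h <- mk_hits(t, c(10L, 10L, 40L), c(32L, 32L, 62L))
  nf <- structure(list(library_total = 2e6, his58_total = 1000),
                  class = "normalization_factors")
  pm <- positional_profile(h, t, nf, mode = "per_million")
  expect_equal(pm$values[32], 2 * 1e6 / 2e6)
  ph <- positional_profile(h, t, nf, mode = "per_his58")
  expect_equal(ph$values[32], 2 / 1000)
  # doubling reads and totals leaves normalized profiles bit-identical
  h2 <- rbind(h, h)
  nf2 <- structure(list(library_total = 4e6, his58_total = 2000),
                   class = "normalization_factors")
  expect_identical(positional_profile(h2, t, nf2, mode = "per_million")$values,
                   pm$values)
  expect_identical(positional_profile(h2, t, nf2, mode = "per_his58")$values,
                   ph$values)
  # zero normalizer reads in per_his58 mode is an error
  nf0 <- structure(list(library_total = 10, his58_total = 0),
                   class = "normalization_factors")
  expect_error(positional_profile(h, t, nf0, mode = "per_his58"), "zero normalizer")
})

test_that("exon/intron assignment follows the genomic 5' end", {
  t <- transcript_model("tx", rand_seq(60),
                        exons = cbind(start = c(0L, 100L), end = c(30L, 130L)))
  # 5' ends inside exon 1, intron 1, exon 2
  counts <- exon_intron_counts(data.frame(gpos = c(5L, 50L, 110L)), t,
                               library_total = 1e6)
  expect_equal(counts$count[counts$feature == "exon1"], 1)
  expect_equal(counts$count[counts$feature == "intron1"], 1)
  expect_equal(counts$count[counts$feature == "exon2"], 1)
  expect_equal(counts$rpm, counts$count)  # library 1e6 -> rpm == count
  # single-exon transcript has no introns
  t1 <- tiny_refs(1, len = 50, seed = 45)$t1
  expect_false("intron" %in% exon_intron_counts(data.frame(gpos = 10L), t1)$type)
  expect_error(exon_intron_counts(data.frame(gpos = 500L), t), "outside")
})

test_that("ip_enrichment folds behave under identity, pseudocount and zeros", {
  t <- tiny_refs(1, len = 100, seed = 46)$t1
  h <- mk_hits(t, c(10L, 40L, 70L), c(32L, 62L, 92L))
  nf <- structure(list(library_total = 1e6, his58_total = 1),
                  class = "normalization_factors")
  p <- positional_profile(h, t, nf, mode = "per_million")
  same <- ip_enrichment(p, p)
  expect_true(all(same$fold == 1))
  # all-zero control stays finite through the pseudocount
  p0 <- positional_profile(h[0, ], t, nf, mode = "per_million")
  expect_true(all(is.finite(ip_enrichment(p, p0)$fold)))
  # mismatched normalization is an error
  praw <- positional_profile(h, t, mode = "raw")
  expect_error(ip_enrichment(p, praw), "normalization")
})

test_that("profile writers emit readable bedGraph and TSV", {
  t <- tiny_refs(1, len = 50, seed = 47)$t1
  p <- positional_profile(mk_hits(t, 10L, 32L), t, mode = "raw")
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(p, bg)
  lines <- readLines(bg)
  expect_match(lines[1], "bedGraph")
  expect_equal(length(lines), 2L)  # header + the single nonzero run
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(sum(back$value), 1)
})
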