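test_that("classify_22g applies the length and 5' nucleotide definition", {
  expect_true(classify_22g(paste0("G", rand_seq(21))))          # 22 nt, 5' G
  expect_false(classify_22g(paste0("T", rand_seq(20))))         # 21U class
  expect_false(classify_22g(paste0("A", rand_seq(21))))         # wrong 5' nt
  expect_false(classify_22g(paste0("G", rand_seq(25))))         # too long
  expect_true(classify_22g(paste0("A", rand_seq(21)), first_nt = "A"))
  expect_error(classify_22g(""), "empty")
})

test_that("align_exact reports constructed hits with correct coordinates", {
  refs <- tiny_refs(2, len = 200, seed = 21)
  # antisense read at [100, 122) of t1
  r_anti <- oracle_revcomp(substr(refs$t1$sequence, 101, 122))
  hits <- align_exact(c(r_anti), refs)
  anti <- hits[hits$orientation == "antisense", ]
  expect_equal(nrow(anti), 1L)
  expect_equal(anti$start, 100L)
  expect_equal(anti$end, 122L)
  expect_equal(anti$transcript_id, "t1")
  expect_equal(anti$n_loci[1], 1L)
  # a read present in both transcripts carries n_loci 2 on both hits
  shared <- substr(refs$t1$sequence, 11, 32)
  refs2 <- refs
  refs2$t2 <- transcript_model("t2", paste0(shared, substr(refs$t2$sequence, 23, 200)))
  h2 <- align_exact(c(shared), refs2)
  expect_equal(nrow(h2), 2L)
  expect_true(all(h2$n_loci == 2L))
  # absent read: no hits
  expect_equal(nrow(align_exact("GGGGGGGGGGGGGGGGGGGGGG", refs)), 0L)
  # read longer than every reference
  expect_error(align_exact(rand_seq(300), refs), "longer than every reference")
})

test_that("align_exact agrees with the naive sliding-window oracle", {
  piRNAspread:::with_seed(22, {
    refs <- lapply(1:20, function(i) transcript_model(paste0("t", i), rand_seq(80)))
    names(refs) <- paste0("t", 1:20)
    # half substring-derived reads (guaranteed hits), half random
    reads <- c(
      vapply(1:50, function(i) {
        t <- sample(20, 1); p <- sample(60, 1)
        s <- substr(refs[[t]]$sequence, p, p + 21)
        if (runif(1) < 0.5) oracle_revcomp(s) else s
      }, character(1)),
      vapply(1:50, function(i) rand_seq(22), character(1)))
  })
  hits <- align_exact(reads, refs)
  for (i in seq_along(reads)) {
    mine <- hits[hits$read_id == paste0("r", i),
                 c("transcript_id", "start", "end", "orientation")]
    mine <- mine[order(mine$transcript_id, mine$start, mine$orientation), ]
    oracle <- oracle_align_one(reads[i], refs)
    oracle <- oracle[order(oracle$transcript_id, oracle$start, oracle$orientation), ]
    expect_equal(as.matrix(mine), as.matrix(oracle), ignore_attr = TRUE,
                 info = paste("read", i))
    # n_loci equals the oracle's total occurrence count
    if (nrow(mine)) {
      expect_true(all(hits$n_loci[hits$read_id == paste0("r", i)] == nrow(oracle)))
    }
  }
})

test_that("filter_hits enforces uniqueness, orientation and class; idempotent", {
  refs <- tiny_refs(2, len = 150, seed = 23)
  # an antisense 22-mer whose 5' end sits on a template C (so it starts G)
  cpos <- as.integer(gregexpr("C", refs$t1$sequence)[[1]])
  e <- cpos[cpos >= 60][1]
  seqs <- c(
    oracle_revcomp(substr(refs$t1$sequence, e - 21, e)),  # antisense 22G
    substr(refs$t2$sequence, 5, 26),                       # sense
    oracle_revcomp(substr(refs$t1$sequence, 100, 125)))    # antisense, 26 nt
  hits <- align_exact(seqs, refs)
  f <- filter_hits(hits)
  expect_equal(nrow(f), 1L)
  expect_true(all(f$orientation == "antisense"))
  expect_true(all(f$n_loci == 1L))
  expect_true(all(classify_22g(f$sequence)))
  # idempotence
  f2 <- filter_hits(f)
  expect_equal(as.data.frame(f2), as.data.frame(f), ignore_attr = TRUE)
  expect_named(attr(f, "filter_log"),
               c("input", "after_orientation", "after_unique", "after_class"))
  # sense-only input with antisense filter is empty
  sense_only <- hits[hits$orientation == "sense", ]
  expect_equal(nrow(filter_hits(sense_only)), 0L)
})

test_that("unique antisense hits never exceed the number of input reads", {
  sim <- simulate_sensor_scenario(sim_config(seed = 31, depth = 2e4),
                                  "wild_type")
  hits <- align_exact(sim$reads, sensor_construct())
  f <- filter_hits(hits)
  expect_lte(nrow(f), nrow(sim$reads))
})

test_that("normalization factors: his-58 containment and ratio arithmetic", {
  cons <- sensor_construct()
  seg <- cons$segments
  his <- c(seg$start[seg$role == "normalizer"], seg$end[seg$role == "normalizer"])
  # reads fully inside his-58 (sense), plus one straddling the boundary
  inside <- vapply(1:5, function(i)
    substr(cons$sequence, his[1] + 10 * i, his[1] + 10 * i + 21), character(1))
  straddle <- substr(cons$sequence, his[1] - 10, his[1] + 11)
  rs <- read_set(data.frame(read_id = paste0("n", 1:6),
                            sequence = c(inside, straddle)))
  hits <- align_exact(rs, cons)
  nf <- normalization_factors(rs, hits, construct = cons)
  expect_equal(nf$library_total, 6L)
  expect_equal(nf$his58_total, 5L)  # the straddling read is not contained
  # per_his58 profile value: 500 antisense reads at one position / 1000 his58
  prof_vals <- 500 / 1000
  expect_equal(prof_vals, 0.5)
  # per_million: 4 reads at a position, library 2e6 -> 2.0
  expect_equal(4 * 1e6 / 2e6, 2)
})

test_that("FASTQ round trip preserves reads and external alignment TSV loads", {
  rs <- read_set(data.frame(read_id = c("a", "b"),
                            sequence = c("GACGTACGTACGTACGTACGTA", "GTTTACGGACGTATTTACGGAC")))
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_reads(fq)
  expect_equal(back$sequence, rs$sequence)
  expect_equal(back$read_id, rs$read_id)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("read_id\ttranscript_id\tstart\tend\tstrand\tn_loci",
               "a\tt1\t10\t32\t-\t1"), tsv)
  al <- read_alignments_tsv(tsv)
  expect_identical(al$orientation, "antisense")
  expect_equal(al$end - al$start, 22L)
})
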