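test_that("genotype epistasis: tertiary production requires secondary", {
  expect_error(genotype_spec("x", secondary_active = FALSE, tertiary_active = TRUE),
               "epistasis")
  for (nm in c("prg-1", "mut-16", "rrf-1;ego-1", "drh-3")) {
    g <- genotype_preset(nm)
    expect_false(g$secondary_active)
    expect_false(g$tertiary_active)
  }
  for (nm in c("hrde-1", "nrde-1", "nrde-4")) {
    g <- genotype_preset(nm)
    expect_true(g$secondary_active)
    expect_false(g$tertiary_active)
  }
  expect_error(genotype_preset("unknown-1"), "unknown genotype")
})

test_that("sim_config validates rates, probabilities and fractions", {
  expect_error(sim_config(lambda_proximal = -1), ">= 0")
  expect_error(sim_config(read_length_probs = c(`21` = 0.5, `22` = 0.2, `23` = 0.2)),
               "sum to 1")
  expect_error(sim_config(fraction_cluster6_like = 0.8,
                          fraction_cluster1_like = 0.3), "fractions sum")
})

test_that("sensor scenario emits the genotype-dependent read populations", {
  cfg <- sim_config(seed = 61, depth = 3e4)
  cons <- sensor_construct()
  wt <- simulate_sensor_scenario(cfg, "wild_type", cons)
  tab <- wt$truth$class_counts
  expect_gt(tab[["proximal"]], 0)
  expect_gt(tab[["distal"]], 0)
  expect_gt(wt$truth$expected[["distal"]], 0)
  hr <- simulate_sensor_scenario(cfg, "hrde-1", cons)
  expect_gt(hr$truth$class_counts[["proximal"]], 0)
  expect_equal(hr$truth$expected[["distal"]], 0)
  # prg-1 with zero background: no antisense reads on the construct at all
  cfg0 <- sim_config(seed = 61, depth = 3e4, lambda_background = 0)
  pr <- simulate_sensor_scenario(cfg0, "prg-1", cons)
  expect_equal(sum(pr$reads$orientation == "antisense"), 0L)
  # a construct without a target site is rejected
  no_site <- build_transgene(data.frame(name = "x", role = "coding",
                                        sequence = rand_seq(500)))
  expect_error(simulate_sensor_scenario(cfg, "wild_type", no_site), "target_site")
})

test_that("emitted reads are antisense revcomp substrings with 5' G", {
  cfg <- sim_config(seed = 62, depth = 2e4)
  cons <- sensor_construct()
  sim <- simulate_sensor_scenario(cfg, "wild_type", cons)
  anti <- sim$reads[sim$reads$orientation == "antisense", ]
  expect_true(all(substr(anti$sequence, 1, 1) == "G"))
  check <- sample(nrow(anti), 50)
  for (i in check) {
    tmpl <- substr(cons$sequence, anti$start[i] + 1, anti$end[i])
    expect_identical(anti$sequence[i], oracle_revcomp(tmpl))
  }
  # lengths follow the configured support
  expect_true(all(nchar(sim$reads$sequence) %in% 21:23))
})

test_that("region counts converge to lambda * region * depth within 3 SE", {
  cfg <- sim_config(seed = 63, depth = 1e5)
  cons <- sensor_construct()
  sim <- simulate_sensor_scenario(cfg, "wild_type", cons)
  tab <- sim$truth$class_counts
  exp_prox <- sim$truth$expected[["proximal"]]
  expect_lt(abs(tab[["proximal"]] - exp_prox), 3 * sqrt(exp_prox))
  exp_his <- cfg$his58_rate * cfg$depth
  expect_lt(abs(tab[["normalizer"]] - exp_his), 3 * sqrt(exp_his))
})

test_that("fixed seeds give byte-identical fixtures; writer errors on read-only dir", {
  cfg <- sim_config(seed = 64, depth = 5e3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(d1, simulate_sensor_scenario(cfg, "wild_type"))
  write_fixture(d2, simulate_sensor_scenario(cfg, "wild_type"))
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # manifest record counts match what was emitted
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  fq <- Filter(function(x) grepl("fastq$", x$file), man$files)[[1]]
  sim <- simulate_sensor_scenario(cfg, "wild_type")
  expect_equal(fq$records, nrow(sim$reads))
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)
  expect_error(write_fixture(blocker, simulate_sensor_scenario(cfg, "wild_type")),
               "writable")
})

test_that("genome panel composition, truth labels and class structure", {
  cfg <- sim_config(seed = 65, depth = 2e4, n_genes = 40,
                    fraction_cluster6_like = 0.5, fraction_cluster1_like = 0.2)
  panel <- simulate_genome_panel(cfg)
  expect_length(panel$references, 40)
  tg <- panel$truth$genes
  expect_equal(sum(tg$class == "cluster6_like"), 20)
  expect_equal(sum(tg$class == "cluster1_like"), 8)
  # cluster6-like sites sit in the 3' half, cluster1-like in the 5' half
  s <- merge(panel$truth$sites, tg, by = "transcript_id")
  expect_true(all(s$half[s$class == "cluster6_like"] == "three_prime"))
  expect_true(all(s$half[s$class == "cluster1_like"] == "five_prime"))
  # implanted sites really are perfect antisense matches of the piRNAs
  i <- which(s$class == "cluster6_like")[1]
  tseq <- panel$references[[s$transcript_id[i]]]$sequence
  expect_identical(substr(tseq, s$start[i] + 1, s$start[i] + 21),
                   oracle_revcomp(unname(panel$pirnas[[s$pirna_id[i]]])))
  # nrde libraries deplete the lost half of targeted genes
  f <- filter_hits(align_exact(panel$read_sets[["nrde-4"]], panel$references))
  g6 <- tg$transcript_id[tg$class == "cluster6_like"]
  pos5 <- f$end[f$transcript_id %in% g6] - 1L
  lens <- stats::setNames(tg$spliced_length, tg$transcript_id)
  in5 <- pos5 < lens[f$transcript_id[f$transcript_id %in% g6]] %/% 2L
  expect_lt(sum(in5), sum(!in5) / 5)
  # prg-1 removes targeted genes' 22Gs (background only)
  rp <- panel$read_sets[["prg-1"]]
  targeted <- tg$transcript_id[tg$class %in% c("cluster6_like", "cluster1_like")]
  expect_true(all(rp$class[rp$transcript_id %in% targeted] == "background"))
  expect_error(simulate_genome_panel(sim_config(n_genes = 5)), "n_genes")
})

test_that("panel reads arise from the spliced template only (exons only)", {
  cfg <- sim_config(seed = 66, depth = 2e4, n_genes = 20)
  panel <- simulate_genome_panel(cfg)
  intron_total <- 0
  for (id in names(panel$references)) {
    t <- panel$references[[id]]
    if (nrow(t$exons) == 1L) next
    for (gt in names(panel$read_sets)) {
      rs <- panel$read_sets[[gt]]
      rs <- rs[rs$transcript_id == id, ]
      if (!nrow(rs)) next
      g <- data.frame(gpos = map_to_genomic(t, rs$end - 1L))
      ec <- exon_intron_counts(g, t)
      intron_total <- intron_total + sum(ec$count[ec$type == "intron"])
    }
  }
  expect_equal(intron_total, 0)
})

test_that("IP pair resampling recovers the generative weight and rejects bad input", {
  cfg <- sim_config(seed = 67, ip_fold = 1, depth = 2e4)
  base <- simulate_scenario("sensor_ip", cfg)
  pair <- simulate_ip_pair(cfg, base$reads)
  # null case: ip_fold = 1 leaves composition statistically unchanged
  tab <- rbind(table(pair$ip$class %in% c("proximal", "distal")),
               table(pair$ip_control$class %in% c("proximal", "distal")))
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.01)
  expect_error(simulate_ip_pair(sim_config(ip_fold = 0.5), base$reads), "ip_fold")
  empty <- read_set(data.frame(read_id = character(0), sequence = character(0)))
  expect_error(simulate_ip_pair(cfg, empty), "empty")
})

test_that("operon and RNAi-feeding scenario presets shape reads as declared", {
  cfg <- sim_config(seed = 68, depth = 3e4)
  ts <- simulate_scenario("operon_trans_silenced", cfg)
  expect_gt(sum(ts$reads$class == "proximal"), 0)  # GFP cistron
  expect_gt(sum(ts$reads$class == "distal"), 0)    # spread into mCherry
  p0 <- simulate_scenario("rnai_feeding_P0", cfg)
  expect_equal(sum(p0$reads$class == "distal"), 0)
  f2 <- simulate_scenario("rnai_feeding_F2", cfg)
  expect_gt(sum(f2$reads$class == "distal"), 0)
  oc <- simulate_scenario("operon_outcrossed", cfg)
  expect_lt(sum(oc$reads$class == "proximal"),
            0.6 * sum(ts$reads$class == "proximal"))
  expect_error(simulate_scenario("nope", cfg), "unknown scenario")
})
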