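# End-to-end orchestration: simulate -> align -> filter -> profile ->
# cluster -> target scan -> statistics, with logged, checksummed outputs.

.sensor_keys <- c("outdir", "seed", "depth", "genotypes", "normalization",
                  "window", "include_ip", "lambda_proximal", "lambda_distal",
                  "lambda_background", "his58_rate", "ip_fold")
.genome_keys <- c("outdir", "seed", "depth", "n_genes",
                  "fraction_cluster6_like", "fraction_cluster1_like",
                  "k_range", "cluster_genotype", "max_mm",
                  "spreading_threshold", "min_reads", "pseudocount")

.check_keys <- function(cfg, allowed) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg
}

.merge_cfg <- function(cfg, defaults) {
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg
}

.sim_config_from <- function(cfg, seed) {
  args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  args$seed <- seed
  do.call(sim_config, args)
}

# Per-gene 10-bin raw antisense count matrix from filtered hits.
#' Bin matrix over a reference set
#'
#' Tabulates the 5' ends of filtered antisense hits per transcript and bins
#' each transcript's counts with [bin_profile()]. Rows cover every reference
#' transcript (zero rows for genes without hits).
#'
#' @param hits Filtered hits (antisense, 22G, unique).
#' @param refs List of [transcript_model()]s.
#' @param n_bins Number of bins (default 10).
#' @return Numeric matrix, genes x bins.
#' @export
bin_matrix_from_hits <- function(hits, refs, n_bins = 10L) {
  ids <- vapply(refs, `[[`, "", "id")
  m <- matrix(0, length(ids), n_bins, dimnames = list(ids, NULL))
  pos5 <- hits$end - 1L
  by_gene <- split(pos5, hits$transcript_id)
  for (id in names(by_gene)) {
    L <- refs[[id]]$spliced_length
    counts <- tabulate(by_gene[[id]] + 1L, nbins = L)
    m[id, ] <- bin_profile(as.numeric(counts), n_bins)$bins
  }
  m
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.manifest <- function(outdir, files, params) {
  manifest <- list(
    parameters = params,
    files = lapply(files, function(f) list(file = basename(f),
                                           md5 = unname(tools::md5sum(f)))))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the sensor (transgene) analysis end to end
#'
#' Simulates one sensor library per genotype, aligns reads exactly to the
#' construct, filters to unique antisense 22G hits, computes his-58 (or
#' per-million) normalized positional profiles and the proximal/distal
#' partition, and optionally an IP/input pair with per-bin fold enrichment.
#'
#' @param cfg Named list; allowed keys: `outdir` (required), `seed`, `depth`,
#'   `genotypes`, `normalization` (`"per_his58"` or `"per_million"`),
#'   `window`, `include_ip`, `lambda_proximal`, `lambda_distal`,
#'   `lambda_background`, `his58_rate`, `ip_fold`. Unknown keys are an
#'   error.
#' @return Report bundle (list) with per-genotype profiles, the
#'   proximal/distal summary table, the IP fold table, parameters, logs and
#'   the list of files written.
#' @export
run_sensor_analysis <- function(cfg) {
  cfg <- .check_keys(cfg, .sensor_keys)
  cfg <- .merge_cfg(cfg, list(
    seed = 1L, depth = 1e5,
    genotypes = c("wild_type", "prg-1", "mut-16", "hrde-1", "nrde-4"),
    normalization = "per_his58", window = 200L, include_ip = TRUE))
  if (is.null(cfg$outdir)) stop2("config needs 'outdir'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  construct <- sensor_construct()
  site <- construct$target_site_interval
  files <- character(0)
  logs <- list()
  profiles <- list()
  rows <- list()
  for (i in seq_along(cfg$genotypes)) {
    gt <- cfg$genotypes[i]
    scfg <- .sim_config_from(cfg, seed = cfg$seed + 1000L * i)
    sim <- simulate_sensor_scenario(scfg, gt, construct)
    hits <- align_exact(sim$reads, construct)
    norm <- normalization_factors(sim$reads, hits, construct = construct)
    fhits <- filter_hits(hits)
    logs[[gt]] <- c(n_reads = nrow(sim$reads), attr(fhits, "filter_log"),
                    his58 = norm$his58_total)
    if (cfg$normalization == "per_his58" && norm$his58_total == 0) {
      stop2("missing normalizer reads in per_his58 mode (", gt, ")")
    }
    prof <- positional_profile(fhits, construct, norm, mode = cfg$normalization)
    raw <- positional_profile(fhits, construct, norm, mode = "raw")
    profiles[[gt]] <- prof
    pd <- proximal_distal(raw, site, cfg$window)
    rows[[gt]] <- data.frame(
      genotype = gt, n_reads = nrow(sim$reads),
      his58_reads = norm$his58_total, antisense_22g = raw$n_hits,
      proximal = pd$proximal, distal = pd$distal,
      distal_proximal_ratio = if (pd$proximal > 0) pd$distal / pd$proximal else NA,
      stringsAsFactors = FALSE)
    safe <- gsub("[^A-Za-z0-9._-]", "_", gt)
    files <- c(files,
               write_profile_tsv(prof, file.path(cfg$outdir, paste0("profile_", safe, ".tsv"))),
               write_bedgraph(prof, file.path(cfg$outdir, paste0("profile_", safe, ".bedgraph"))))
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  files <- c(files, .write_tsv(summary, file.path(cfg$outdir, "proximal_distal_summary.tsv")))

  ip <- NULL
  if (isTRUE(cfg$include_ip)) {
    ipcfg <- .sim_config_from(cfg, seed = cfg$seed + 900000L)
    base <- simulate_scenario("sensor_ip", ipcfg)
    pair <- simulate_ip_pair(ipcfg, base$reads)
    prof_of <- function(rs) {
      h <- filter_hits(align_exact(rs, construct))
      positional_profile(h, construct, normalization_factors(rs),
                         mode = "per_million")
    }
    p_ip <- prof_of(pair$ip)
    p_ctrl <- prof_of(pair$ip_control)
    fold_bins <- ip_enrichment(p_ip, p_ctrl, n_bins = 10L)
    fold_all <- ip_enrichment(p_ip, p_ctrl, n_bins = 1L)$fold
    ip <- list(bins = fold_bins, overall_fold = fold_all,
               generative_fold = ipcfg$ip_fold)
    files <- c(files, .write_tsv(fold_bins, file.path(cfg$outdir, "ip_enrichment.tsv")))
  }
  params <- cfg
  bundle <- list(kind = "sensor", construct_id = construct$id, site = site,
                 profiles = profiles, summary = summary, ip = ip,
                 params = params, logs = logs)
  sj <- file.path(cfg$outdir, "sensor_summary.json")
  jsonlite::write_json(list(summary = summary,
                            ip_overall_fold = ip$overall_fold %||% NULL,
                            parameters = params[setdiff(names(params), "outdir")]),
                       sj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, sj)
  files <- c(files, .manifest(cfg$outdir, files,
                              params[setdiff(names(params), "outdir")]))
  bundle$files <- files
  bundle
}

#' Run the genome-panel analysis end to end
#'
#' Simulates the panel, aligns and filters each genotype's reads, builds the
#' per-gene 10-bin matrix, clusters the mutant-condition bin shapes
#' (k chosen over `k_range` by the convergence rule), computes per-cluster
#' mutant/WT log-ratio curves and spreading calls, predicts piRNA target
#' sites and their per-cluster 3'-half enrichment, the per-gene prg-1/WT
#' level-change tables, and the exon/intron read partition.
#'
#' @param cfg Named list; allowed keys: `outdir` (required), `seed`, `depth`,
#'   `n_genes`, `fraction_cluster6_like`, `fraction_cluster1_like`,
#'   `k_range`, `cluster_genotype`, `max_mm`, `spreading_threshold`,
#'   `min_reads`, `pseudocount`. Unknown keys are an error.
#' @return Report bundle (list): bin matrices, `clustering`, `curves`,
#'   `calls`, `predictions`, `enrichment`, `level_change`, `exon_intron`,
#'   truth, parameters, files.
#' @export
run_genome_analysis <- function(cfg) {
  cfg <- .check_keys(cfg, .genome_keys)
  cfg <- .merge_cfg(cfg, list(
    seed = 1L, depth = 1e5, n_genes = 300L,
    fraction_cluster6_like = 0.5, fraction_cluster1_like = 0.2,
    k_range = 2:8, cluster_genotype = "nrde-4", max_mm = 3L,
    spreading_threshold = 0.5, min_reads = 1, pseudocount = 1e-6))
  if (is.null(cfg$outdir)) stop2("config needs 'outdir'")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  scfg <- .sim_config_from(cfg, seed = cfg$seed)
  panel <- simulate_genome_panel(scfg)
  refs <- panel$references
  files <- character(0)

  mats <- list(); totals <- list(); lib <- numeric(0); fhits_by_gt <- list()
  for (gt in names(panel$read_sets)) {
    rs <- panel$read_sets[[gt]]
    fhits <- filter_hits(align_exact(rs, refs))
    fhits_by_gt[[gt]] <- fhits
    mats[[gt]] <- bin_matrix_from_hits(fhits, refs)
    totals[[gt]] <- rowSums(mats[[gt]])
    lib[gt] <- nrow(rs)
  }
  if (!length(Reduce(intersect, lapply(totals, function(x) names(x[x > 0]))))) {
    stop2("conditions have disjoint gene universes")
  }

  cg <- cfg$cluster_genotype
  if (!cg %in% names(mats)) stop2("cluster_genotype not among simulated sets")
  prep <- prepare_bin_matrix(mats[[cg]], min_reads = cfg$min_reads)
  sel <- select_k(prep, k_range = cfg$k_range, seed = cfg$seed)
  result <- sel$results[[paste0("k", sel$k_chosen)]]
  curves <- ratio_curves(result, mats[[cg]], mats[["wild_type"]],
                         library_sizes = c(lib[[cg]], lib[["wild_type"]]),
                         pseudocount = cfg$pseudocount)
  calls <- call_spreading(curves, threshold = cfg$spreading_threshold)

  predictions <- predict_sites(panel$pirnas, refs, max_mm = cfg$max_mm)
  universe <- names(result$assignments)
  enrichment <- lapply(sort(unique(result$assignments)), function(cl) {
    inc <- universe[result$assignments == cl]
    half_enrichment(predictions, inc, setdiff(universe, inc))
  })
  names(enrichment) <- paste0("cluster", sort(unique(result$assignments)))

  lc <- per_gene_level_change(totals[["prg-1"]][universe],
                              totals[["wild_type"]][universe],
                              library_sizes = c(lib[["prg-1"]], lib[["wild_type"]]),
                              clusters = result$assignments)

  # exon/intron partition of the clustering condition's filtered hits
  ei <- lapply(universe, function(id) {
    h <- fhits_by_gt[[cg]]
    h <- h[h$transcript_id == id, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    g <- data.frame(gpos = map_to_genomic(refs[[id]], h$end - 1L))
    cbind(transcript_id = id,
          exon_intron_counts(g, refs[[id]], library_total = lib[[cg]]))
  })
  ei <- do.call(rbind, ei[!vapply(ei, is.null, TRUE)])

  assignments_df <- data.frame(transcript_id = universe,
                               cluster = unname(result$assignments),
                               truth_class = panel$truth$genes$class[
                                 match(universe, panel$truth$genes$transcript_id)],
                               stringsAsFactors = FALSE)
  files <- c(files,
    .write_tsv(cbind(transcript_id = rownames(mats[[cg]]), as.data.frame(mats[[cg]])),
               file.path(cfg$outdir, "bin_matrix.tsv")),
    .write_tsv(assignments_df, file.path(cfg$outdir, "cluster_assignments.tsv")),
    .write_tsv(curves, file.path(cfg$outdir, "ratio_curves.tsv")),
    .write_tsv(predictions, file.path(cfg$outdir, "site_predictions.tsv")),
    .write_tsv(lc$tests, file.path(cfg$outdir, "level_change_tests.tsv")),
    .write_tsv(lc$box, file.path(cfg$outdir, "level_change_box.tsv")),
    .write_tsv(ei, file.path(cfg$outdir, "exon_intron_counts.tsv")))

  summary <- list(
    k_chosen = sel$k_chosen,
    k_report = sel$report,
    spreading_calls = calls,
    half_enrichment = lapply(enrichment, function(e)
      list(table = as.list(e$table), log2_enrichment = e$log2_enrichment,
           p = e$p, p_binomial = e$p_binomial)),
    level_change = lc$tests,
    intron_reads_total = sum(ei$count[ei$type == "intron"]),
    parameters = cfg[setdiff(names(cfg), "outdir")])
  sj <- file.path(cfg$outdir, "genome_summary.json")
  jsonlite::write_json(summary, sj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, sj)
  files <- c(files, .manifest(cfg$outdir, files,
                              cfg[setdiff(names(cfg), "outdir")]))
  list(kind = "genome", panel = panel, bin_matrices = mats, totals = totals,
       library_sizes = lib, clustering = sel, result = result,
       curves = curves, calls = calls, predictions = predictions,
       enrichment = enrichment, level_change = lc, exon_intron = ei,
       assignments = assignments_df, params = cfg, files = files)
}

#' Write a markdown report for one or both bundles
#'
#' One section per analysis stage; stages whose inputs are absent are
#' marked skipped.
#'
#' @param bundle A bundle from [run_sensor_analysis()] /
#'   [run_genome_analysis()], or a list with elements `sensor` and/or
#'   `genome`.
#' @param path Output markdown path.
#' @return Invisibly, `path`.
#' @export
make_report <- function(bundle, path) {
  if (is.null(bundle) || !length(bundle)) stop2("empty bundle")
  if (!is.null(bundle$kind)) {
    bundle <- stats::setNames(list(bundle), bundle$kind)
  }
  sensor <- bundle$sensor
  genome <- bundle$genome
  ln <- character(0)
  emit <- function(...) ln <<- c(ln, ...)
  fmt_tbl <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 5))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  skipped <- function(title) emit(paste0("## ", title), "", "_Skipped: no input._", "")

  emit("# 22G-RNA spreading analysis report", "")

  emit("## Sensor antisense 22G profiles", "")
  if (!is.null(sensor)) {
    emit(fmt_tbl(sensor$summary), "")
  } else emit("_Skipped: no input._", "")

  emit("## HRDE-1 IP enrichment", "")
  if (!is.null(sensor$ip)) {
    emit(sprintf("Overall construct fold (IP/control): %.3f (generative weight %.3g)",
                 sensor$ip$overall_fold, sensor$ip$generative_fold), "",
         fmt_tbl(sensor$ip$bins), "")
  } else emit("_Skipped: no input._", "")

  emit("## Endogenous-gene 22G profiles (per-million)", "")
  if (!is.null(genome)) {
    cg <- genome$params$cluster_genotype
    emit(sprintf("Panel of %d genes; bin matrices computed for %s.",
                 nrow(genome$panel$truth$genes),
                 paste(names(genome$bin_matrices), collapse = ", ")), "")
  } else emit("_Skipped: no input._", "")

  emit("## Spreading-pattern clusters and mutant/WT ratio calls", "")
  if (!is.null(genome)) {
    emit(sprintf("k chosen: %d (largest converged in range).", genome$clustering$k_chosen), "",
         fmt_tbl(genome$clustering$report), "", fmt_tbl(genome$calls), "")
  } else emit("_Skipped: no input._", "")

  emit("## piRNA target-site 3'-half enrichment", "")
  if (!is.null(genome)) {
    e <- do.call(rbind, lapply(names(genome$enrichment), function(nm) {
      x <- genome$enrichment[[nm]]
      data.frame(cluster = nm, log2_enrichment = x$log2_enrichment,
                 fisher_p = x$p, binomial_p = x$p_binomial)
    }))
    emit(fmt_tbl(e), "")
  } else emit("_Skipped: no input._", "")

  emit("## Per-gene 22G level changes (prg-1 vs wild type)", "")
  if (!is.null(genome)) emit(fmt_tbl(genome$level_change$tests), "")
  else emit("_Skipped: no input._", "")

  emit("## Exon/intron read partition", "")
  if (!is.null(genome)) {
    intr <- sum(genome$exon_intron$count[genome$exon_intron$type == "intron"])
    exn <- sum(genome$exon_intron$count[genome$exon_intron$type == "exon"])
    emit(sprintf("Exon-assigned reads: %d; intron-assigned reads: %d.", exn, intr), "")
  } else emit("_Skipped: no input._", "")

  emit("## Parameters and stage logs", "")
  for (nm in names(bundle)) {
    p <- bundle[[nm]]$params
    emit(paste0("### ", nm), "",
         paste0("```json"),
         jsonlite::toJSON(p[setdiff(names(p), "outdir")], auto_unbox = TRUE,
                          pretty = TRUE),
         "```", "")
    if (!is.null(bundle[[nm]]$logs)) {
      for (g in names(bundle[[nm]]$logs)) {
        emit(paste0("- ", g, ": ",
                    paste(names(bundle[[nm]]$logs[[g]]),
                          bundle[[nm]]$logs[[g]], sep = "=", collapse = ", ")))
      }
      emit("")
    }
  }
  writeLines(ln, path)
  invisible(path)
}

#' One-command sensor preset
#'
#' Runs the full sensor analysis (all default genotypes + IP) with default
#' parameters into `outdir` and writes the report. Identical seed implies
#' byte-identical outputs.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @return The bundle, invisibly.
#' @export
reproduce_sensor <- function(outdir, seed = 1L) {
  bundle <- run_sensor_analysis(list(outdir = outdir, seed = seed))
  make_report(bundle, file.path(outdir, "report.md"))
  invisible(bundle)
}

#' One-command genome-panel preset
#'
#' Runs the full genome-panel analysis with default parameters into
#' `outdir` and writes the report. Identical seed implies byte-identical
#' outputs.
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @return The bundle, invisibly.
#' @export
reproduce_panel <- function(outdir, seed = 1L) {
  bundle <- run_genome_analysis(list(outdir = outdir, seed = seed))
  make_report(bundle, file.path(outdir, "report.md"))
  invisible(bundle)
}
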