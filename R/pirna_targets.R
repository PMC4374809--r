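# piRNA target-site prediction and positional enrichment statistics.

#' Predict piRNA target sites on transcripts
#'
#' A piRNA targets a transcript position `p` when the transcript window
#' `[p, p+21)` is within `max_mm` mismatches of the reverse complement of
#' the piRNA (ungapped, end-to-end over all 21 positions; N counts as a
#' mismatch). All hits are reported, including overlapping ones. Each site
#' is assigned to the transcript half containing its midpoint.
#'
#' @param pirnas Named character vector of 21-nt piRNA sequences (DNA or RNA
#'   alphabet; U is converted to T).
#' @param transcripts List of [transcript_model()]s (or named character
#'   vector of sequences).
#' @param max_mm Maximum mismatches (default 3).
#' @param strict Error (rather than warn) on malformed piRNAs.
#' @return data.frame: `pirna_id`, `transcript_id`, `start` (0-based),
#'   `mismatches`, `half`.
#' @export
predict_sites <- function(pirnas, transcripts, max_mm = 3L, strict = TRUE) {
  pirnas <- validate_pirnas(dna_from_rna(pirnas), strict = strict)
  pirnas <- pirnas[nchar(pirnas) == 21L]
  if (is.character(transcripts)) {
    ids <- names(transcripts) %||% paste0("t", seq_along(transcripts))
    seqs <- unname(transcripts)
  } else {
    if (inherits(transcripts, "transcript_model")) transcripts <- list(transcripts)
    ids <- vapply(transcripts, `[[`, "", "id")
    seqs <- vapply(transcripts, `[[`, "", "sequence")
  }
  subjects <- lapply(seqs, Biostrings::DNAString)
  pats <- lapply(revcomp(pirnas), Biostrings::DNAString)
  out <- vector("list", length(pats) * length(subjects))
  n <- 0L
  for (i in seq_along(pats)) {
    for (j in seq_along(subjects)) {
      L <- length(subjects[[j]])
      if (L < 21L) next
      m <- Biostrings::matchPattern(pats[[i]], subjects[[j]],
                                    max.mismatch = max_mm, with.indels = FALSE,
                                    fixed = TRUE)
      st <- BiocGenerics::start(m)
      keep <- st >= 1L & st + 20L <= L
      st <- st[keep]
      if (!length(st)) next
      mm <- Biostrings::neditStartingAt(pats[[i]], subjects[[j]], starting.at = st,
                                        with.indels = FALSE, fixed = TRUE)
      n <- n + 1L
      out[[n]] <- data.frame(pirna_id = names(pirnas)[i], transcript_id = ids[j],
                             start = st - 1L, mismatches = mm,
                             row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  if (n == 0L) {
    return(data.frame(pirna_id = character(0), transcript_id = character(0),
                      start = integer(0), mismatches = integer(0),
                      half = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(n)])
  res <- res[res$mismatches <= max_mm, , drop = FALSE]
  lens <- stats::setNames(nchar(seqs), ids)
  mid <- res$start + 10L
  res$half <- ifelse(mid < lens[res$transcript_id] %/% 2L,
                     "five_prime", "three_prime")
  rownames(res) <- NULL
  res
}

#' 3'-half vs 5'-half target-site enrichment of a gene cluster
#'
#' Tests whether predicted piRNA target sites of a cluster's genes fall in
#' the 3' transcript half more often than those of background genes, with a
#' one-sided Fisher's exact test on the 2x2 table (cluster 3'/5' site counts
#' vs background 3'/5'). The log2 enrichment is reported with a pseudocount
#' (display only; the test uses raw counts). A within-cluster binomial test
#' of the 3' fraction against 0.5 is included as a secondary statistic.
#'
#' @param predictions Output of [predict_sites()].
#' @param cluster_genes,background_genes Disjoint character vectors of
#'   transcript ids; predictions must cover their union.
#' @param pseudocount Per-cell pseudocount for the log2 display (default 0.5).
#' @return A `half_enrichment` list: `table` (a, b, c, d), `log2_enrichment`,
#'   `p` (Fisher, one-sided 3'-biased), `p_binomial`, `n_cluster_sites`.
#' @export
half_enrichment <- function(predictions, cluster_genes, background_genes,
                            pseudocount = 0.5) {
  if (!length(cluster_genes)) stop2("empty cluster gene set")
  if (length(intersect(cluster_genes, background_genes))) {
    stop2("cluster and background gene sets overlap")
  }
  cl <- predictions[predictions$transcript_id %in% cluster_genes, ]
  bg <- predictions[predictions$transcript_id %in% background_genes, ]
  a <- sum(cl$half == "three_prime"); b <- sum(cl$half == "five_prime")
  c_ <- sum(bg$half == "three_prime"); d <- sum(bg$half == "five_prime")
  log2_enr <- log2(((a + pseudocount) / (b + pseudocount)) /
                   ((c_ + pseudocount) / (d + pseudocount)))
  p <- if (a + b + c_ + d > 0) {
    fisher_exact(a, b, c_, d, alternative = "greater")
  } else NA_real_
  p_bin <- if (a + b > 0) {
    stats::binom.test(a, a + b, p = 0.5, alternative = "greater")$p.value
  } else NA_real_
  structure(list(table = c(a = a, b = b, c = c_, d = d),
                 log2_enrichment = log2_enr, p = p, p_binomial = p_bin,
                 n_cluster_sites = a + b),
            class = "half_enrichment")
}

#' @export
print.half_enrichment <- function(x, ...) {
  cat(sprintf("3'-half site enrichment: log2 = %.3f, Fisher p = %.4g (binomial p = %.4g)\n",
              x$log2_enrichment, x$p, x$p_binomial))
  cat(sprintf("  cluster 3'/5' = %d/%d; background 3'/5' = %d/%d\n",
              x$table["a"], x$table["b"], x$table["c"], x$table["d"]))
  invisible(x)
}

#' Per-gene 22G level change between two libraries
#'
#' Library-size-normalized per-gene log2 ratios (mutant over wild type),
#' a paired Wilcoxon signed-rank test of the normalized counts (per cluster
#' when assignments are given), and boxplot summaries (quartiles, 1.5 x IQR
#' whiskers).
#'
#' @param counts_mut,counts_wt Named numeric vectors of raw per-gene
#'   antisense 22G totals over the same gene universe.
#' @param library_sizes Length-2 numeric `c(mutant, wt)`.
#' @param clusters Optional named integer vector of cluster assignments
#'   (genes absent from it form no group).
#' @param pseudocount Added to both normalized counts (default 1e-6 = 1 RPM).
#' @param alternative Sidedness of the Wilcoxon test (default `"less"`:
#'   reads lost in the mutant).
#' @return List: `ratios` (named vector), `tests` (data.frame cluster/n/W/
#'   p/method), `box` (data.frame of boxplot stats per cluster).
#' @export
per_gene_level_change <- function(counts_mut, counts_wt, library_sizes,
                                  clusters = NULL, pseudocount = 1e-6,
                                  alternative = "less") {
  genes <- names(counts_wt)
  if (is.null(genes) || !setequal(genes, names(counts_mut))) {
    stop2("mutant and wild-type gene universes differ")
  }
  counts_mut <- counts_mut[genes]
  m <- counts_mut / library_sizes[1L]
  w <- counts_wt / library_sizes[2L]
  ratios <- log2((m + pseudocount) / (w + pseudocount))
  groups <- if (is.null(clusters)) {
    list(all = genes)
  } else {
    split(names(clusters), clusters)
  }
  tests <- do.call(rbind, lapply(names(groups), function(cl) {
    g <- intersect(groups[[cl]], genes)
    res <- wilcoxon_signed_rank(m[g] - w[g], alternative = alternative)
    data.frame(cluster = cl, n = length(g), W = res$W, p = res$p,
               method = res$method, median_log2 = stats::median(ratios[g]),
               stringsAsFactors = FALSE)
  }))
  box <- do.call(rbind, lapply(names(groups), function(cl) {
    g <- intersect(groups[[cl]], genes)
    s <- grDevices::boxplot.stats(ratios[g])$stats
    data.frame(cluster = cl, lower_whisker = s[1L], q1 = s[2L],
               median = s[3L], q3 = s[4L], upper_whisker = s[5L],
               stringsAsFactors = FALSE)
  }))
  list(ratios = ratios, tests = tests, box = box)
}
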