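# Positional antisense profiles, proximal/distal partitions, bin vectors,
# exon/intron partitions and IP fold enrichment.

#' Per-nucleotide positional profile of filtered hits
#'
#' Under the default `five_prime_end` counting rule each read contributes
#' once, at the spliced position of its 5' end: for an antisense hit interval
#' `[start, end)` that is position `end - 1`; for a sense hit it is `start`.
#' `full_coverage` increments every covered position instead (for
#' visualization parity). Raw counts are then scaled per normalization mode:
#' `per_million` divides by `library_total` and multiplies by 1e6;
#' `per_his58` divides by `his58_total`.
#'
#' @param hits Hits restricted to one transcript (pre-filtered to antisense,
#'   22G, unique via [filter_hits()] for the standard analysis).
#' @param t A [transcript_model()].
#' @param norm A [normalization_factors()] object (required unless
#'   `mode = "raw"`).
#' @param mode `"raw"`, `"per_million"` or `"per_his58"`.
#' @param counting_rule `"five_prime_end"` or `"full_coverage"`.
#' @return A `positional_profile`: list with `transcript_id`, `values`
#'   (length `spliced_length`), `normalization`, `counting_rule`, `n_hits`.
#' @export
positional_profile <- function(hits, t, norm = NULL,
                               mode = c("raw", "per_million", "per_his58"),
                               counting_rule = c("five_prime_end", "full_coverage")) {
  mode <- match.arg(mode)
  counting_rule <- match.arg(counting_rule)
  L <- t$spliced_length
  hits <- hits[hits$transcript_id == t$id, , drop = FALSE]
  if (nrow(hits) && (any(hits$start < 0L) || any(hits$end > L))) {
    stop2("hit interval outside transcript ", t$id)
  }
  values <- numeric(L)
  if (nrow(hits)) {
    if (counting_rule == "five_prime_end") {
      pos5 <- ifelse(hits$orientation == "sense", hits$start, hits$end - 1L)
      tab <- tabulate(pos5 + 1L, nbins = L)
      values <- as.numeric(tab)
    } else {
      for (i in seq_len(nrow(hits))) {
        rng <- (hits$start[i] + 1L):hits$end[i]
        values[rng] <- values[rng] + 1
      }
    }
  }
  if (mode != "raw") {
    if (is.null(norm)) stop2("normalization factors required for mode ", mode)
    if (mode == "per_million") {
      if (norm$library_total <= 0) stop2("library_total must be positive")
      values <- values * 1e6 / norm$library_total
    } else {
      if (norm$his58_total <= 0) stop2("per_his58 requested with zero normalizer reads")
      values <- values / norm$his58_total
    }
  }
  structure(list(transcript_id = t$id, values = values, normalization = mode,
                 counting_rule = counting_rule, n_hits = nrow(hits)),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> %s: %d nt, %d hits, %s/%s, total %.4g\n",
              x$transcript_id, length(x$values), x$n_hits,
              x$normalization, x$counting_rule, sum(x$values)))
  invisible(x)
}

#' Plot a positional profile
#'
#' @param x A [positional_profile()].
#' @param construct Optional construct whose segment boundaries are drawn.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.positional_profile <- function(x, construct = NULL, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "h",
                 xlab = "nt from start codon", ylab = x$normalization,
                 main = x$transcript_id, ...)
  if (!is.null(construct)) {
    graphics::abline(v = construct$segments$start[-1L], lty = 2, col = "grey50")
  }
  invisible(x)
}

#' Partition a profile into target-site proximal and distal signal
#'
#' Proximal signal lies within `window` nt of the piRNA target site
#' (default 200, the operational definition of secondary 22G-RNAs); distal
#' signal is the remainder of the transcript.
#'
#' @param profile A [positional_profile()].
#' @param site Length-2 integer `c(start, end)`, 0-based half-open.
#' @param window Flank width in nt (>= 0).
#' @return A `region_summary` list: `proximal`, `distal`, `window_nt`.
#' @export
proximal_distal <- function(profile, site, window = 200L) {
  if (window < 0) stop2("window must be >= 0")
  L <- length(profile$values)
  if (site[1L] < 0L || site[2L] > L || site[2L] <= site[1L]) {
    stop2("site interval outside transcript")
  }
  lo <- max(0L, site[1L] - window)
  hi <- min(L, site[2L] + window)
  proximal <- if (hi > lo) sum(profile$values[(lo + 1L):hi]) else 0
  structure(list(proximal = proximal,
                 distal = sum(profile$values) - proximal,
                 window_nt = as.integer(window)),
            class = "region_summary")
}

# Internal: bin index (1..n_bins) of each 0-based position for length L.
.bin_of <- function(L, n_bins) {
  edges <- floor((0:n_bins) * L / n_bins)
  findInterval(0:(L - 1L), edges, rightmost.closed = FALSE)
}

#' Summarize a profile into evenly spaced bins
#'
#' Bin `b` (0-based) covers spliced positions `[floor(b*L/n), floor((b+1)*L/n))`,
#' ordered 5' to 3'; the bin sum equals the profile total exactly.
#'
#' @param profile A [positional_profile()] (or numeric vector of values).
#' @param n_bins Number of bins (default 10).
#' @return A `bin_vector` list: `transcript_id`, `bins`, `total`.
#' @export
bin_profile <- function(profile, n_bins = 10L) {
  values <- if (inherits(profile, "positional_profile")) profile$values else profile
  L <- length(values)
  if (L < n_bins) stop2("transcript shorter than n_bins (", L, " < ", n_bins, ")")
  b <- .bin_of(L, n_bins)
  bins <- vapply(seq_len(n_bins), function(k) sum(values[b == k]), numeric(1))
  structure(list(transcript_id = if (inherits(profile, "positional_profile"))
                   profile$transcript_id else NA_character_,
                 bins = bins, total = sum(values)),
            class = "bin_vector")
}

#' Per-exon and per-intron read counts
#'
#' Reads are assigned to the feature (exon or intron) containing their
#' genomic 5' end; counts are reported both raw and as reads per million of
#' `library_total`. Features are ordered 5' to 3' along the transcript.
#'
#' @param genomic_hits data.frame with column `gpos`: genomic 0-based
#'   position of each read's 5' end (e.g. via [map_to_genomic()]).
#' @param t A [transcript_model()] with genomic exon structure.
#' @param library_total Library size for the RPM scaling.
#' @return data.frame: `feature`, `type`, `gstart`, `gend`, `count`, `rpm`.
#' @export
exon_intron_counts <- function(genomic_hits, t, library_total = NULL) {
  ex <- t$exons
  n <- nrow(ex)
  feats <- data.frame(gstart = ex[, "start"], gend = ex[, "end"],
                      type = "exon", stringsAsFactors = FALSE)
  if (n > 1L) {
    feats <- rbind(feats,
                   data.frame(gstart = ex[-n, "end"], gend = ex[-1L, "start"],
                              type = "intron", stringsAsFactors = FALSE))
  }
  feats <- feats[order(feats$gstart), , drop = FALSE]
  if (t$strand == "-") feats <- feats[rev(seq_len(nrow(feats))), , drop = FALSE]
  idx_exon <- cumsum(feats$type == "exon")
  idx_intron <- cumsum(feats$type == "intron")
  feats$feature <- ifelse(feats$type == "exon",
                          paste0("exon", idx_exon), paste0("intron", idx_intron))
  gpos <- genomic_hits$gpos
  span <- c(min(ex[, "start"]), max(ex[, "end"]))
  if (length(gpos) && (any(gpos < span[1L]) || any(gpos >= span[2L]))) {
    stop2("hit outside the genomic span of ", t$id)
  }
  feats$count <- vapply(seq_len(nrow(feats)), function(i) {
    sum(gpos >= feats$gstart[i] & gpos < feats$gend[i])
  }, numeric(1))
  total <- library_total %||% max(1, length(gpos))
  feats$rpm <- feats$count * 1e6 / total
  rownames(feats) <- NULL
  feats[, c("feature", "type", "gstart", "gend", "count", "rpm")]
}

#' IP fold enrichment per bin
#'
#' Fold enrichment of an immunoprecipitated library over its control
#' (e.g. anti-HRDE-1 IP from wild type vs from the deletion mutant), per bin
#' of the transcript: `(wt + pseudocount) / (ctrl + pseudocount)` on
#' per-million profiles.
#'
#' @param profile_ip,profile_ctrl [positional_profile()]s on the same
#'   transcript and normalization (`per_million`).
#' @param pseudocount Added to both numerator and denominator (default 1,
#'   i.e. one read per million).
#' @param n_bins Number of bins (default 10); `n_bins = 1` gives the whole-
#'   transcript fold.
#' @return data.frame: `bin`, `ip`, `ctrl`, `fold`.
#' @export
ip_enrichment <- function(profile_ip, profile_ctrl, pseudocount = 1, n_bins = 10L) {
  if (profile_ip$transcript_id != profile_ctrl$transcript_id) {
    stop2("profiles are on different transcripts")
  }
  if (profile_ip$normalization != profile_ctrl$normalization) {
    stop2("profiles have different normalization modes")
  }
  a <- bin_profile(profile_ip, n_bins)$bins
  b <- bin_profile(profile_ctrl, n_bins)$bins
  data.frame(bin = seq_len(n_bins), ip = a, ctrl = b,
             fold = (a + pseudocount) / (b + pseudocount))
}

#' Write a profile as bedGraph (transcript-space)
#'
#' @param profile A [positional_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(profile, path) {
  v <- profile$values
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%g", profile$transcript_id,
                   starts[keep], ends[keep], r$values[keep])
  writeLines(c(sprintf("track type=bedGraph name=%s_%s", profile$transcript_id,
                       profile$normalization), lines), path)
  invisible(path)
}

#' Write a profile as TSV
#'
#' @param profile A [positional_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(transcript_id = profile$transcript_id,
               pos = seq_along(profile$values) - 1L,
               value = profile$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
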