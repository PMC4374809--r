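# Reference transcripts, transgene constructs and piRNA sets, plus the
# coordinate conventions every downstream profile uses.
#
# Conventions (used package-wide):
#  * All positions are 0-based, half-open, on the SPLICED transcript, with
#    the start of the sequence (start codon for the constructs) at 0.
#  * Exons are genomic 0-based half-open intervals, sorted by genomic start;
#    for minus-strand transcripts the last genomic exon is the 5' end.

#' Construct a spliced transcript model
#'
#' @param id Transcript identifier (unique within a reference set).
#' @param sequence Spliced nucleotide sequence, 5'->3' of the mRNA
#'   (alphabet A/C/G/T/N).
#' @param exons Optional two-column matrix or data.frame of genomic exon
#'   intervals (0-based, half-open), sorted and non-overlapping. Their summed
#'   width must equal `nchar(sequence)`. Default: one exon covering the
#'   sequence.
#' @param strand `"+"` or `"-"`.
#' @param chrom Genomic sequence name the exons live on (defaults to `id`).
#' @return An object of class `transcript_model` with fields `id`, `strand`,
#'   `chrom`, `exons`, `sequence`, `spliced_length`.
#' @export
transcript_model <- function(id, sequence, exons = NULL, strand = "+", chrom = id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    stop2("transcript ", id, ": sequence alphabet must be A/C/G/T/N")
  }
  L <- nchar(sequence)
  if (is.null(exons)) exons <- cbind(start = 0L, end = L)
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) == 0L) stop2("transcript ", id, ": no exons")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop2("transcript ", id, ": empty or inverted exon interval")
  if (is.unsorted(exons[, "start"], strictly = TRUE) ||
      any(exons[-1L, "start", drop = TRUE] < exons[-nrow(exons), "end", drop = TRUE]))
    stop2("transcript ", id, ": exons must be sorted and non-overlapping")
  if (!strand %in% c("+", "-")) stop2("strand must be '+' or '-'")
  widths <- exons[, "end"] - exons[, "start"]
  if (sum(widths) != L) {
    stop2("transcript ", id, ": exon widths sum to ", sum(widths),
          " but sequence length is ", L)
  }
  structure(
    list(id = id, strand = strand, chrom = chrom, exons = exons,
         sequence = sequence, spliced_length = L),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s strand, %d nt spliced, %d exon%s)\n",
              x$id, x$strand, x$spliced_length, nrow(x$exons),
              if (nrow(x$exons) == 1L) "" else "s"))
  invisible(x)
}

#' Load reference transcripts from FASTA (+ optional annotation)
#'
#' Without an annotation every FASTA record becomes a single-exon transcript.
#' With an annotation (GFF3 exon features grouped by `Parent`, or BED12
#' blocks) the FASTA is taken to hold the spliced sequences and the
#' annotation supplies genomic exon structure; annotated exon widths must sum
#' to the sequence length. One annotation dialect per file.
#'
#' @param fasta Path to a FASTA file of spliced transcript sequences.
#' @param annotation Optional path to a GFF3 (`.gff`, `.gff3`) or BED12
#'   (`.bed`) file.
#' @return Named list of [transcript_model()] objects.
#' @export
load_references <- function(fasta, annotation = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop2("empty FASTA: ", fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop2("duplicate sequence ids in ", fasta, ": ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqchr <- as.character(seqs)
  names(seqchr) <- ids
  ann <- if (!is.null(annotation)) read_annotation(annotation) else NULL
  models <- lapply(ids, function(id) {
    if (!is.null(ann) && id %in% names(ann)) {
      a <- ann[[id]]
      transcript_model(id, seqchr[[id]], exons = a$exons,
                       strand = a$strand, chrom = a$chrom)
    } else {
      transcript_model(id, seqchr[[id]])
    }
  })
  if (!is.null(ann)) {
    missing <- setdiff(names(ann), ids)
    if (length(missing)) {
      stop2("annotated transcripts without a FASTA sequence: ",
            paste(missing, collapse = ", "))
    }
  }
  names(models) <- ids
  models
}

# Parse GFF3 or BED12 into list(id -> list(exons, strand, chrom)).
read_annotation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(gr) == 0L) stop2("no exon features in ", path)
    pl <- as.list(gr$Parent)
    if (any(lengths(pl) != 1L)) {
      stop2("exon features lacking a single Parent in ", path)
    }
    parent <- sub("^transcript:", "", unlist(pl, use.names = FALSE))
    out <- lapply(split(seq_along(gr), parent), function(i) {
      sub <- gr[i]
      o <- order(BiocGenerics::start(sub))
      list(exons = cbind(start = BiocGenerics::start(sub)[o] - 1L,
                         end = BiocGenerics::end(sub)[o]),
           strand = as.character(BiocGenerics::strand(sub))[1L],
           chrom = as.character(GenomeInfoDb::seqnames(sub))[1L])
    })
    return(out)
  }
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (is.null(gr$blocks)) stop2(path, " is not BED12 (no block structure)")
    out <- lapply(seq_along(gr), function(i) {
      bl <- gr$blocks[[i]]
      gstart <- BiocGenerics::start(gr)[i] - 1L   # back to 0-based
      list(exons = cbind(start = gstart + BiocGenerics::start(bl) - 1L,
                         end = gstart + BiocGenerics::end(bl)),
           strand = as.character(BiocGenerics::strand(gr))[i],
           chrom = as.character(GenomeInfoDb::seqnames(gr))[i])
    })
    names(out) <- gr$name
    return(out)
  }
  stop2("unsupported annotation dialect: ", path,
        " (expected .gff/.gff3 or .bed)")
}

#' Write reference transcripts to FASTA + BED12
#'
#' Inverse of [load_references()]: `load_references(fasta, bed)` on the
#' written pair reproduces the models.
#'
#' @param models List of [transcript_model()] objects.
#' @param fasta,bed Output paths.
#' @return Invisibly, the two paths.
#' @export
write_references <- function(models, fasta, bed) {
  seqs <- Biostrings::DNAStringSet(vapply(models, `[[`, "", "sequence"))
  names(seqs) <- vapply(models, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta)
  lines <- vapply(models, function(t) {
    ex <- t$exons
    chromStart <- ex[1L, "start"]
    chromEnd <- ex[nrow(ex), "end"]
    sizes <- ex[, "end"] - ex[, "start"]
    starts <- ex[, "start"] - chromStart
    paste(t$chrom, chromStart, chromEnd, t$id, 0L, t$strand,
          chromStart, chromEnd, "0,0,0", nrow(ex),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, bed)
  invisible(c(fasta = fasta, bed = bed))
}

#' Assign a spliced position to the 5' or 3' transcript half
#'
#' Positions strictly below `floor(L/2)` are the 5' half; the midpoint of an
#' odd-length transcript goes to the 3' half, so the two halves differ by at
#' most one position.
#'
#' @param t A [transcript_model()] (or a single integer length).
#' @param pos Integer vector of spliced positions (0-based).
#' @return Character vector, `"five_prime"` or `"three_prime"`.
#' @export
position_in_half <- function(t, pos) {
  L <- if (inherits(t, "transcript_model")) t$spliced_length else as.integer(t)
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= L)) {
    stop2("position out of range [0, ", L, "): ",
          paste(pos[pos < 0L | pos >= L], collapse = ", "))
  }
  ifelse(pos < L %/% 2L, "five_prime", "three_prime")
}

#' Build a transgene construct from an ordered segment list
#'
#' Segments tile the construct without gaps, in order; the construct is a
#' single-exon transcript whose position 0 is the construct start (the start
#' codon for the reporter fusions). A segment with role `target_site` sets
#' `target_site_interval`.
#'
#' @param segments data.frame with columns `name`, `role` (one of `coding`,
#'   `normalizer`, `target_site`, `utr`, `linker`) and `sequence`.
#' @param id Construct identifier.
#' @return An object of class `transgene_construct`; also a valid
#'   `transcript_model`. Extra fields: `segments` (with 0-based half-open
#'   `start`/`end`), `target_site_interval` (length-2 integer or `NULL`).
#' @export
build_transgene <- function(segments, id = "transgene") {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments) == 0L) stop2("empty segment list")
  required <- c("name", "role", "sequence")
  if (!all(required %in% names(segments))) {
    stop2("segments need columns: ", paste(required, collapse = ", "))
  }
  roles <- c("coding", "normalizer", "target_site", "utr", "linker")
  if (!all(segments$role %in% roles)) {
    stop2("unknown segment role(s): ",
          paste(setdiff(segments$role, roles), collapse = ", "))
  }
  if (any(!nzchar(segments$sequence))) stop2("segment with empty sequence")
  ts <- segments$name[segments$role == "target_site"]
  if (anyDuplicated(ts)) {
    stop2("two target_site segments for the same piRNA id: ",
          paste(unique(ts[duplicated(ts)]), collapse = ", "))
  }
  widths <- nchar(segments$sequence)
  segments$end <- as.integer(cumsum(widths))
  segments$start <- segments$end - as.integer(widths)
  seq <- paste(segments$sequence, collapse = "")
  tm <- transcript_model(id, seq)
  tsi <- NULL
  i <- which(segments$role == "target_site")
  if (length(i) == 1L) tsi <- c(segments$start[i], segments$end[i])
  if (length(i) > 1L) {
    tsi <- c(segments$start[i[1L]], segments$end[i[1L]])
  }
  tm$segments <- segments[, c("name", "role", "start", "end", "sequence")]
  tm$target_site_interval <- tsi
  class(tm) <- c("transgene_construct", class(tm))
  tm
}

#' @export
print.transgene_construct <- function(x, ...) {
  cat(sprintf("<transgene_construct> %s (%d nt)\n", x$id, x$spliced_length))
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("  [%5d,%5d) %-12s %s\n", seg$start[i], seg$end[i],
                seg$role[i], seg$name[i]))
  }
  invisible(x)
}

#' Look up the construct segment containing a position
#'
#' @param construct A [build_transgene()] result.
#' @param pos Spliced position(s), 0-based.
#' @return data.frame with `name` and `role` per position.
#' @export
segment_at <- function(construct, pos) {
  seg <- construct$segments
  idx <- findInterval(pos, seg$start)
  if (any(pos < 0L | pos >= construct$spliced_length)) stop2("position outside construct")
  seg[idx, c("name", "role")]
}

#' Map spliced transcript positions to genomic coordinates
#'
#' @param t A [transcript_model()].
#' @param pos Spliced positions (0-based). For minus-strand transcripts
#'   spliced position 0 maps to the genomic end of the last exon.
#' @return Integer vector of genomic positions (0-based).
#' @export
map_to_genomic <- function(t, pos) {
  pos <- as.integer(pos)
  L <- t$spliced_length
  if (any(pos < 0L | pos >= L)) stop2("spliced position out of range")
  ex <- t$exons
  widths <- ex[, "end"] - ex[, "start"]
  if (t$strand == "-") {
    # spliced 5' end is the genomic right end of the last exon
    ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    widths <- rev(widths)
  }
  offs <- cumsum(c(0L, widths))
  i <- findInterval(pos, offs, rightmost.closed = FALSE, left.open = FALSE)
  within <- pos - offs[i]
  if (t$strand == "+") ex[i, "start"] + within else ex[i, "end"] - 1L - within
}

#' Load a piRNA set from FASTA
#'
#' piRNAs (21U-RNAs) are 21 nt with a 5' uridine. Sequences are stored in the
#' DNA alphabet (U -> T) for matching.
#'
#' @param fasta Path to a FASTA of piRNA sequences.
#' @param strict If `TRUE`, a wrong length or 5' nucleotide is an error;
#'   otherwise a warning.
#' @return Named character vector of 21-nt DNA sequences.
#' @export
load_pirnas <- function(fasta, strict = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  x <- dna_from_rna(as.character(seqs))
  names(x) <- sub("\\s.*$", "", names(seqs))
  validate_pirnas(x, strict = strict)
}

validate_pirnas <- function(x, strict = FALSE) {
  bad_len <- nchar(x) != 21L
  bad_nt <- substr(x, 1L, 1L) != "T"
  msg <- character(0)
  if (any(bad_len)) msg <- c(msg, paste0(sum(bad_len), " piRNA(s) not 21 nt"))
  if (any(bad_nt)) msg <- c(msg, paste0(sum(bad_nt), " piRNA(s) without 5' U"))
  if (length(msg)) {
    if (strict) stop2(paste(msg, collapse = "; ")) else warning(paste(msg, collapse = "; "), call. = FALSE)
  }
  x
}
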