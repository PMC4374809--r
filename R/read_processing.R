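# Read classification, exact placement on reference transcripts, and
# normalization factors.
#
# Alignment here is exact matching of error-free reads against the supplied
# reference set (transgene constructs and/or transcripts); uniqueness
# (n_loci) is defined across that reference set only, not genome-wide.

#' Construct a read set
#'
#' A read set is a data.frame with at least `read_id` and `sequence`;
#' simulator-produced sets additionally carry provenance columns
#' (`transcript_id`, `start`, `end`, `orientation`, `class`) that downstream
#' code treats as ground truth for testing, never as input to the analysis.
#'
#' @param reads data.frame with columns `read_id`, `sequence` (+ optional
#'   provenance columns).
#' @param label Free-text label (e.g. genotype) stored as an attribute.
#' @return A `read_set` (data.frame subclass).
#' @export
read_set <- function(reads, label = NA_character_) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  if (nrow(reads) && any(!nzchar(reads$sequence))) stop2("empty read sequence")
  reads$sequence <- dna_from_rna(reads$sequence)
  ok <- grepl("^[ACGTN]+$", reads$sequence) | !nzchar(reads$sequence)
  if (nrow(reads) && !all(ok)) stop2("read alphabet must be A/C/G/T/N/U")
  structure(reads, label = label, class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads%s\n", nrow(x),
              if (!is.na(attr(x, "label"))) paste0(" [", attr(x, "label"), "]") else ""))
  if (nrow(x)) {
    lens <- nchar(x$sequence)
    cat(sprintf("  lengths %d-%d nt; %.1f%% 5'-G\n", min(lens), max(lens),
                100 * mean(substr(x$sequence, 1, 1) == "G")))
  }
  invisible(x)
}

#' Read a FASTQ/FASTA file into a read set
#'
#' @param path FASTQ or FASTA file of adapter-trimmed small-RNA reads.
#' @param format `"fastq"` or `"fasta"` (guessed from the extension).
#' @param label Optional label.
#' @return A [read_set()].
#' @export
read_reads <- function(path, format = NULL, label = NA_character_) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  read_set(data.frame(read_id = sub("\\s.*$", "", names(ss)),
                      sequence = as.character(ss),
                      stringsAsFactors = FALSE),
           label = label)
}

#' Write a read set as FASTQ (Phred-33, constant quality)
#'
#' @param reads A [read_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Classify reads as 22G-RNAs
#'
#' 22G-RNAs are defined by their characteristic length and 5' nucleotide:
#' default 21-23 nt with a 5' G (both configurable; field practice tolerates
#' +/- 1 nt around 22).
#'
#' @param reads A [read_set()] or character vector of read sequences.
#' @param length_range Length-2 integer vector, inclusive bounds.
#' @param first_nt Required 5' nucleotide.
#' @return Logical vector.
#' @export
classify_22g <- function(reads, length_range = c(21L, 23L), first_nt = "G") {
  seqs <- if (is.data.frame(reads)) reads$sequence else dna_from_rna(reads)
  if (any(!nzchar(seqs))) stop2("empty read sequence")
  len <- nchar(seqs)
  len >= length_range[1L] & len <= length_range[2L] &
    substr(seqs, 1L, 1L) == first_nt
}

# Internal: concatenate reference sequences with N spacers; returns the
# subject plus the offset table used to map hit coordinates back.
.build_subject <- function(refs) {
  seqs <- vapply(refs, function(r) if (inherits(r, "transcript_model")) r$sequence else r,
                 character(1))
  ids <- vapply(seq_along(refs), function(i) {
    r <- refs[[i]]
    if (inherits(r, "transcript_model")) r$id else names(refs)[i] %||% paste0("ref", i)
  }, character(1))
  spacer <- 30L
  lens <- nchar(seqs)
  offsets <- cumsum(c(0L, head(lens + spacer, -1L)))
  list(subject = Biostrings::DNAString(paste(seqs, collapse = strrep("N", spacer))),
       ids = ids, lens = lens, offsets = offsets)
}

# Internal: exact matches of a set of equal-length patterns on a subject.
# Returns data.frame(pattern_index, subject_start) (1-based).
.match_block <- function(patterns, subject) {
  pd <- Biostrings::PDict(patterns)
  m <- Biostrings::matchPDict(pd, subject)
  counts <- S4Vectors::elementNROWS(m)
  if (sum(counts) == 0L) {
    return(data.frame(pattern_index = integer(0), subject_start = integer(0)))
  }
  ir <- unlist(m)
  data.frame(pattern_index = rep(seq_along(counts), counts),
             subject_start = BiocGenerics::start(ir))
}

#' Place reads on reference transcripts by exact matching
#'
#' Every exact occurrence of each read (sense) and of its reverse complement
#' (antisense to the transcript) across all references is reported. `n_loci`
#' is the total number of placements of that read sequence across the whole
#' reference set, in both orientations; `n_loci == 1` defines a unique match.
#' Reads containing N cannot match exactly and yield no hits.
#'
#' @param reads A [read_set()] or character vector of sequences.
#' @param refs List of [transcript_model()] objects (or named character
#'   vector of sequences).
#' @return data.frame of hits: `read_id`, `sequence`, `transcript_id`,
#'   `start`, `end` (0-based half-open spliced coordinates), `orientation`
#'   (`"sense"`/`"antisense"`), `n_loci`.
#' @export
align_exact <- function(reads, refs) {
  if (is.character(refs)) refs <- as.list(refs)
  if (inherits(refs, "transcript_model")) refs <- list(refs)
  sub <- .build_subject(refs)
  if (is.character(reads)) {
    reads <- read_set(data.frame(read_id = paste0("r", seq_along(reads)),
                                 sequence = reads, stringsAsFactors = FALSE))
  }
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      transcript_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0),
                      n_loci = integer(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  if (max(nchar(reads$sequence)) > max(sub$lens)) {
    stop2("read longer than every reference (", max(nchar(reads$sequence)),
          " nt vs ", max(sub$lens), " nt)")
  }
  useq <- unique(reads$sequence)
  clean <- !grepl("N", useq, fixed = TRUE)
  hit_list <- list()
  for (len in sort(unique(nchar(useq[clean])))) {
    idx <- which(clean & nchar(useq) == len)
    pats <- Biostrings::DNAStringSet(useq[idx])
    for (ori in c("sense", "antisense")) {
      block <- if (ori == "sense") pats else Biostrings::reverseComplement(pats)
      mm <- .match_block(block, sub$subject)
      if (nrow(mm)) {
        mm$useq_index <- idx[mm$pattern_index]
        mm$orientation <- ori
        mm$len <- len
        hit_list[[length(hit_list) + 1L]] <- mm
      }
    }
  }
  if (!length(hit_list)) return(empty)
  h <- do.call(rbind, hit_list)
  tid_idx <- findInterval(h$subject_start, sub$offsets + 1L)
  h$transcript_id <- sub$ids[tid_idx]
  h$start <- h$subject_start - 1L - sub$offsets[tid_idx]
  h$end <- h$start + h$len
  n_loci <- tabulate(h$useq_index, nbins = length(useq))
  h$n_loci <- n_loci[h$useq_index]
  # expand unique sequences back to individual reads
  read_useq <- match(reads$sequence, useq)
  per_seq <- split(seq_len(nrow(h)), h$useq_index)
  take <- per_seq[as.character(read_useq)]
  n_each <- lengths(take)
  keep_reads <- rep(seq_len(nrow(reads)), n_each)
  hrow <- unlist(take, use.names = FALSE)
  out <- data.frame(read_id = reads$read_id[keep_reads],
                    sequence = reads$sequence[keep_reads],
                    transcript_id = h$transcript_id[hrow],
                    start = h$start[hrow],
                    end = h$end[hrow],
                    orientation = h$orientation[hrow],
                    n_loci = h$n_loci[hrow],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter alignment hits
#'
#' Retains hits that are uniquely placed (`n_loci == 1`), in the requested
#' orientation, and whose reads pass [classify_22g()]. Idempotent. The
#' counts removed at each step are attached as attribute `"filter_log"`.
#'
#' @param hits Output of [align_exact()] (must carry `sequence`, `n_loci`).
#' @param unique_only Keep only uniquely placed reads.
#' @param orientation `"antisense"`, `"sense"` or `NULL` (keep both).
#' @param class_22g Apply the 22G class filter to the read sequences.
#' @param length_range,first_nt Passed to [classify_22g()].
#' @return Filtered hits data.frame.
#' @export
filter_hits <- function(hits, unique_only = TRUE, orientation = "antisense",
                        class_22g = TRUE, length_range = c(21L, 23L),
                        first_nt = "G") {
  log <- c(input = nrow(hits))
  if (!is.null(orientation)) {
    hits <- hits[hits$orientation == orientation, , drop = FALSE]
  }
  log <- c(log, after_orientation = nrow(hits))
  if (unique_only) hits <- hits[hits$n_loci == 1L, , drop = FALSE]
  log <- c(log, after_unique = nrow(hits))
  if (class_22g && nrow(hits)) {
    hits <- hits[classify_22g(hits$sequence, length_range, first_nt), , drop = FALSE]
  }
  log <- c(log, after_class = nrow(hits))
  rownames(hits) <- NULL
  attr(hits, "filter_log") <- log
  hits
}

#' Read external alignments from TSV
#'
#' Six columns: `read_id`, `transcript_id`, `start`, `end` (0-based,
#' half-open spliced coordinates), `strand` (`+` = sense, `-` = antisense to
#' the transcript), `n_loci`. A `sequence` column is optional but required
#' for 22G classification downstream.
#'
#' @param path TSV path (with header).
#' @return Hits data.frame as from [align_exact()] (minus `sequence` if
#'   absent from the file).
#' @export
read_alignments_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("read_id", "transcript_id", "start", "end", "strand", "n_loci")
  if (!all(need %in% names(x))) {
    stop2("alignment TSV needs columns: ", paste(need, collapse = ", "))
  }
  x$orientation <- ifelse(x$strand == "+", "sense", "antisense")
  x$strand <- NULL
  x
}

#' Library normalization factors
#'
#' `library_total` is the number of reads in the library; `his58_total`
#' counts reads fully contained in the normalizer segment, in either
#' orientation and of any length/class (containment avoids edge
#' double-counting).
#'
#' @param reads The full [read_set()] the hits came from.
#' @param hits Alignment hits (unfiltered) used to locate normalizer reads.
#' @param construct Optional [build_transgene()] construct with a
#'   `normalizer` segment; alternatively give `normalizer_interval` and
#'   `transcript_id` directly.
#' @param normalizer_interval Length-2 integer `c(start, end)`, 0-based
#'   half-open.
#' @param transcript_id Transcript the interval lives on.
#' @return A `normalization_factors` list: `library_total`, `his58_total`.
#' @export
normalization_factors <- function(reads, hits = NULL, construct = NULL,
                                  normalizer_interval = NULL,
                                  transcript_id = NULL) {
  library_total <- nrow(reads)
  his58_total <- 0L
  if (!is.null(construct)) {
    seg <- construct$segments
    i <- which(seg$role == "normalizer")
    if (length(i)) {
      normalizer_interval <- c(seg$start[i[1L]], seg$end[i[1L]])
      transcript_id <- construct$id
    }
  }
  if (!is.null(normalizer_interval) && !is.null(hits) && nrow(hits)) {
    inside <- hits$transcript_id == transcript_id &
      hits$start >= normalizer_interval[1L] &
      hits$end <= normalizer_interval[2L]
    his58_total <- length(unique(hits$read_id[inside]))
  }
  structure(list(library_total = library_total, his58_total = his58_total),
            class = "normalization_factors")
}
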