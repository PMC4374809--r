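# Built-in reporter constructs and piRNA sets.
#
# The real reporter transgene sequences are not bundled; the segment layouts
# (names, roles, lengths) follow the published construct schematics, and the
# nucleotide content is SYNTHETIC random sequence generated deterministically.
# That is sufficient for every analysis here, which depends on positions and
# exact matching against the same reference, never on real sequence content.

.construct_seed <- 20150326L  # fixed: built-in references must be stable

#' The synthetic 21UR-1-like piRNA
#'
#' A deterministic synthetic 21-nt, 5'-U piRNA (DNA alphabet) whose perfect
#' target site is embedded in [sensor_construct()].
#'
#' @return Named character vector of length 1.
#' @export
pirna_21ur1 <- function() {
  with_seed(.construct_seed, {
    p <- paste0("T", paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
  })
  c(`21UR-1` = p)
}

#' A synthetic piRNA panel
#'
#' `n` deterministic synthetic 21-nt piRNAs with 5' U (DNA alphabet),
#' the first being [pirna_21ur1()].
#'
#' @param n Number of piRNAs.
#' @return Named character vector.
#' @export
builtin_pirnas <- function(n = 50) {
  stopifnot(n >= 1)
  rest <- with_seed(.construct_seed + 1L, {
    vapply(seq_len(n - 1L), function(i) {
      paste0("T", paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
    }, character(1))
  })
  out <- c(pirna_21ur1(), rest)
  names(out) <- c("21UR-1", if (n > 1L) sprintf("piR-%03d", seq_len(n - 1L)))
  out[seq_len(n)]
}

#' The piRNA sensor construct
#'
#' Single-copy reporter fusion: GFP coding sequence, his-58 (Histone 2B)
#' normalizer segment, the 21UR-1 target site with +/- 50 bp flanks, and a
#' tbb-2 3'UTR. Segment lengths follow the published layout (870, 370,
#' 121 = 21 + 2x50, 200 nt); sequence content is synthetic. The embedded
#' target site is the exact antisense match of [pirna_21ur1()].
#'
#' @return A [build_transgene()] construct, id `"piRNA_sensor"`.
#' @export
sensor_construct <- function() {
  site <- revcomp(unname(pirna_21ur1()))
  segs <- with_seed(.construct_seed + 2L, {
    data.frame(
      name = c("GFP", "his-58", "21UR-1_site", "tbb-2_3UTR"),
      role = c("coding", "normalizer", "target_site", "utr"),
      sequence = c(random_dna(1, 870),
                   random_dna(1, 370),
                   paste0(random_dna(1, 50), site, random_dna(1, 50)),
                   random_dna(1, 200)),
      stringsAsFactors = FALSE
    )
  })
  build_transgene(segs, id = "piRNA_sensor")
}

#' The operon reporter construct
#'
#' Two-cistron reporter: mCherry, the gpd-2 trans-splicing linker, GFP and a
#' par-5 3'UTR. Carries no piRNA target site; in the trans-silencing
#' scenarios the GFP cistron is the homology region through which silencing
#' enters. The GFP segment sequence is identical to the sensor's GFP so reads
#' against GFP are shared homology (they are flagged non-unique when both
#' constructs are in the reference set, as in the living animal).
#'
#' @return A [build_transgene()] construct, id `"operon"`.
#' @export
operon_construct <- function() {
  gfp <- sensor_construct()$segments$sequence[1L]
  segs <- with_seed(.construct_seed + 3L, {
    data.frame(
      name = c("mCherry", "gpd-2_linker", "GFP", "par-5_3UTR"),
      role = c("coding", "linker", "coding", "utr"),
      sequence = c(random_dna(1, 711), random_dna(1, 100), gfp,
                   random_dna(1, 200)),
      stringsAsFactors = FALSE
    )
  })
  build_transgene(segs, id = "operon")
}
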