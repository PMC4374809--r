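# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All randomized operations in the package route through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse-complement DNA sequences
#'
#' Vectorized reverse complement over character vectors in the DNA alphabet
#' (A, C, G, T, N). piRNA sequences given in the RNA alphabet should be
#' converted with U -> T first (see [dna_from_rna()]).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert RNA-alphabet sequences to DNA alphabet
#'
#' @param x Character vector; U/u replaced by T/t, then upper-cased.
#' @return Character vector in the DNA alphabet.
#' @export
dna_from_rna <- function(x) toupper(chartr("Uu", "Tt", x))

# Random DNA string(s); caller is responsible for seeding.
random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# 0-based positions of a given base within a sequence (default C, the
# template base that yields a 5'-G antisense read).
base_positions <- function(sequence, base = "C") {
  hits <- gregexpr(base, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
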