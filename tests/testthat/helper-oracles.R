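# Independent oracles and tiny fixture builders used across the suite.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the implementation they check.

# -- plain-R reverse complement (no Biostrings) ------------------------------
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")

# -- naive sliding-window exact aligner --------------------------------------
# Returns data.frame(transcript_id, start, end, orientation) of every exact
# occurrence of `read` (sense) or its reverse complement (antisense).
oracle_align_one <- function(read, refs) {
  out <- list()
  for (id in names(refs)) {
    s <- refs[[id]]
    if (is.list(s)) s <- s$sequence
    L <- nchar(s); w <- nchar(read)
    if (w > L) next
    for (ori in c("sense", "antisense")) {
      pat <- if (ori == "sense") read else oracle_revcomp(read)
      for (p in 0:(L - w)) {
        if (substr(s, p + 1, p + w) == pat) {
          out[[length(out) + 1L]] <- data.frame(
            transcript_id = id, start = p, end = p + w, orientation = ori,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), orientation = character(0)))
  }
  do.call(rbind, out)
}

# -- vectorized Hamming scan for 21-nt antisense sites -----------------------
# Mismatch count of revcomp(pirna) against every window [p, p+21) of tseq;
# integer-code sliding window, no pattern-matching library.
oracle_hamming_scan <- function(pirna, tseq) {
  L <- nchar(tseq)
  if (L < 21L) return(integer(0))
  pat <- utf8ToInt(oracle_revcomp(pirna))
  s <- utf8ToInt(tseq)
  n <- L - 21L + 1L
  mism <- integer(n)
  for (k in 1:21) mism <- mism + (s[k:(k + n - 1L)] != pat[k])
  mism
}

# -- hypergeometric enumeration for Fisher's exact test ----------------------
oracle_fisher <- function(a, b, c, d, alternative) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  x <- max(0, r1 + c1 - n):min(r1, c1)
  p <- stats::dhyper(x, c1, n - c1, r1)
  obs <- p[x == a]
  switch(alternative,
         greater = sum(p[x >= a]),
         less = sum(p[x <= a]),
         two_sided = sum(p[p <= obs * (1 + 1e-7)]))
}

# -- 2^n sign-flip enumeration for the signed-rank test ----------------------
oracle_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wperm <- as.vector(signs %*% r)
  switch(alternative,
         greater = mean(Wperm >= W),
         less = mean(Wperm <= W),
         two_sided = min(1, 2 * min(mean(Wperm >= W), mean(Wperm <= W))))
}

# -- brute-force optimal 2-partition by within-cluster sum of squares --------
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_wss <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    g <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(g) || all(g)) next
    wss <- 0
    for (side in list(which(g), which(!g))) {
      cc <- colMeans(x[side, , drop = FALSE])
      wss <- wss + sum(sweep(x[side, , drop = FALSE], 2, cc)^2)
    }
    if (wss < best_wss) { best_wss <- wss; best <- g }
  }
  list(groups = best, wss = best_wss)
}

# -- naive position-by-position binning --------------------------------------
oracle_bin <- function(values, n_bins) {
  L <- length(values)
  bins <- numeric(n_bins)
  for (p in 0:(L - 1)) {
    for (b in 0:(n_bins - 1)) {
      if (p >= floor(b * L / n_bins) && p < floor((b + 1) * L / n_bins)) {
        bins[b + 1] <- bins[b + 1] + values[p + 1]
        break
      }
    }
  }
  bins
}

# -- tiny fixtures ------------------------------------------------------------
tiny_refs <- function(n = 3, len = 120, seed = 42) {
  piRNAspread:::with_seed(seed, {
    refs <- lapply(seq_len(n), function(i) {
      transcript_model(paste0("t", i), rand_seq(len))
    })
  })
  names(refs) <- paste0("t", seq_len(n))
  refs
}
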