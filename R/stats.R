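# Exact small-sample statistics used by the pipeline, implemented from
# first principles. All hypergeometric mass is computed in log space
# (log-gamma via lchoose) so margins up to ~1e6 are safe.

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the first cell `a` follows a hypergeometric
#' distribution; p-values sum its exact mass. The two-sided p-value uses the
#' probability-mass rule: all tables whose probability does not exceed that
#' of the observed table (with 1e-7 relative slack), the dominant convention.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`. Alternatively pass a 2x2 matrix as `a`.
#' @param alternative `"two_sided"`, `"greater"` (large `a`) or `"less"`.
#' @return The p-value (in (0, 1]).
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(!vapply(cells, is_count, TRUE))) stop2("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop2("empty table")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  obs <- logp[x == a]
  p <- switch(alternative,
    greater  = sum(exp(logp[x >= a])),
    less     = sum(exp(logp[x <= a])),
    two_sided = sum(exp(logp[logp <= obs + log1p(1e-7)]))
  )
  min(1, max(p, exp(obs)))  # never below the observed table's own mass
}

#' Wilcoxon signed-rank test
#'
#' Ranks of |differences| with midranks for ties; `W` is the sum of ranks of
#' the positive differences. Zeros are dropped before ranking by default
#' (Wilcoxon's original treatment); `zero_policy = "pratt"` ranks them with
#' the rest and then discards their ranks. The null distribution is
#' enumerated exactly over all 2^n sign assignments when `n_nonzero` is at
#' most `exact_threshold` and the |differences| are tie-free; otherwise a
#' normal approximation with tie and continuity correction is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @param alternative `"two_sided"`, `"greater"` (positive shift) or `"less"`.
#' @param zero_policy `"drop"` or `"pratt"`.
#' @param exact_threshold Largest `n_nonzero` for exact enumeration.
#' @param correct Apply the continuity correction in the normal approximation.
#' @return A `signed_rank_result`: list with `n_nonzero`, `W`, `p`, `method`
#'   (`"exact"`, `"normal_approx"` or `"degenerate"`), `alternative`.
#' @export
wilcoxon_signed_rank <- function(diffs,
                                 alternative = c("two_sided", "greater", "less"),
                                 zero_policy = c("drop", "pratt"),
                                 exact_threshold = 12,
                                 correct = TRUE) {
  alternative <- match.arg(alternative)
  zero_policy <- match.arg(zero_policy)
  if (length(diffs) < 1L) stop2("need at least one difference")
  if (anyNA(diffs)) stop2("NA differences")

  if (zero_policy == "drop") {
    d <- diffs[diffs != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(diffs))
    keep <- diffs != 0
    d <- diffs[keep]
    r <- r_all[keep]
  }
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_nonzero = 0L, W = 0, p = 1, method = "degenerate",
                          alternative = alternative),
                     class = "signed_rank_result"))
  }
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  exact_ok <- n <= exact_threshold && !ties && zero_policy == "drop"

  if (exact_ok) {
    # distribution of sum of a random subset of ranks 1..n, by convolution
    maxW <- n * (n + 1) / 2
    cnt <- numeric(maxW + 1)
    cnt[1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(numeric(k), cnt[seq_len(maxW + 1 - k)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w_vals <- 0:maxW
    p_ge <- sum(probs[w_vals >= W])
    p_le <- sum(probs[w_vals <= W])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      return(structure(list(n_nonzero = n, W = W, p = 1, method = "degenerate",
                            alternative = alternative),
                       class = "signed_rank_result"))
    }
    cc <- if (correct) 0.5 else 0
    s <- sqrt(sigma2)
    p <- switch(alternative,
      greater  = stats::pnorm((W - mu - cc) / s, lower.tail = FALSE),
      less     = stats::pnorm((W - mu + cc) / s),
      two_sided = {
        z <- (abs(W - mu) - cc) / s
        min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
      })
    method <- "normal_approx"
  }
  structure(list(n_nonzero = n, W = W, p = max(p, .Machine$double.xmin),
                 method = method, alternative = alternative),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %.4g (%s, %s)\n",
              x$W, x$n_nonzero, x$p, x$method, x$alternative))
  invisible(x)
}
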