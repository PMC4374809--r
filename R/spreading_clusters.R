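# Clustering of per-gene bin vectors and classification of spreading
# direction from per-cluster mutant/wild-type log-ratio curves.

#' Build a genes x bins matrix from raw antisense counts
#'
#' Genes below the inclusion threshold (no 22G signal in the clustering
#' condition) are excluded; rows are optionally scaled to proportions so the
#' clustering captures the shape of the read distribution along the gene,
#' not its abundance.
#'
#' @param bin_mat Numeric matrix (genes x bins) of raw antisense 22G counts,
#'   rownames = gene ids.
#' @param min_reads Minimum raw total for a gene to be "22G-targeted"
#'   (default 1 read).
#' @param scale_proportions Divide each row by its total (default `TRUE`).
#' @return Filtered (and scaled) matrix.
#' @export
prepare_bin_matrix <- function(bin_mat, min_reads = 1, scale_proportions = TRUE) {
  totals <- rowSums(bin_mat)
  keep <- totals >= min_reads
  m <- bin_mat[keep, , drop = FALSE]
  if (scale_proportions) m <- m / rowSums(m)
  m
}

# k-means++ initial centers (RNG already seeded by caller).
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (all(d2 == 0)) p <- rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

.assign_nearest <- function(x, centers) {
  # squared distances via the expansion |x|^2 - 2 x.c + |c|^2
  cross <- x %*% t(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  list(cluster = max.col(-d2, ties.method = "first"),
       wss = sum(d2[cbind(seq_len(nrow(x)), max.col(-d2, ties.method = "first"))]))
}

#' k-means clustering of bin vectors (Lloyd's algorithm, k-means++ start)
#'
#' Deterministic given `seed`. "Converged" means the maximum centroid shift
#' between successive iterations dropped to `tol` or below within `max_iter`
#' iterations. An emptied cluster is re-seeded with the point farthest from
#' its centroid. The within-cluster sum of squares after each update is
#' recorded in `wss_trace` (non-increasing).
#'
#' @param x Numeric matrix (genes x bins).
#' @param k Number of clusters (1 <= k <= distinct rows).
#' @param seed RNG seed for the k-means++ initialization.
#' @param max_iter,tol Convergence controls.
#' @return A `cluster_result`: `k`, `assignments` (named integer),
#'   `centroids`, `seed`, `converged`, `n_iter`, `wss_trace`,
#'   `tot_withinss`.
#' @export
kmeans_spread <- function(x, k, seed = 1L, max_iter = 300L, tol = 1e-6) {
  x <- as.matrix(x)
  if (k < 1) stop2("k must be >= 1")
  if (k > nrow(x)) stop2("k exceeds the number of rows")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) stop2("k exceeds the number of distinct rows")
  centers <- with_seed(seed, .kmeanspp_init(x, k))
  wss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  assign <- NULL
  repeat {
    iter <- iter + 1L
    a <- .assign_nearest(x, centers)
    assign <- a$cluster
    new_centers <- centers
    for (j in seq_len(k)) {
      rows <- which(assign == j)
      if (length(rows)) {
        new_centers[j, ] <- colMeans(x[rows, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the worst-fit point
        d2 <- rowSums((x - centers[assign, , drop = FALSE])^2)
        far <- which.max(d2)
        new_centers[j, ] <- x[far, ]
        assign[far] <- j
      }
    }
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    a2 <- .assign_nearest(x, centers)
    wss_trace <- c(wss_trace, a2$wss)
    if (shift <= tol) { converged <- TRUE; assign <- a2$cluster; break }
    if (iter >= max_iter) { assign <- a2$cluster; break }
  }
  names(assign) <- rownames(x)
  structure(list(k = as.integer(k), assignments = assign, centroids = centers,
                 seed = as.integer(seed), converged = converged,
                 n_iter = iter, wss_trace = wss_trace,
                 tot_withinss = wss_trace[length(wss_trace)]),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, %d genes, %sconverged in %d iter, WSS %.4g\n",
              x$k, length(x$assignments), if (x$converged) "" else "NOT ",
              x$n_iter, x$tot_withinss))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Choose k over a range by the convergence rule
#'
#' Runs [kmeans_spread()] for every k in `k_range` and returns the largest k
#' whose run converged, with a per-k report. (With well-behaved data all k
#' may converge, in which case the top of the range is chosen.)
#'
#' @param x Numeric matrix (genes x bins).
#' @param k_range Integer vector of candidate k (default 2:8).
#' @param seed,max_iter,tol Passed to [kmeans_spread()].
#' @return List: `k_chosen`, `report` (data.frame k/converged/n_iter/wss),
#'   `results` (per-k `cluster_result`s).
#' @export
select_k <- function(x, k_range = 2:8, seed = 1L, max_iter = 300L, tol = 1e-6) {
  results <- lapply(k_range, function(k)
    kmeans_spread(x, k, seed = seed, max_iter = max_iter, tol = tol))
  report <- data.frame(
    k = k_range,
    converged = vapply(results, `[[`, TRUE, "converged"),
    n_iter = vapply(results, `[[`, 1L, "n_iter"),
    tot_withinss = vapply(results, `[[`, 1, "tot_withinss"))
  if (!any(report$converged)) stop2("no k in the range converged")
  k_chosen <- max(k_range[report$converged])
  list(k_chosen = k_chosen, report = report,
       results = stats::setNames(results, paste0("k", k_range)))
}

#' Per-cluster mutant/wild-type log-ratio curves
#'
#' For each cluster and bin: the average raw bin count over the cluster's
#' genes in the mutant, scaled by its library size, is divided by the same
#' quantity in wild type, and the log2 taken (with a pseudocount on both
#' scaled means, default one read per million).
#'
#' @param result A [kmeans_spread()] `cluster_result`.
#' @param mutant_bins,wt_bins Raw count matrices (genes x bins) covering at
#'   least the clustered genes, same gene universe.
#' @param library_sizes Length-2 numeric `c(mutant, wt)` library totals.
#' @param pseudocount Added to both scaled means (default 1e-6 = 1 RPM).
#' @return data.frame: `cluster`, `n_genes`, `bin`, `log2_ratio`.
#' @export
ratio_curves <- function(result, mutant_bins, wt_bins, library_sizes,
                         pseudocount = 1e-6) {
  genes <- names(result$assignments)
  if (!all(genes %in% rownames(mutant_bins)) ||
      !all(genes %in% rownames(wt_bins))) {
    stop2("clustered genes missing from a bin matrix")
  }
  out <- lapply(sort(unique(result$assignments)), function(cl) {
    g <- genes[result$assignments == cl]
    if (!length(g)) stop2("empty cluster ", cl)
    m <- colMeans(mutant_bins[g, , drop = FALSE]) / library_sizes[1L]
    w <- colMeans(wt_bins[g, , drop = FALSE]) / library_sizes[2L]
    data.frame(cluster = cl, n_genes = length(g),
               bin = seq_along(m),
               log2_ratio = log2((m + pseudocount) / (w + pseudocount)))
  })
  do.call(rbind, out)
}

#' Classify clusters by spreading direction
#'
#' The spreading index of a cluster is the mean log-ratio over bins 1-5
#' minus the mean over bins 6-10. An index below `-threshold` means the 5'
#' end lost reads in the mutant (`loss_5prime`, 3'-to-5' spreading in wild
#' type); above `+threshold`, `loss_3prime`; otherwise `none`.
#'
#' @param curves Output of [ratio_curves()].
#' @param threshold Symmetric calling threshold in log2 units (default 0.5).
#' @return data.frame: `cluster`, `n_genes`, `index`, `label`.
#' @export
call_spreading <- function(curves, threshold = 0.5) {
  out <- lapply(split(curves, curves$cluster), function(cc) {
    cc <- cc[order(cc$bin), ]
    nb <- nrow(cc)
    lo <- seq_len(nb %/% 2)
    idx <- mean(cc$log2_ratio[lo]) - mean(cc$log2_ratio[setdiff(seq_len(nb), lo)])
    data.frame(cluster = cc$cluster[1L], n_genes = cc$n_genes[1L],
               index = idx,
               label = if (idx < -threshold) "loss_5prime"
                       else if (idx > threshold) "loss_3prime" else "none",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot per-cluster ratio curves
#'
#' @param curves Output of [ratio_curves()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_ratio_curves <- function(curves, ...) {
  m <- do.call(cbind, lapply(split(curves, curves$cluster),
                             function(cc) cc$log2_ratio[order(cc$bin)]))
  graphics::matplot(m, type = "l", lty = 1, xlab = "bin (5' to 3')",
                    ylab = "log2 mutant/WT", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::legend("bottomright", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), cex = 0.7)
  invisible(m)
}
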