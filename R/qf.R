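# Adaptive binning of a merged pair of samples and the quadratic-form
# dissimilarity between binned distributions: the metric engine behind
# cluster matching and the QF-tree.

#' Adaptive binning of two merged samples
#'
#' Merges the two event sets and recursively splits the merged set at the
#' median of the highest-variance dimension. The recursion depth is global,
#' `L = round(log2(n_merged / (2 ln N)))` with `N` the number of events in
#' the smaller sample, so the tree is balanced with `B = 2^L` bins and on
#' average about `2 ln N` events per bin. Events equal to a split threshold
#' go to the right child. Bin centroids are the means of the merged events
#' per bin.
#'
#' @param events_a,events_b Numeric event matrices (or [sic_events()]).
#' @param dims Columns (shared channels) to bin on; default all of A.
#' @return A list of class `qf_binning` with the split tree (`dim`, `thr`
#'   heap arrays), `L`, `B`, `centroids`, `n_small` and per-bin merged
#'   counts.
#' @export
adaptive_bin <- function(events_a, events_b, dims = NULL) {
  a <- event_values(events_a); b <- event_values(events_b)
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("empty input: both samples must contain events")
  }
  if (is.null(dims)) dims <- seq_len(ncol(a))
  a <- a[, dims, drop = FALSE]; b <- b[, dims, drop = FALSE]
  stopifnot(ncol(a) == ncol(b))
  merged <- rbind(a, b)
  n_small <- min(nrow(a), nrow(b))
  L <- if (n_small < 2L) 0L else {
    max(0L, as.integer(round(log2(nrow(merged) / (2 * log(n_small))))))
  }
  B <- 2L^L
  n_internal <- B - 1L
  dim_of <- integer(n_internal)
  thr_of <- numeric(n_internal)
  centroids <- matrix(NA_real_, B, ncol(merged))
  counts <- integer(B)

  build <- function(node, rows, depth) {
    if (depth == L) {
      bin <- node - n_internal
      counts[bin] <<- length(rows)
      centroids[bin, ] <<- if (length(rows) > 0L) {
        colMeans(merged[rows, , drop = FALSE])
      } else {
        NA_real_  # filled from the nearest non-empty ancestor below
      }
      return(invisible(NULL))
    }
    if (length(rows) > 0L) {
      v <- apply(merged[rows, , drop = FALSE], 2, stats::var)
      v[is.na(v)] <- 0
      d <- which.max(v)  # lowest index wins ties
      t <- stats::median(merged[rows, d])
    } else {
      d <- 1L; t <- Inf
    }
    dim_of[node] <<- d
    thr_of[node] <<- t
    go_right <- merged[rows, d] >= t
    build(2L * node, rows[!go_right], depth + 1L)
    build(2L * node + 1L, rows[go_right], depth + 1L)
    invisible(NULL)
  }
  if (L > 0L) {
    build(1L, seq_len(nrow(merged)), 0L)
  } else {
    counts[1] <- nrow(merged)
    centroids[1, ] <- colMeans(merged)
  }
  # Empty bins inherit the centroid of their deepest non-empty ancestor so
  # the similarity matrix stays well defined.
  if (anyNA(centroids)) {
    fill <- colMeans(merged)
    for (bin in which(is.na(centroids[, 1]))) {
      node <- bin + n_internal
      repeat {
        node <- node %/% 2L
        if (node == 0L) { centroids[bin, ] <- fill; break }
        # Ancestor mean over its leaf bins weighted by counts.
        leaves <- leaf_bins_under(node, L)
        w <- counts[leaves]
        if (sum(w) > 0L) {
          centroids[bin, ] <- colSums(centroids[leaves, , drop = FALSE] * w,
                                      na.rm = TRUE) / sum(w)
          break
        }
      }
    }
  }
  structure(
    list(L = L, B = B, dim = dim_of, thr = thr_of, centroids = centroids,
         counts = counts, n_small = n_small, n_merged = nrow(merged),
         dims = dims),
    class = "qf_binning"
  )
}

# Leaf bin indices (1..B) under an internal heap node.
leaf_bins_under <- function(node, L) {
  depth <- floor(log2(node))
  span <- 2L^(L - depth)
  first_leaf_node <- node * 2L^(L - depth)
  (first_leaf_node:(first_leaf_node + span - 1L)) - (2L^L - 1L)
}

#' Assign events to bins
#'
#' Walks the balanced split tree of a [adaptive_bin()] binning; identical
#' trees applied to any event set partition it.
#'
#' @param binning A `qf_binning`.
#' @param events Numeric event matrix over the same full channel space used
#'   to build the binning (the binning's `dims` are selected internally).
#' @return Integer bin index in `1..B` per event.
#' @export
assign_bins <- function(binning, events) {
  m <- event_values(events)[, binning$dims, drop = FALSE]
  node <- rep(1L, nrow(m))
  if (binning$L == 0L) return(node)
  for (depth in seq_len(binning$L)) {
    d <- binning$dim[node]
    t <- binning$thr[node]
    node <- 2L * node + as.integer(m[cbind(seq_len(nrow(m)), d)] >= t)
  }
  node - (binning$B - 1L)
}

#' Binned frequency distribution of a cluster
#'
#' Counts a cluster's member events per bin of a shared binning and
#' normalizes to sum one.
#'
#' @param binning A [adaptive_bin()] binning.
#' @param events Event matrix of the cluster's sample.
#' @param member_indices Row indices of the cluster's events.
#' @return Numeric length-B frequency vector summing to 1.
#' @export
bin_cluster <- function(binning, events, member_indices) {
  if (length(member_indices) == 0L) {
    stop("empty input: cluster has no member events")
  }
  m <- event_values(events)[member_indices, , drop = FALSE]
  bins <- assign_bins(binning, m)
  tabulate(bins, nbins = binning$B) / length(member_indices)
}

#' Bin similarity matrix
#'
#' `A[i, j] = 1 - d(i, j) / d_max` where `d` is the Euclidean distance
#' between bin centroids and `d_max` its maximum over all pairs; computed
#' once per binning and shared by all cluster-pair comparisons.
#'
#' @param binning A [adaptive_bin()] binning.
#' @return Symmetric B x B matrix with unit diagonal, entries in `[0, 1]`.
#' @export
bin_similarity <- function(binning) {
  if (binning$B == 1L) return(matrix(1, 1, 1))
  d <- unname(as.matrix(stats::dist(binning$centroids)))
  dmax <- max(d)
  if (dmax == 0) return(diag(binning$B))
  1 - d / dmax
}

#' Quadratic-form dissimilarity between binned distributions
#'
#' `sqrt(max(0, sum_ij (f_i - g_i)(f_j - g_j) A_ij))`: zero iff the
#' distributions coincide (for full-rank `A`), symmetric, and sensitive to
#' both frequency differences within bins and the distances between the
#' bins where mass sits.
#'
#' @param f,g Frequency vectors of equal length B.
#' @param sim B x B similarity matrix from [bin_similarity()].
#' @return Nonnegative dissimilarity score.
#' @export
qf_distance <- function(f, g, sim) {
  if (length(f) != length(g) || length(f) != nrow(sim) ||
      nrow(sim) != ncol(sim)) {
    stop("shape error: f, g and sim must share the bin count")
  }
  h <- f - g
  sqrt(max(0, drop(h %*% sim %*% h)))
}
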