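# Exhaustive Projection Pursuit: recursive splitting of a multidimensional
# event set across the best axis-pair 2D projection until no candidate
# decision boundary with acceptably small misclassification error remains.

# Enumerate candidate two-way splits of a clustering: every
# cluster-vs-rest split plus every bipartition whose sides are connected in
# the cluster adjacency graph. Returns a list of side-assignment vectors.
candidate_splits <- function(clustering) {
  k <- clustering$n_clusters
  if (k < 2L) return(list())
  adj <- clustering$adjacency
  connected <- function(members) {
    if (length(members) <= 1L) return(TRUE)
    seen <- members[1]
    repeat {
      nb <- members[members %in% seen |
                      colSums(adj[seen, members, drop = FALSE]) > 0]
      if (length(nb) == length(seen)) break
      seen <- nb
    }
    length(seen) == length(members)
  }
  cands <- list()
  keys <- character(0)
  add <- function(side1) {
    sides <- rep(2L, k); sides[side1] <- 1L
    key <- paste(sort(side1), collapse = ",")
    alt <- paste(sort(setdiff(seq_len(k), side1)), collapse = ",")
    if (key %in% keys || alt %in% keys) return()
    keys <<- c(keys, key)
    cands[[length(cands) + 1L]] <<- sides
  }
  for (c in seq_len(k)) add(c)
  if (k > 2L && k <= 12L) {
    for (code in seq_len(2^(k - 1L) - 1L)) {
      side1 <- which(bitwAnd(code, 2^(seq_len(k) - 1L)) > 0)
      if (length(side1) < 2L || length(side1) > k - 2L) next
      if (connected(side1) && connected(setdiff(seq_len(k), side1))) add(side1)
    }
  }
  cands
}

#' Find the best 2D projection split of an event subset
#'
#' Runs density-based clustering on every unordered channel pair, evaluates
#' every candidate two-way split by its estimated misclassification error
#' across the decision boundary, and returns the globally best one. Ties
#' break lexicographically by channel-pair order, then candidate order;
#' side 1 is the side containing the lowest-index event.
#'
#' @param values Numeric event matrix (full sample).
#' @param indices Row indices of the subset under consideration.
#' @param channels Column indices to search over.
#' @param cfg A [sic_config()].
#' @return `NULL` when no candidate has error `<= cfg$max_error` with both
#'   sides at least the minimum leaf size; otherwise a list with `pair`,
#'   `clustering`, `sides`, `error`, `side1_events`, `side2_events`.
#' @export
best_projection <- function(values, indices = seq_len(nrow(values)),
                            channels = seq_len(ncol(values)),
                            cfg = sic_config()) {
  values <- event_values(values)
  min_leaf <- min_leaf_for(cfg, nrow(values))
  best <- NULL
  pairs <- utils::combn(sort(channels), 2L)
  for (pi in seq_len(ncol(pairs))) {
    pr <- pairs[, pi]
    pts <- values[indices, pr, drop = FALSE]
    if (stats::sd(pts[, 1]) == 0 || stats::sd(pts[, 2]) == 0) next
    cl <- tryCatch(
      cluster_2d(pts, grid_size = cfg$grid_size, theta = cfg$dbm_theta,
                 prominence = cfg$dbm_prominence,
                 outlier_frac = cfg$outlier_frac),
      error = function(e) NULL
    )
    if (is.null(cl) || cl$n_clusters < 2L) next
    for (sides in candidate_splits(cl)) {
      n1 <- sum(sides[cl$labels] == 1L)
      if (n1 < min_leaf || length(indices) - n1 < min_leaf) next
      err <- boundary_error(pts, cl, sides, grid_size = cfg$grid_size)
      if (err <= cfg$max_error && (is.null(best) || err < best$error)) {
        best <- list(pair = pr, clustering = cl, sides = sides, error = err)
      }
    }
  }
  if (is.null(best)) return(NULL)
  ev_side <- best$sides[best$clustering$labels]
  # Side 1 must contain the lowest-index event of the subset.
  if (ev_side[1] != 1L) {
    ev_side <- 3L - ev_side
    best$sides <- 3L - best$sides
  }
  best$side1_events <- indices[ev_side == 1L]
  best$side2_events <- indices[ev_side == 2L]
  best
}

#' Exhaustive Projection Pursuit clustering
#'
#' Recursively splits the event set across the top-ranked decision boundary
#' found by [best_projection()] until no further splits are found. Leaves
#' are the final clusters, labelled 1..K in depth-first discovery order
#' (side 1 explored first). Deterministic for fixed input and
#' configuration.
#'
#' @param x A [sic_events()] object or numeric event matrix.
#' @param channels Channels to analyse (names or indices); default all.
#' @param cfg A [sic_config()].
#' @return An object of class `epp` with components `labels` (per-event
#'   cluster id), `tree` (list of gating-tree nodes), `subsets` (per-cluster
#'   indices, medians, SDs, relative frequencies), `channels`, `config`.
#' @seealso [qfmatch()], [qf_tree()], [mds_embed()]
#' @export
#' @examples
#' \donttest{
#' specs <- canonical_pair_specs()
#' sim <- simulate_pair(specs$spec_a, specs$spec_b, seed = 1)
#' fit <- epp(sim$events_a)
#' fit
#' }
epp <- function(x, channels = NULL, cfg = sic_config()) {
  values <- event_values(x)
  ch_idx <- if (inherits(x, "sic_events")) {
    resolve_channels(x, channels)
  } else if (is.null(channels)) {
    seq_len(ncol(values))
  } else if (is.numeric(channels)) {
    as.integer(channels)
  } else {
    match(channels, colnames(values))
  }
  if (length(ch_idx) < 2L) stop("insufficient data: need at least 2 channels")
  min_leaf <- min_leaf_for(cfg, nrow(values))
  if (nrow(values) < 2L * min_leaf) {
    stop("insufficient data: need at least ", 2L * min_leaf, " events")
  }

  nodes <- list()
  labels <- integer(nrow(values))
  n_leaves <- 0L

  recurse <- function(indices, depth) {
    node_id <- length(nodes) + 1L
    nodes[[node_id]] <<- list(id = node_id, n = length(indices),
                              depth = depth, projection = NULL,
                              error = NA_real_, children = integer(0),
                              leaf_id = NA_integer_)
    split <- if (length(indices) >= 2L * min_leaf) {
      best_projection(values, indices, channels = ch_idx, cfg = cfg)
    } else NULL
    if (is.null(split)) {
      n_leaves <<- n_leaves + 1L
      nodes[[node_id]]$leaf_id <<- n_leaves
      labels[indices] <<- n_leaves
      return(node_id)
    }
    c1 <- recurse(split$side1_events, depth + 1L)
    c2 <- recurse(split$side2_events, depth + 1L)
    nodes[[node_id]]$projection <<- split$pair
    nodes[[node_id]]$error <<- split$error
    nodes[[node_id]]$children <<- c(c1, c2)
    node_id
  }
  recurse(seq_len(nrow(values)), 0L)

  structure(
    list(labels = labels, tree = nodes,
         subsets = make_subsets(values, labels, dims = ch_idx),
         n_clusters = n_leaves, channels = ch_idx,
         channel_names = colnames(values)[ch_idx],
         config = cfg, n_events = nrow(values),
         sample_id = if (inherits(x, "sic_events")) x$sample_id else "sample",
         call = match.call()),
    class = "epp"
  )
}

#' Summarize clusters from labels
#'
#' Builds the per-cluster summaries used throughout the pipeline: member
#' indices, per-channel medians and standard deviations over member events,
#' and the relative frequency in the sample.
#'
#' @param values Numeric event matrix.
#' @param labels Integer cluster labels (`>= 1`), one per event.
#' @param dims Column indices to summarize; default all.
#' @return A list of subsets, each with `label`, `indices`, `median`, `sd`,
#'   `n`, `frequency`.
#' @export
make_subsets <- function(values, labels, dims = seq_len(ncol(values))) {
  values <- event_values(values)
  stopifnot(length(labels) == nrow(values))
  labs <- sort(unique(labels[labels > 0L]))
  lapply(labs, function(l) {
    idx <- which(labels == l)
    sub <- values[idx, dims, drop = FALSE]
    list(label = l, indices = idx,
         median = apply(sub, 2, stats::median),
         sd = apply(sub, 2, stats::sd),
         n = length(idx), frequency = length(idx) / length(labels))
  })
}

#' @export
print.epp <- function(x, ...) {
  cat(sprintf("EPP clustering of '%s': %d events, %d clusters\n",
              x$sample_id, x$n_events, x$n_clusters))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  freq <- vapply(x$subsets, `[[`, numeric(1), "frequency")
  cat("  cluster frequencies:",
      paste(sprintf("%d: %.1f%%", seq_along(freq), 100 * freq),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.epp <- function(object, ...) {
  med <- t(vapply(object$subsets, `[[`, numeric(length(object$channels)),
                  "median"))
  colnames(med) <- object$channel_names
  df <- data.frame(
    cluster = vapply(object$subsets, `[[`, integer(1), "label"),
    n = vapply(object$subsets, `[[`, integer(1), "n"),
    frequency = vapply(object$subsets, `[[`, numeric(1), "frequency")
  )
  cbind(df, med)
}

#' @export
plot.epp <- function(x, events = NULL, pair = NULL, ...) {
  vals <- if (!is.null(events)) event_values(events) else NULL
  if (is.null(vals)) stop("supply the event matrix used for fitting via 'events'")
  pr <- if (is.null(pair)) x$channels[1:2] else pair
  graphics::plot(vals[, pr[1]], vals[, pr[2]], col = x$labels, pch = ".",
                 xlab = colnames(vals)[pr[1]], ylab = colnames(vals)[pr[2]],
                 main = sprintf("EPP clusters (%d)", x$n_clusters), ...)
  invisible(x)
}

#' Export a gating tree as structured text
#'
#' Writes the recursion tree of an EPP fit as JSON: for every node its
#' size, projection channel pair, boundary error, children and leaf id.
#'
#' @param fit An [epp()] object.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string when `path` is `NULL`), invisibly.
#' @export
gating_tree_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "epp"))
  nodes <- lapply(fit$tree, function(nd) {
    list(id = nd$id, n = nd$n, depth = nd$depth,
         channels = if (is.null(nd$projection)) NULL else
           fit$channel_names[match(nd$projection, fit$channels)],
         error = if (is.na(nd$error)) NULL else nd$error,
         children = if (length(nd$children)) nd$children else NULL,
         leaf_id = if (is.na(nd$leaf_id)) NULL else nd$leaf_id)
  })
  js <- jsonlite::toJSON(nodes, auto_unbox = TRUE, pretty = TRUE,
                         null = "null", digits = NA)
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}
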