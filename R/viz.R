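# Cluster-level displays: a classical MDS embedding of cluster medians
# (both samples in one frame) and the agglomerative QF-tree hierarchy.

#' MDS embedding of cluster medians
#'
#' Pools the cluster medians of one or two samples, computes their pairwise
#' Euclidean distances and embeds them in 2D by classical (Torgerson)
#' scaling. The embedding is deterministic up to reflection; axes are
#' ordered by eigenvalue and signs fixed so the first cluster has
#' nonnegative coordinates. Circle radii are proportional to the square
#' root of the relative frequency so circle area tracks frequency.
#'
#' @param subsets_a Subsets of sample A ([make_subsets()] or `epp$subsets`).
#' @param subsets_b Optional subsets of sample B for a joint embedding.
#' @param match Optional [qfmatch()] result; matched clusters share a color
#'   group in the layout.
#' @return An object of class `sic_mds` with `coords`, `radii`, `sample`,
#'   `label`, `group` (color group; `0` = unmatched) and `eig`.
#' @export
mds_embed <- function(subsets_a, subsets_b = NULL, match = NULL) {
  subs <- c(subsets_a, subsets_b)
  if (length(subs) < 2L) {
    stop("insufficient data: need at least 2 clusters to embed")
  }
  med <- t(vapply(subs, `[[`, numeric(length(subs[[1]]$median)), "median"))
  d <- stats::dist(med)
  fit <- stats::cmdscale(d, k = min(2L, length(subs) - 1L), eig = TRUE)
  coords <- fit$points
  if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  for (ax in 1:2) {
    j <- which(abs(coords[, ax]) > 1e-12)[1]
    if (!is.na(j) && coords[j, ax] < 0) coords[, ax] <- -coords[, ax]
  }
  sample <- c(rep("A", length(subsets_a)),
              rep("B", length(if (is.null(subsets_b)) list() else subsets_b)))
  label <- vapply(subs, `[[`, integer(1), "label")
  group <- integer(length(subs))
  if (!is.null(match)) {
    stopifnot(inherits(match, "qfmatch"))
    for (gi in seq_along(match$matches)) {
      m <- match$matches[[gi]]
      group[sample == "A" & label %in% m$a_labels] <- gi
      group[sample == "B" & label %in% m$b_labels] <- gi
    }
  }
  structure(
    list(coords = coords,
         radii = sqrt(vapply(subs, `[[`, numeric(1), "frequency")),
         sample = sample, label = label, group = group,
         eig = fit$eig, medians = med),
    class = "sic_mds"
  )
}

#' @export
print.sic_mds <- function(x, ...) {
  cat(sprintf("MDS layout of %d cluster medians (%d from A, %d from B)\n",
              nrow(x$coords), sum(x$sample == "A"), sum(x$sample == "B")))
  invisible(x)
}

#' @export
plot.sic_mds <- function(x, ...) {
  pal <- grDevices::hcl.colors(max(1L, max(x$group)), "Dark 3")
  col <- ifelse(x$group > 0, pal[pmax(1L, x$group)], "grey40")
  rng <- apply(x$coords, 2, range)
  pad <- 0.15 * max(diff(rng[, 1]), diff(rng[, 2]), 1e-9)
  graphics::plot(NA, xlim = rng[, 1] + c(-pad, pad),
                 ylim = rng[, 2] + c(-pad, pad),
                 xlab = "MDS 1", ylab = "MDS 2", asp = 1,
                 main = "Cluster medians (MDS)", ...)
  r <- x$radii / max(x$radii) * pad
  graphics::symbols(x$coords[, 1], x$coords[, 2], circles = r,
                    inches = FALSE, add = TRUE, fg = col,
                    bg = grDevices::adjustcolor(col, 0.4))
  graphics::text(x$coords[, 1], x$coords[, 2],
                 paste0(x$sample, x$label), cex = 0.7)
  invisible(x)
}

#' Agglomerative QF-tree of one sample's clusters
#'
#' Builds a bottom-up hierarchy of the clusters under the dissimilarity
#' `QF + c * DM`, where `QF` is the quadratic-form score of the pair (each
#' pair of groups rebinned as a two-sample comparison), `DM` the Euclidean
#' distance between group medians, and `c` a scaling factor computed once
#' as (smallest pairwise QF) / (largest pairwise DM) so both terms are of
#' the same order of magnitude. At every level the closest two groups merge
#' and are treated as one pooled cluster; dissimilarities are then
#' recomputed against the merged group. Merge heights are clamped to be
#' monotone (with a warning) since the dissimilarity is recomputed per
#' level.
#'
#' @param x A [sic_events()] object or event matrix.
#' @param labels Integer cluster labels, one per event.
#' @param channels Channels to use; default all.
#' @param cfg A [sic_config()].
#' @return An object of class `qf_tree` with hclust-style `merge` and
#'   `height`, per-merge `qf` and `dm` components, `scale_c` and `labels`.
#' @export
qf_tree <- function(x, labels, channels = NULL, cfg = sic_config()) {
  values <- event_values(x)
  dims <- if (is.null(channels)) seq_len(ncol(values)) else {
    if (inherits(x, "sic_events")) resolve_channels(x, channels)
    else if (is.numeric(channels)) as.integer(channels)
    else match(channels, colnames(values))
  }
  subs <- make_subsets(values, labels, dims = dims)
  k <- length(subs)
  if (k < 2L) stop("insufficient data: need at least 2 clusters for a tree")

  groups <- lapply(subs, function(s) s$indices)
  medians <- lapply(subs, function(s) s$median)

  pair_qf <- function(gi, gj) {
    bi <- adaptive_bin(values[gi, dims, drop = FALSE],
                       values[gj, dims, drop = FALSE])
    sim <- bin_similarity(bi)
    f <- tabulate(assign_bins(bi, values[gi, dims, drop = FALSE]),
                  nbins = bi$B) / length(gi)
    g <- tabulate(assign_bins(bi, values[gj, dims, drop = FALSE]),
                  nbins = bi$B) / length(gj)
    qf_distance(f, g, sim)
  }
  pair_dm <- function(mi, mj) sqrt(sum((mi - mj)^2))

  qf0 <- matrix(NA_real_, k, k)
  dm0 <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      qf0[i, j] <- pair_qf(groups[[i]], groups[[j]])
      dm0[i, j] <- pair_dm(medians[[i]], medians[[j]])
    }
  }
  max_dm <- max(dm0, na.rm = TRUE)
  scale_c <- if (max_dm > 0) min(qf0, na.rm = TRUE) / max_dm else 0
  if (max_dm == 0) {
    warning("all cluster medians coincide; falling back to pure QF scores")
  }

  # Agglomeration in hclust encoding: negative ids are original clusters,
  # positive ids are earlier merges.
  active <- as.list(-(seq_len(k)))
  act_groups <- groups
  act_medians <- medians
  qf_m <- qf0; dm_m <- dm0
  merge <- matrix(0L, k - 1L, 2L)
  height <- numeric(k - 1L)
  qf_of <- numeric(k - 1L)
  dm_of <- numeric(k - 1L)
  clamped <- FALSE
  for (step in seq_len(k - 1L)) {
    diss <- qf_m + scale_c * dm_m
    idx <- which(diss == min(diss, na.rm = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- min(idx); j <- max(idx)
    h <- diss[i, j]
    if (step > 1L && h < height[step - 1L]) {
      h <- height[step - 1L]
      clamped <- TRUE
    }
    merge[step, ] <- c(active[[i]], active[[j]])
    height[step] <- h
    qf_of[step] <- qf_m[i, j]
    dm_of[step] <- dm_m[i, j]

    new_group <- c(act_groups[[i]], act_groups[[j]])
    new_median <- apply(values[new_group, dims, drop = FALSE], 2,
                        stats::median)
    keep <- setdiff(seq_along(active), c(i, j))
    active <- c(active[keep], list(step))
    act_groups <- c(act_groups[keep], list(new_group))
    act_medians <- c(act_medians[keep], list(new_median))
    m <- length(active)
    nq <- matrix(NA_real_, m, m); nd <- matrix(NA_real_, m, m)
    if (m > 1L) {
      old_pos <- keep
      nq[seq_len(m - 1L), seq_len(m - 1L)] <-
        qf_m[old_pos, old_pos, drop = FALSE]
      nd[seq_len(m - 1L), seq_len(m - 1L)] <-
        dm_m[old_pos, old_pos, drop = FALSE]
      for (t in seq_len(m - 1L)) {
        nq[t, m] <- pair_qf(act_groups[[t]], new_group)
        nd[t, m] <- pair_dm(act_medians[[t]], new_median)
      }
    }
    qf_m <- nq; dm_m <- nd
  }
  if (clamped) {
    warning("merge heights were clamped to preserve monotonicity")
  }
  structure(
    list(merge = merge, height = height, qf = qf_of, dm = dm_of,
         scale_c = scale_c, labels = vapply(subs, `[[`, integer(1), "label"),
         frequencies = vapply(subs, `[[`, numeric(1), "frequency"),
         dims = dims),
    class = "qf_tree"
  )
}

#' @export
print.qf_tree <- function(x, ...) {
  k <- length(x$labels)
  cat(sprintf("QF-tree of %d clusters (scaling c = %.4g)\n", k, x$scale_c))
  for (s in seq_len(k - 1L)) {
    nm <- function(id) if (id < 0) paste0("cluster ", x$labels[-id]) else
      paste0("node ", id)
    cat(sprintf("  merge %d: %s + %s at height %.4g (QF %.4g, DM %.4g)\n",
                s, nm(x$merge[s, 1]), nm(x$merge[s, 2]), x$height[s],
                x$qf[s], x$dm[s]))
  }
  invisible(x)
}

#' @export
as.hclust.qf_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height,
         order = hclust_order(x$merge),
         labels = paste0("cluster_", x$labels),
         method = "qf_tree", dist.method = "qf+c*dm"),
    class = "hclust"
  )
}

# Leaf order for plotting an hclust-encoded merge matrix.
hclust_order <- function(merge) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1]), walk(merge[id, 2]))
  }
  walk(nrow(merge))
}

#' @export
plot.qf_tree <- function(x, ...) {
  graphics::plot(as.hclust.qf_tree(x),
                 main = "QF-tree", xlab = "", sub = "",
                 ylab = "QF + c*DM dissimilarity", ...)
  invisible(x)
}

#' Convert a QF-tree to an ape phylogeny
#'
#' Edge lengths are the QF component of each merge (both child edges of a
#' merge carry its QF score), matching the display convention that edge
#' length corresponds to the quadratic-form score.
#'
#' @param x A [qf_tree()] object.
#' @return An `ape::phylo` object.
#' @export
qf_tree_phylo <- function(x) {
  k <- length(x$labels)
  n_int <- k - 1L
  # phylo numbering: tips 1..k, root k+1, internal nodes follow.
  node_of_merge <- integer(n_int)
  node_of_merge[n_int] <- k + 1L
  if (n_int > 1L) {
    node_of_merge[seq_len(n_int - 1L)] <- k + 1L + rev(seq_len(n_int - 1L))
  }
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  for (s in seq_len(n_int)) {
    for (child in x$merge[s, ]) {
      to <- if (child < 0) -child else node_of_merge[child]
      edges <- rbind(edges, c(node_of_merge[s], to))
      lens <- c(lens, x$qf[s])
    }
  }
  structure(
    list(edge = edges, edge.length = lens,
         Nnode = n_int, tip.label = paste0("cluster_", x$labels)),
    class = "phylo"
  )
}

#' Write a QF-tree as Newick
#'
#' @param x A [qf_tree()] object.
#' @param path Output path; `NULL` returns the Newick string.
#' @return The path or Newick string, invisibly.
#' @export
write_qf_tree_newick <- function(x, path = NULL) {
  ph <- qf_tree_phylo(x)
  if (is.null(path)) {
    return(invisible(ape::write.tree(ph)))
  }
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Render a layout or tree to an image plus machine-readable export
#'
#' Writes a PNG of the display and, next to it, a machine-readable export:
#' a coordinates CSV for MDS layouts, a Newick file for QF-trees.
#'
#' @param x A `sic_mds` or `qf_tree` object.
#' @param path Output image path (`.png`).
#' @return Named character vector of written paths, invisibly.
#' @export
sic_render <- function(x, path) {
  grDevices::png(path, width = 900, height = 700, res = 110)
  ok <- tryCatch({ plot(x); TRUE }, finally = grDevices::dev.off())
  if (inherits(x, "sic_mds")) {
    export <- sub("\\.png$", "_coords.csv", path)
    utils::write.csv(
      data.frame(sample = x$sample, cluster = x$label,
                 mds1 = x$coords[, 1], mds2 = x$coords[, 2],
                 radius = x$radii, group = x$group),
      export, row.names = FALSE)
  } else if (inherits(x, "qf_tree")) {
    export <- sub("\\.png$", ".nwk", path)
    write_qf_tree_newick(x, export)
  } else {
    stop("sic_render handles 'sic_mds' and 'qf_tree' objects")
  }
  invisible(c(image = path, export = export))
}
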