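# Binned kernel density estimation on a regular grid, plus the mode-seeking
# cluster step and the decision-boundary misclassification index used by
# projection pursuit.

# Gaussian KDE of 1D/2D-binned counts on fixed cell centers. Returns the
# density at cell centers, normalized so sum(density) * cell_area == 1.
kde_on_grid <- function(points, edges_x, edges_y, h) {
  gx <- length(edges_x) - 1L
  gy <- length(edges_y) - 1L
  ix <- pmin(pmax(findInterval(points[, 1], edges_x, rightmost.closed = TRUE), 1L), gx)
  iy <- pmin(pmax(findInterval(points[, 2], edges_y, rightmost.closed = TRUE), 1L), gy)
  counts <- matrix(0, gx, gy)
  tab <- table(factor(ix, levels = seq_len(gx)), factor(iy, levels = seq_len(gy)))
  counts[] <- as.numeric(tab)
  cx <- (edges_x[-1] + edges_x[-length(edges_x)]) / 2
  cy <- (edges_y[-1] + edges_y[-length(edges_y)]) / 2
  kx <- stats::dnorm(outer(cx, cx, "-"), sd = h[1])
  ky <- stats::dnorm(outer(cy, cy, "-"), sd = h[2])
  dens <- kx %*% counts %*% t(ky)
  cell_area <- mean(diff(edges_x)) * mean(diff(edges_y))
  s <- sum(dens) * cell_area
  if (s <= 0) stop("degenerate density: all mass outside the grid")
  dens / s
}

#' Estimate a 2D density on a regular grid
#'
#' Binned Gaussian kernel density estimate with per-axis Silverman
#' rule-of-thumb bandwidths ([stats::bw.nrd0()]). The grid spans the data
#' range padded by three bandwidths on each side and the returned density
#' integrates to one.
#'
#' @param points Numeric n x 2 matrix of finite coordinates.
#' @param grid_size Cells per axis; requires `n >= 2 * grid_size`.
#' @param bandwidth Optional per-axis bandwidths overriding Silverman's rule.
#' @return A list of class `density_grid` with `cell_edges` (list of two
#'   edge vectors), `centers`, `density` (grid_size x grid_size matrix),
#'   `bandwidth` and `cell_area`.
#' @export
estimate_density <- function(points, grid_size = 128L, bandwidth = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L)
  n <- nrow(points)
  if (n < 2L * grid_size) {
    stop("insufficient data: need at least ", 2L * grid_size,
         " points for a ", grid_size, "-cell grid (got ", n, ")")
  }
  if (any(!is.finite(points))) stop("points must be finite")
  h <- if (is.null(bandwidth)) {
    c(stats::bw.nrd0(points[, 1]), stats::bw.nrd0(points[, 2]))
  } else {
    rep_len(as.numeric(bandwidth), 2L)
  }
  if (any(h <= 0) || stats::sd(points[, 1]) == 0 || stats::sd(points[, 2]) == 0) {
    stop("degenerate axis: zero variance along axis ",
         which(c(stats::sd(points[, 1]), stats::sd(points[, 2])) == 0)[1])
  }
  edges <- lapply(1:2, function(j) {
    seq(min(points[, j]) - 3 * h[j], max(points[, j]) + 3 * h[j],
        length.out = grid_size + 1L)
  })
  dens <- kde_on_grid(points, edges[[1]], edges[[2]], h)
  centers <- lapply(edges, function(e) (e[-1] + e[-length(e)]) / 2)
  structure(
    list(grid_size = as.integer(grid_size), cell_edges = edges,
         centers = centers, density = dens, bandwidth = h,
         cell_area = mean(diff(edges[[1]])) * mean(diff(edges[[2]]))),
    class = "density_grid"
  )
}

# Offsets of the 8-neighborhood, fixed order (self handled separately).
.nb_off <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                 dj = c(-1, 0, 1, -1, 1, -1, 0, 1))

# For every cell, the linear index of its highest-density 8-neighbor
# (itself when no strictly denser neighbor exists -> density mode).
steepest_neighbor <- function(dens) {
  g1 <- nrow(dens); g2 <- ncol(dens)
  pad <- matrix(-Inf, g1 + 2L, g2 + 2L)
  pad[2:(g1 + 1L), 2:(g2 + 1L)] <- dens
  self_idx <- matrix(seq_len(g1 * g2), g1, g2)
  best_val <- dens
  best_idx <- self_idx
  for (k in seq_len(nrow(.nb_off))) {
    di <- .nb_off[k, 1]; dj <- .nb_off[k, 2]
    nb_val <- pad[(2 + di):(g1 + 1 + di), (2 + dj):(g2 + 1 + dj)]
    nb_idx_row <- matrix(rep(seq_len(g1) + di, g2), g1, g2)
    nb_idx_col <- matrix(rep(seq_len(g2) + dj, each = g1), g1, g2)
    nb_idx <- (nb_idx_col - 1L) * g1 + nb_idx_row
    upd <- nb_val > best_val
    best_val[upd] <- nb_val[upd]
    best_idx[upd] <- nb_idx[upd]
  }
  best_idx
}

# Saddle table between basins: for each pair of adjacent basins the highest
# density of a shared boundary (max over touching cell pairs of the lower
# of the two cell densities).
basin_saddles <- function(dens, basin) {
  g1 <- nrow(dens); g2 <- ncol(dens)
  pairs <- list()
  for (k in seq_len(nrow(.nb_off))) {
    di <- .nb_off[k, 1]; dj <- .nb_off[k, 2]
    ri <- max(1, 1 - di):min(g1, g1 - di)
    rj <- max(1, 1 - dj):min(g2, g2 - dj)
    b0 <- basin[ri, rj]
    b1 <- basin[ri + di, rj + dj]
    ok <- b0 > 0L & b1 > 0L & b0 != b1
    if (!any(ok)) next
    v <- pmin(dens[ri, rj][ok], dens[ri + di, rj + dj][ok])
    lo <- pmin(b0[ok], b1[ok]); hi <- pmax(b0[ok], b1[ok])
    pairs[[length(pairs) + 1L]] <- cbind(lo, hi, v)
  }
  if (length(pairs) == 0L) {
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("lo", "hi", "v"))))
  }
  tab <- do.call(rbind, pairs)
  key <- paste(tab[, 1], tab[, 2])
  agg <- tapply(tab[, 3], key, max)
  ids <- do.call(rbind, strsplit(names(agg), " "))
  cbind(lo = as.integer(ids[, 1]), hi = as.integer(ids[, 2]),
        v = as.numeric(agg))
}

#' Density-based clustering of a 2D point set
#'
#' Simplified density-based merging: modes of a binned kernel density grid
#' seed clusters, cells hill-climb to their mode, and weakly separated
#' modes merge when the highest saddle density between their basins exceeds
#' a fraction `theta` of the lower peak density. Cells with density below
#' `outlier_frac` of the peak are initially unclustered; their events are
#' then assigned to the nearest cluster by Euclidean distance to cluster
#' member events, so every event receives a label.
#'
#' @param points Numeric n x 2 matrix, `n >= 50`.
#' @param grid_size Cells per axis (reduced automatically for small n).
#' @param theta Saddle/peak mode-merging threshold in (0, 1).
#' @param prominence Minimum topographic prominence of a mode, as a
#'   fraction of the global peak density; less prominent modes merge into
#'   (or dissolve towards) their strongest neighbour.
#' @param outlier_frac Low-density cutoff as a fraction of the peak density.
#' @return A list of class `clustering2d` with `labels` (integer, all
#'   `>= 1`), `n_clusters`, `mode_cells`, `adjacency` (cluster adjacency
#'   matrix) and the underlying `grid`.
#' @export
cluster_2d <- function(points, grid_size = 128L, theta = 0.85,
                       prominence = 0.05, outlier_frac = 1e-4) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 50L) stop("insufficient data: need at least 50 points (got ", n, ")")
  grid_size <- as.integer(min(grid_size, n %/% 2L))
  grid <- estimate_density(points, grid_size = grid_size)
  dens <- grid$density
  peak <- max(dens)
  active <- dens >= outlier_frac * peak

  ptr <- steepest_neighbor(dens)
  # Resolve each cell to its mode by pointer chasing.
  root <- as.vector(ptr)
  repeat {
    nxt <- root[root]
    if (identical(nxt, root)) break
    root <- nxt
  }
  basin <- matrix(0L, grid_size, grid_size)
  basin[active] <- match(root[as.vector(active)], sort(unique(root[as.vector(active)])))
  n_basin <- max(basin)

  # Merge insignificant modes. Two adjacent basins merge when the mode
  # separation is weak in either sense: the saddle density exceeds theta of
  # the lower peak (shallow valley), or the lower peak's topographic
  # prominence (peak minus saddle) is below prominence * global peak (noise
  # wiggle of the kernel estimate). Strongest connections merge first.
  peak_of <- vapply(seq_len(n_basin), function(b) max(dens[basin == b]), numeric(1))
  map <- seq_len(n_basin)
  repeat {
    cur <- matrix(0L, grid_size, grid_size)
    cur[active] <- map[basin[active]]
    sad <- basin_saddles(dens, cur)
    if (nrow(sad) == 0L) break
    cur_peak <- vapply(seq_len(n_basin), function(b) {
      max(peak_of[map == map[b]])
    }, numeric(1))
    lower <- pmin(cur_peak[sad[, "lo"]], cur_peak[sad[, "hi"]])
    ratio <- sad[, "v"] / lower
    qualify <- ratio > theta | (lower - sad[, "v"]) < prominence * peak
    if (!any(qualify)) break
    k <- which(qualify)[which.max(ratio[qualify])]
    from <- map[sad[k, "hi"]]; to <- map[sad[k, "lo"]]
    map[map == from] <- to
  }
  # Dissolve surviving low-peak basins with no qualifying neighbour (noise
  # islands disconnected from the bulk): their cells become outlier cells.
  cur_peak <- vapply(seq_len(n_basin), function(b) {
    max(peak_of[map == map[b]])
  }, numeric(1))
  weak <- cur_peak[basin[active]] < prominence * peak
  if (any(weak) && !all(weak)) {
    act_idx <- which(active)
    active[act_idx[weak]] <- FALSE
  }
  final <- matrix(0L, grid_size, grid_size)
  final[active] <- match(map[basin[active]], sort(unique(map[basin[active]])))
  k_final <- max(final)

  # Cluster adjacency after merging (used for split enumeration upstream).
  adj <- matrix(FALSE, k_final, k_final)
  sad <- basin_saddles(dens, final)
  if (nrow(sad) > 0L) {
    adj[sad[, c("lo", "hi"), drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
  }

  # Events -> cells -> clusters; outlier-cell events to nearest member event.
  ix <- pmin(pmax(findInterval(points[, 1], grid$cell_edges[[1]],
                               rightmost.closed = TRUE), 1L), grid_size)
  iy <- pmin(pmax(findInterval(points[, 2], grid$cell_edges[[2]],
                               rightmost.closed = TRUE), 1L), grid_size)
  raw <- final[cbind(ix, iy)]
  un <- which(raw == 0L)
  as_ <- which(raw > 0L)
  if (length(un) > 0L) {
    for (chunk in split(un, ceiling(seq_along(un) / 256L))) {
      d2 <- outer(points[chunk, 1], points[as_, 1], "-")^2 +
        outer(points[chunk, 2], points[as_, 2], "-")^2
      raw[chunk] <- raw[as_[max.col(-d2, ties.method = "first")]]
    }
  }
  # Renumber clusters by first appearance in event order (deterministic and
  # invariant to internal basin numbering).
  old_of_new <- unique(raw)
  labels <- match(raw, old_of_new)

  mode_cells <- t(vapply(seq_len(k_final), function(b) {
    cells <- which(final == b, arr.ind = TRUE)
    if (is.null(dim(cells))) cells <- matrix(cells, 1)
    cells[which.max(dens[cells]), ]
  }, numeric(2)))

  # Some basins can lose every event to others via outlier reassignment;
  # keep only clusters that own events, in event-order numbering.
  k_out <- length(old_of_new)
  adj_out <- adj[old_of_new, old_of_new, drop = FALSE]
  structure(
    list(labels = labels, n_clusters = k_out,
         mode_cells = mode_cells[old_of_new, , drop = FALSE],
         adjacency = adj_out, grid = grid,
         cell_of_event = cbind(ix, iy)),
    class = "clustering2d"
  )
}

#' Misclassification index across a decision boundary
#'
#' Estimated Bayes error of the two-class problem defined by assigning each
#' cluster to one of two sides: the densities of the two sides are
#' estimated on a shared grid and the overlap
#' `sum(min(pi1 * p1, pi2 * p2)) * cell_area` is returned. Symmetric in the
#' two sides and bounded by `[0, 0.5]`.
#'
#' @param points Numeric n x 2 matrix.
#' @param clustering A [cluster_2d()] result for `points`.
#' @param sides Integer vector (values 1 or 2), one entry per cluster.
#' @param grid_size Cells per axis of the shared evaluation grid.
#' @return Estimated misclassification error in `[0, 0.5]`.
#' @export
boundary_error <- function(points, clustering, sides, grid_size = 128L) {
  points <- as.matrix(points)
  stopifnot(length(sides) == clustering$n_clusters,
            all(sides %in% c(1L, 2L)))
  ev_side <- sides[clustering$labels]
  n1 <- sum(ev_side == 1L); n2 <- sum(ev_side == 2L)
  if (n1 == 0L || n2 == 0L) stop("invalid split: one side has no events")
  grid_size <- as.integer(min(grid_size, nrow(points) %/% 2L))
  h <- c(stats::bw.nrd0(points[, 1]), stats::bw.nrd0(points[, 2]))
  edges <- lapply(1:2, function(j) {
    seq(min(points[, j]) - 3 * h[j], max(points[, j]) + 3 * h[j],
        length.out = grid_size + 1L)
  })
  p1 <- kde_on_grid(points[ev_side == 1L, , drop = FALSE],
                    edges[[1]], edges[[2]], h)
  p2 <- kde_on_grid(points[ev_side == 2L, , drop = FALSE],
                    edges[[1]], edges[[2]], h)
  pi1 <- n1 / (n1 + n2); pi2 <- n2 / (n1 + n2)
  cell_area <- mean(diff(edges[[1]])) * mean(diff(edges[[2]]))
  min(0.5, sum(pmin(pi1 * p1, pi2 * p2)) * cell_area)
}
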