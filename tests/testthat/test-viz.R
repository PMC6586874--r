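# Cluster-level displays: MDS of medians and the QF-tree.

mk_subset <- function(label, median, freq = 0.25) {
  list(label = as.integer(label), median = median,
       sd = rep(1, length(median)), frequency = freq, n = 100L,
       indices = integer(0))
}

test_that("classical MDS recovers planar configurations exactly", {
  # A 3-4-5 right triangle embedded in 5 dimensions.
  subs <- list(mk_subset(1, c(0, 0, 0, 0, 0)),
               mk_subset(2, c(3, 0, 0, 0, 0)),
               mk_subset(3, c(0, 4, 0, 0, 0)))
  lay <- mds_embed(subs)
  d <- as.matrix(stats::dist(lay$coords))
  expect_equal(sort(c(d[1, 2], d[1, 3], d[2, 3])), c(3, 4, 5),
               tolerance = 1e-9)
  # Deterministic: identical call, identical coordinates.
  expect_identical(lay$coords, mds_embed(subs)$coords)
})

test_that("two clusters embed at their true median distance", {
  subs <- list(mk_subset(1, c(1, 2, 3)), mk_subset(2, c(4, 6, 3)))
  lay <- mds_embed(subs)
  expect_equal(as.numeric(stats::dist(lay$coords)), 5, tolerance = 1e-9)
  expect_error(mds_embed(subs[1]), "insufficient data")
})

test_that("joint embeddings preserve the rank order of median distances", {
  sim <- canonical_sim(1L)
  sa <- make_subsets(sim$events_a$values, sim$labels_a)
  sb <- make_subsets(sim$events_b$values, sim$labels_b)
  lay <- mds_embed(sa, sb)
  true_d <- stats::dist(rbind(t(vapply(sa, `[[`, numeric(3), "median")),
                              t(vapply(sb, `[[`, numeric(3), "median"))))
  emb_d <- stats::dist(lay$coords)
  expect_gte(stats::cor(as.numeric(true_d), as.numeric(emb_d),
                        method = "spearman"), 0.9)
  # Matched clusters share a colour group.
  m <- qfmatch(sim$events_a, sim$events_b,
               labels_a = sim$labels_a, labels_b = sim$labels_b)
  lay2 <- mds_embed(sa, sb, match = m)
  g_a1 <- lay2$group[lay2$sample == "A" & lay2$label == 1L]
  g_b1 <- lay2$group[lay2$sample == "B" & lay2$label == 1L]
  expect_gt(g_a1, 0)
  expect_equal(g_a1, g_b1)
  # Radii encode frequency: area proportional to relative frequency.
  expect_equal(lay2$radii[1]^2,
               sa[[1]]$frequency, tolerance = 1e-12)
})

test_that("the two-cluster QF-tree applies the scaling rule exactly", {
  set.seed(61)
  vals <- rbind(matrix(stats::rnorm(2000), 1000, 2),
                matrix(stats::rnorm(2000, 6), 1000, 2))
  labs <- rep(1:2, each = 1000)
  tr <- qf_tree(vals, labs)
  # With one pair, c = QF/DM so the merge height is exactly 2 * QF.
  expect_equal(tr$scale_c, tr$qf[1] / tr$dm[1], tolerance = 1e-12)
  expect_equal(tr$height[1], 2 * tr$qf[1], tolerance = 1e-12)
  expect_error(qf_tree(vals, rep(1L, nrow(vals))), "insufficient data")
})

test_that("the split component merges first in the canonical QF-tree", {
  sim <- canonical_sim(1L)
  tr <- suppressWarnings(qf_tree(sim$events_b$values, sim$labels_b))
  expect_equal(sort(-tr$merge[1, ]), c(3L, 4L))
  expect_true(all(diff(tr$height) >= -1e-12))
  expect_gt(tr$scale_c, 0)
  expect_setequal(tr$labels, 1:4)
})

test_that("QF-trees export as Newick parseable by an independent reader", {
  sim <- canonical_sim(1L)
  tr <- suppressWarnings(qf_tree(sim$events_b$values, sim$labels_b))
  p <- withr::local_tempfile(fileext = ".nwk")
  write_qf_tree_newick(tr, p)
  ph <- ape::read.tree(p)
  expect_equal(length(ph$tip.label), 4L)
  expect_equal(ph$Nnode, 3L)
  expect_setequal(ph$tip.label, paste0("cluster_", 1:4))
  # Edge lengths are the QF components of the merges.
  expect_setequal(round(unique(ph$edge.length), 9), round(unique(tr$qf), 9))
  # hclust conversion is plottable and preserves leaf count.
  hc <- as.hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_equal(length(hc$order), 4L)
})

test_that("rendering writes an image plus a machine-readable export", {
  subs <- list(mk_subset(1, c(0, 0)), mk_subset(2, c(5, 0)),
               mk_subset(3, c(0, 7)))
  lay <- mds_embed(subs)
  img <- withr::local_tempfile(fileext = ".png")
  paths <- sic_render(lay, img)
  expect_true(all(file.exists(paths)))
  coords <- utils::read.csv(paths["export"])
  expect_equal(nrow(coords), 3L)

  sim <- canonical_sim(1L)
  tr <- suppressWarnings(qf_tree(sim$events_b$values, sim$labels_b))
  img2 <- withr::local_tempfile(fileext = ".png")
  paths2 <- sic_render(tr, img2)
  expect_true(all(file.exists(paths2)))
})
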