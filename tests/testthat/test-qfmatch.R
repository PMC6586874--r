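# Cluster matching: gating, greedy assignment, merge resolution.

test_that("the median gate admits close pairs and rejects distant ones", {
  mk <- function(med, sd) list(median = med, sd = sd)
  a <- mk(c(0, 0, 0), c(1, 1, 1))
  expect_true(median_gate(a, a))
  expect_true(median_gate(a, mk(c(3.9, 0, 0), c(1, 1, 1))))
  expect_false(median_gate(a, mk(c(5, 0, 0), c(1, 1, 1))))
  # The wider of the two SDs sets the scale per dimension.
  expect_true(median_gate(a, mk(c(7, 0, 0), c(2, 1, 1))))
  # Zero-SD dimensions require exact equality.
  z <- mk(c(0, 0), c(0, 1))
  expect_true(median_gate(z, mk(c(0, 0.5), c(0, 1))))
  expect_false(median_gate(z, mk(c(1e-9, 0), c(0, 1))))
  expect_error(median_gate(a, z), "shape error")
})

test_that("matching a sample against itself is the identity with zero scores", {
  sim <- canonical_sim(1L)
  m <- qfmatch(sim$events_a, sim$events_a,
               labels_a = sim$labels_a, labels_b = sim$labels_a)
  expect_equal(length(m$matches), 3L)
  expect_equal(length(m$missing), 0L)
  for (x in m$matches) {
    expect_equal(x$a_labels, x$b_labels)
    expect_lt(x$score, 1e-9)
    expect_identical(x$kind, "match")
  }
})

test_that("the canonical fixture reproduces the expected alignment", {
  sim <- canonical_sim(1L)
  m <- qfmatch(sim$events_a, sim$events_b,
               labels_a = sim$labels_a, labels_b = sim$labels_b)
  # Pre-merge stage: three greedy matches, B side holds one candidate.
  expect_equal(length(m$pre_merge), 3L)
  expect_equal(length(m$candidates$A), 0L)
  expect_equal(length(m$candidates$B), 1L)
  expect_true(m$candidates$B %in% c(3L, 4L))
  # Final: A1-B1, A2-B2 matches and the A3 split into B3+B4.
  expect_setequal(match_signature(m),
                  c("A{1}~B{1}:match", "A{2}~B{2}:match", "A{3}~B{3,4}:split"))
  # The merged score undercuts the candidate's initial score.
  split <- Filter(function(x) x$kind == "split", m$matches)[[1]]
  cand_initial <- m$scores[3, m$candidates$B]
  expect_lt(split$score, cand_initial)
  # Distant pairs were gated out (blank cells of the candidate table).
  expect_true(all(is.na(m$scores[1, 2:4])))
  expect_true(all(is.na(m$scores[2, c(1, 3, 4)])))
  expect_true(all(is.na(m$scores[3, 1:2])))
  # Scored cells are symmetric in construction: rebuilt transposed match.
  mt <- qfmatch(sim$events_b, sim$events_a,
                labels_a = sim$labels_b, labels_b = sim$labels_a)
  expect_equal(t(mt$scores), m$scores, tolerance = 1e-9)
})

test_that("every cluster is accounted for exactly once", {
  sim <- canonical_sim(2L)
  m <- qfmatch(sim$events_a, sim$events_b,
               labels_a = sim$labels_a, labels_b = sim$labels_b)
  seen_a <- c(unlist(lapply(m$matches, `[[`, "a_labels")),
              vapply(Filter(function(x) x$sample == "A", m$missing),
                     `[[`, integer(1), "label"))
  seen_b <- c(unlist(lapply(m$matches, `[[`, "b_labels")),
              vapply(Filter(function(x) x$sample == "B", m$missing),
                     `[[`, integer(1), "label"))
  expect_equal(sort(seen_a), sort(unique(sim$labels_a)))
  expect_equal(sort(seen_b), sort(unique(sim$labels_b)))
})

test_that("matching is invariant to cluster label permutation", {
  sim <- canonical_sim(1L)
  perm <- c(3L, 1L, 4L, 2L)  # relabel B clusters
  lb2 <- perm[sim$labels_b]
  m1 <- qfmatch(sim$events_a, sim$events_b,
                labels_a = sim$labels_a, labels_b = sim$labels_b)
  m2 <- qfmatch(sim$events_a, sim$events_b,
                labels_a = sim$labels_a, labels_b = lb2)
  sig2_unpermuted <- vapply(m2$matches, function(x) {
    sprintf("A{%s}~B{%s}:%s", paste(sort(x$a_labels), collapse = ","),
            paste(sort(match(x$b_labels, perm)), collapse = ","), x$kind)
  }, character(1))
  expect_setequal(match_signature(m1), sig2_unpermuted)
})

test_that("a cluster far from everything is reported missing", {
  spec_a <- mixture_spec(rbind(c(0, 0), c(20, 0)), sds = 1,
                         counts = c(1500L, 1500L))
  spec_b <- mixture_spec(rbind(c(0, 0), c(20, 0), c(300, 300)), sds = 1,
                         counts = c(1500L, 1500L, 1000L))
  sim <- simulate_pair(spec_a, spec_b, seed = 9)
  m <- qfmatch(sim$events_a, sim$events_b,
               labels_a = sim$labels_a, labels_b = sim$labels_b)
  expect_equal(length(m$missing), 1L)
  expect_identical(m$missing[[1]]$sample, "B")
  expect_equal(m$missing[[1]]$label, 3L)
  expect_equal(length(m$matches), 2L)
})

test_that("input validation catches malformed calls", {
  sim <- canonical_sim(1L)
  expect_error(qfmatch(sim$events_a, sim$events_b,
                       labels_a = sim$labels_a[-1],
                       labels_b = sim$labels_b),
               "label/event count mismatch")
  expect_error(qfmatch(sim$events_a, sim$events_b, labels_a = sim$labels_a),
               "labels are required")
  expect_error(qfmatch(sim$events_a, sim$events_b,
                       labels_a = sim$labels_a, labels_b = sim$labels_b,
                       channels = "nope"), "unknown channel")
})

test_that("the match report serializes with one row per alignment", {
  sim <- canonical_sim(1L)
  m <- qfmatch(sim$events_a, sim$events_b,
               labels_a = sim$labels_a, labels_b = sim$labels_b)
  p <- withr::local_tempfile(fileext = ".csv")
  write_match_csv(m, p)
  rep <- utils::read.csv(p, colClasses = c("character", "character",
                                           "numeric", "character"))
  expect_equal(nrow(rep), length(m$matches) + length(m$missing))
  expect_true("3+4" %in% rep$b_labels)
})
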