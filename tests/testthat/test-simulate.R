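# Synthetic paired-sample generator.

test_that("identical spec and seed give bit-identical output", {
  spec <- mixture_spec(rbind(c(0, 0)), sds = 1, counts = 100L)
  s1 <- simulate_pair(spec, spec, seed = 7)
  s2 <- simulate_pair(spec, spec, seed = 7)
  expect_identical(s1$events_a$values, s2$events_a$values)
  expect_identical(s1$events_b$values, s2$events_b$values)
  s3 <- simulate_pair(spec, spec, seed = 8)
  expect_false(identical(s1$events_a$values, s3$events_a$values))
})

test_that("the session RNG state is left untouched", {
  set.seed(99)
  before <- .Random.seed
  spec <- mixture_spec(rbind(c(0, 0)), sds = 1, counts = 10L)
  invisible(simulate_pair(spec, spec, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("component moments converge to the specification", {
  spec <- mixture_spec(rbind(c(2, -3, 5), c(20, 0, 0)),
                       sds = rbind(c(1, 2, 0.5), c(1, 1, 1)),
                       counts = c(10000L, 10000L))
  sim <- simulate_pair(spec, spec, seed = 5)
  for (k in 1:2) {
    rows <- sim$labels_a == k
    n <- sum(rows)
    for (j in 1:3) {
      se <- spec$sds[k, j] / sqrt(n)
      expect_lt(abs(mean(sim$events_a$values[rows, j]) - spec$means[k, j]),
                5 * se)
      sd_se <- spec$sds[k, j] / sqrt(2 * (n - 1))
      expect_lt(abs(stats::sd(sim$events_a$values[rows, j]) - spec$sds[k, j]),
                5 * sd_se)
    }
  }
})

test_that("a single-event component yields exactly one labelled draw", {
  spec <- mixture_spec(rbind(c(0, 0), c(50, 50)), sds = 1,
                       counts = c(5L, 1L))
  sim <- simulate_pair(spec, spec, seed = 3)
  expect_equal(sum(sim$labels_a == 2L), 1L)
  expect_equal(nrow(sim$events_a$values), 6L)
})

test_that("spec validation rejects invalid mixtures", {
  expect_error(mixture_spec(rbind(c(0, 0)), sds = 0, counts = 10L), "SDs")
  expect_error(mixture_spec(rbind(c(0, 0)), sds = 1, counts = 0L), "counts")
  expect_error(mixture_spec(rbind(c(0, 0), c(1, 1)), sds = 1,
                            counts = c(5L, 5L), group_ids = c(1L, 1L)),
               "unique")
})

test_that("the canonical fixture encodes the expected structure", {
  specs <- canonical_pair_specs()
  expect_identical(specs, canonical_pair_specs())  # pure function
  expect_equal(nrow(specs$spec_a$means), 3L)
  expect_equal(nrow(specs$spec_b$means), 4L)
  expect_true(sum(specs$spec_a$counts) >= 1e4 &&
                sum(specs$spec_a$counts) <= 5e4)
  expect_true(sum(specs$spec_b$counts) >= 1e4 &&
                sum(specs$spec_b$counts) <= 5e4)
  # B3 + B4 jointly occupy A3's region: equal mixture mean, 3 SD apart,
  # combined count within 10% of A3's.
  b34 <- colMeans(specs$spec_b$means[3:4, ])
  expect_equal(b34, specs$spec_a$means[3, ], ignore_attr = TRUE)
  sep34 <- sqrt(sum((specs$spec_b$means[3, ] - specs$spec_b$means[4, ])^2))
  expect_equal(sep34 / max(specs$spec_b$sds[3:4, ]), 3)
  expect_lt(abs(sum(specs$spec_b$counts[3:4]) - specs$spec_a$counts[3]) /
              specs$spec_a$counts[3], 0.1)
  # A components pairwise separated by at least 8 pooled SD.
  for (i in 1:2) for (j in (i + 1):3) {
    d <- sqrt(sum((specs$spec_a$means[i, ] - specs$spec_a$means[j, ])^2))
    pooled <- max(specs$spec_a$sds[c(i, j), ])
    expect_gte(d / pooled, 8)
  }
  # Metadata records the expected alignment including the split.
  kinds <- vapply(specs$expected, `[[`, character(1), "kind")
  expect_identical(kinds, c("match", "match", "split"))
  expect_equal(specs$expected[[3]]$b_groups, c(3L, 4L))
})

test_that("simulated pairs serialize to disk with labels and metadata", {
  spec <- mixture_spec(rbind(c(0, 0), c(9, 9)), sds = 1, counts = c(60L, 40L))
  sim <- simulate_pair(spec, spec, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_simulated_pair(sim, dir, format = "csv",
                                expected = list(kind = "match"))
  expect_true(all(file.exists(paths)))
  ev <- read_events_csv(paths["sample_a"])
  expect_equal(ev$values, sim$events_a$values, ignore_attr = TRUE)
  expect_identical(read_labels_csv(paths["labels_a"]), sim$labels_a)
  meta <- yaml::read_yaml(paths["meta"])
  expect_equal(meta$n_events_a, 100L)
})
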