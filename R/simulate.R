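#' Specify a Gaussian mixture sample
#'
#' A mixture specification holds the per-component means, per-dimension
#' standard deviations, event counts and ground-truth group ids used by
#' [simulate_pair()]. Components have diagonal covariance.
#'
#' @param means Numeric matrix, one row per component, one column per
#'   dimension.
#' @param sds Matrix of per-dimension standard deviations, same shape as
#'   `means` (a vector is recycled across components).
#' @param counts Integer vector of event counts per component, all `>= 1`.
#' @param group_ids Integer ground-truth ids, unique within the sample.
#' @param sample_id Sample identifier.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(means, sds, counts,
                         group_ids = seq_len(nrow(means)),
                         sample_id = "sample") {
  means <- as.matrix(means)
  if (is.vector(sds)) sds <- matrix(sds, nrow(means), ncol(means), byrow = TRUE)
  sds <- as.matrix(sds)
  stopifnot(ncol(means) >= 2, nrow(sds) == nrow(means),
            ncol(sds) == ncol(means))
  if (any(sds <= 0)) stop("all component SDs must be > 0")
  counts <- as.integer(counts)
  if (length(counts) != nrow(means) || any(counts < 1L)) {
    stop("counts must give one value >= 1 per component")
  }
  group_ids <- as.integer(group_ids)
  if (anyDuplicated(group_ids)) stop("group ids must be unique within a sample")
  structure(
    list(dims = ncol(means), means = means, sds = sds, counts = counts,
         group_ids = group_ids, sample_id = sample_id),
    class = "mixture_spec"
  )
}

# Draw one sample from a mixture spec (assumes the RNG state is set).
draw_mixture <- function(spec, channel_names) {
  n <- sum(spec$counts)
  d <- spec$dims
  vals <- matrix(0, n, d)
  labels <- integer(n)
  at <- 0L
  for (k in seq_len(nrow(spec$means))) {
    nk <- spec$counts[k]
    rows <- at + seq_len(nk)
    vals[rows, ] <- matrix(stats::rnorm(nk * d), nk, d) *
      matrix(spec$sds[k, ], nk, d, byrow = TRUE) +
      matrix(spec$means[k, ], nk, d, byrow = TRUE)
    labels[rows] <- spec$group_ids[k]
    at <- at + nk
  }
  ev <- sic_events(vals, channel_names = channel_names,
                   sample_id = spec$sample_id)
  list(events = ev, labels = labels)
}

#' Simulate a pair of mixture samples
#'
#' Draws both samples from their specifications under a single seed;
#' identical `(spec, seed)` give bit-identical output. The RNG state of the
#' session is left untouched.
#'
#' @param spec_a,spec_b [mixture_spec()] objects with equal dimensionality.
#' @param seed Integer seed.
#' @param channel_names Channel names; default `d1..dk`.
#' @return A list with `events_a`, `labels_a`, `events_b`, `labels_b`.
#' @export
#' @examples
#' specs <- canonical_pair_specs()
#' sim <- simulate_pair(specs$spec_a, specs$spec_b, seed = 1)
#' table(sim$labels_a)
simulate_pair <- function(spec_a, spec_b, seed = 1L,
                          channel_names = paste0("d", seq_len(spec_a$dims))) {
  stopifnot(inherits(spec_a, "mixture_spec"), inherits(spec_b, "mixture_spec"),
            spec_a$dims == spec_b$dims)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  a <- draw_mixture(spec_a, channel_names)
  b <- draw_mixture(spec_b, channel_names)
  list(events_a = a$events, labels_a = a$labels,
       events_b = b$events, labels_b = b$labels)
}

#' Canonical paired-sample fixture
#'
#' The canonical scenario on which the whole pipeline is exercised: two
#' three-dimensional samples of about 2e4 events each. Sample A carries
#' three well-separated components (pairwise mean separation >= 8 pooled
#' SD). Sample B carries four: B1 and B2 sit exactly on A1 and A2, while B3
#' and B4 jointly occupy the region of A3 -- their mixture mean equals A3's
#' mean and their centers are 3 SD apart, so A3 appears split into two
#' clusters in Sample B. The expected cluster alignment is recorded in the
#' returned metadata so downstream checks assert against construction.
#'
#' @return A list with `spec_a`, `spec_b` and `expected`, where `expected`
#'   lists the ground-truth match for each A group (`b_groups`, `kind`).
#' @export
canonical_pair_specs <- function() {
  sd <- 1
  a_means <- rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0))
  b_means <- rbind(c(0, 0, 0), c(12, 0, 0),
                   c(-1.5, 12, 0), c(1.5, 12, 0))
  spec_a <- mixture_spec(a_means, sd, counts = c(8000L, 6000L, 6000L),
                         sample_id = "sample_A")
  spec_b <- mixture_spec(b_means, sd, counts = c(7500L, 6500L, 3000L, 3000L),
                         sample_id = "sample_B")
  expected <- list(
    list(a_group = 1L, b_groups = 1L, kind = "match"),
    list(a_group = 2L, b_groups = 2L, kind = "match"),
    list(a_group = 3L, b_groups = c(3L, 4L), kind = "split")
  )
  list(spec_a = spec_a, spec_b = spec_b, expected = expected)
}

#' Write a simulated pair to disk
#'
#' Writes each sample as FCS or CSV together with ground-truth label CSVs
#' and the specification as a YAML file (including the expected cluster
#' alignment of the canonical fixture when given).
#'
#' @param sim Output of [simulate_pair()].
#' @param dir Output directory, created if needed.
#' @param format `"fcs"` or `"csv"`.
#' @param expected Optional expected-match metadata to record.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_pair <- function(sim, dir, format = c("fcs", "csv"),
                                 expected = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- format
  pa <- file.path(dir, paste0("sample_a.", ext))
  pb <- file.path(dir, paste0("sample_b.", ext))
  if (format == "fcs") {
    write_fcs(sim$events_a, pa); write_fcs(sim$events_b, pb)
  } else {
    write_events_csv(sim$events_a, pa); write_events_csv(sim$events_b, pb)
  }
  la <- file.path(dir, "labels_a.csv")
  lb <- file.path(dir, "labels_b.csv")
  write_labels_csv(sim$labels_a, la)
  write_labels_csv(sim$labels_b, lb)
  meta <- list(
    n_events_a = nrow(sim$events_a$values),
    n_events_b = nrow(sim$events_b$values),
    channels = sim$events_a$channel_names
  )
  if (!is.null(expected)) meta$expected_matches <- expected
  mp <- file.path(dir, "simulation.yaml")
  yaml::write_yaml(meta, mp)
  invisible(c(sample_a = pa, sample_b = pb, labels_a = la, labels_b = lb,
              meta = mp))
}
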