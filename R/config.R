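#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline in one list with
#' documented defaults. All stages run without user input beyond the set of
#' channels to analyse; the defaults below are only overridden explicitly.
#'
#' @param logicle_t Top-of-scale data value for the Logicle transform.
#' @param logicle_m Total display decades.
#' @param logicle_a Additional negative display decades.
#' @param logicle_w Linearization width in decades, or `NA` to estimate it
#'   per channel from the 5th percentile of negative values.
#' @param scatter_regex Case-insensitive regular expression naming channels
#'   (scatter, time) that are linearly rescaled instead of Logicle
#'   transformed.
#' @param grid_size Cells per axis of the 2D density grid.
#' @param dbm_theta Mode-merging threshold: two density modes merge when the
#'   highest saddle density between their basins exceeds this fraction of
#'   the lower peak density.
#' @param dbm_prominence Minimum topographic prominence of a density mode,
#'   as a fraction of the global peak; weaker modes are treated as noise
#'   and merged into their strongest neighbour.
#' @param outlier_frac Grid cells with density below this fraction of the
#'   peak are left unclustered initially; their events are assigned to the
#'   nearest cluster afterwards.
#' @param max_error Largest admissible estimated misclassification error for
#'   a projection-pursuit split; candidates above it are rejected.
#' @param min_leaf_size Smallest admissible cluster size, as
#'   `max(min_leaf_abs, min_leaf_frac * n)`.
#' @param min_leaf_abs,min_leaf_frac Components of `min_leaf_size` when it
#'   is `NA`.
#' @param gate_mult Median gate width: candidate cluster pairs must have
#'   medians within `gate_mult` standard deviations in every dimension.
#' @param merge_cap Largest number of merging-candidate combinations
#'   enumerated exhaustively; beyond it a nearest-median pre-filter applies.
#' @param seed Integer seed for any stochastic stage.
#'
#' @return A list of class `sic_config`.
#' @export
#' @examples
#' cfg <- sic_config(max_error = 0.05)
#' cfg$max_error
sic_config <- function(logicle_t = 262144, logicle_m = 4.5, logicle_a = 0,
                       logicle_w = NA_real_,
                       scatter_regex = "^(fsc|ssc|time)",
                       grid_size = 128L, dbm_theta = 0.85,
                       dbm_prominence = 0.05,
                       outlier_frac = 1e-4,
                       max_error = 0.10, min_leaf_size = NA_real_,
                       min_leaf_abs = 200L, min_leaf_frac = 0.002,
                       gate_mult = 4, merge_cap = 1024L,
                       seed = 1L) {
  cfg <- list(
    logicle_t = logicle_t, logicle_m = logicle_m, logicle_a = logicle_a,
    logicle_w = logicle_w, scatter_regex = scatter_regex,
    grid_size = as.integer(grid_size), dbm_theta = dbm_theta,
    dbm_prominence = dbm_prominence,
    outlier_frac = outlier_frac, max_error = max_error,
    min_leaf_size = min_leaf_size, min_leaf_abs = as.integer(min_leaf_abs),
    min_leaf_frac = min_leaf_frac, gate_mult = gate_mult,
    merge_cap = as.integer(merge_cap), seed = as.integer(seed)
  )
  validate_config(cfg)
  class(cfg) <- "sic_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$logicle_t > 0, cfg$logicle_m > 0, cfg$logicle_a >= 0,
    is.na(cfg$logicle_w) ||
      (cfg$logicle_w >= 0 && cfg$logicle_w <= cfg$logicle_m / 2),
    cfg$grid_size >= 8L,
    cfg$dbm_theta > 0, cfg$dbm_theta < 1,
    cfg$dbm_prominence >= 0, cfg$dbm_prominence < 1,
    cfg$outlier_frac >= 0, cfg$outlier_frac < 1,
    cfg$max_error > 0, cfg$max_error <= 0.5,
    cfg$min_leaf_abs >= 1L, cfg$min_leaf_frac >= 0, cfg$min_leaf_frac < 1,
    cfg$gate_mult > 0, cfg$merge_cap >= 1L
  )
  invisible(cfg)
}

# Effective minimum leaf size for a sample of n events.
min_leaf_for <- function(cfg, n) {
  if (!is.na(cfg$min_leaf_size)) return(as.integer(cfg$min_leaf_size))
  as.integer(max(cfg$min_leaf_abs, ceiling(cfg$min_leaf_frac * n)))
}

#' Read or write a pipeline configuration file
#'
#' Configurations serialize to plain YAML and round-trip losslessly.
#'
#' @param path File path.
#' @param cfg A [sic_config()] object.
#' @return `read_config` returns a `sic_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$logicle_w) && is.character(vals$logicle_w)) {
    vals$logicle_w <- NA_real_
  }
  do.call(sic_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sic_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.sic_config <- function(x, ...) {
  cat("SIC pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
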