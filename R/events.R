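#' Event matrices
#'
#' The core data container: a numeric matrix of events (rows) by channels
#' (columns) with channel names, a per-channel transform state and a sample
#' identifier. Rows containing non-finite values are dropped at
#' construction and counted in `n_dropped`.
#'
#' @param values Numeric matrix, one event per row.
#' @param channel_names Character vector, one name per column. Defaults to
#'   the matrix column names.
#' @param sample_id Free-text sample identifier.
#' @param transformed Per-channel transform state, one of `"raw"`,
#'   `"logicle"`, `"linear"`.
#'
#' @return An object of class `sic_events` with fields `values`,
#'   `channel_names`, `transformed`, `sample_id`, `n_dropped`.
#' @export
#' @examples
#' ev <- sic_events(matrix(rnorm(30), 10, 3),
#'                  channel_names = c("FSC-A", "CD3", "CD19"))
#' nrow(ev$values)
sic_events <- function(values, channel_names = colnames(values),
                       sample_id = "sample",
                       transformed = rep("raw", ncol(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(values)))
  }
  if (length(channel_names) != ncol(values)) {
    stop("number of channel names (", length(channel_names),
         ") does not match number of columns (", ncol(values), ")")
  }
  if (length(transformed) != ncol(values)) {
    stop("'transformed' must have one entry per channel")
  }
  if (!all(transformed %in% c("raw", "logicle", "linear"))) {
    stop("transform states must be 'raw', 'logicle' or 'linear'")
  }
  keep <- rowSums(!is.finite(values)) == 0L
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    values <- values[keep, , drop = FALSE]
    message(n_dropped, " event(s) with non-finite values dropped")
  }
  colnames(values) <- channel_names
  structure(
    list(values = values, channel_names = channel_names,
         transformed = transformed, sample_id = sample_id,
         n_dropped = n_dropped),
    class = "sic_events"
  )
}

#' @export
print.sic_events <- function(x, ...) {
  cat(sprintf("Event matrix '%s': %d events x %d channels\n",
              x$sample_id, nrow(x$values), length(x$channel_names)))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  tr <- unique(x$transformed)
  cat("  transform state:", paste(tr, collapse = "/"),
      if (x$n_dropped > 0) sprintf(" (%d rows dropped)", x$n_dropped) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.sic_events <- function(x) dim(x$values)

# Resolve channel selectors (names or indices) to column indices.
resolve_channels <- function(events, channels) {
  nms <- events$channel_names
  if (is.null(channels)) return(seq_along(nms))
  if (is.numeric(channels)) {
    idx <- as.integer(channels)
    if (any(idx < 1L | idx > length(nms))) {
      stop("channel index out of range; available channels: ",
           paste(nms, collapse = ", "))
    }
    return(idx)
  }
  idx <- match(channels, nms)
  if (anyNA(idx)) {
    stop("unknown channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "),
         "; available channels: ", paste(nms, collapse = ", "))
  }
  idx
}

# Extract the event matrix from sic_events or a plain matrix.
event_values <- function(x) {
  if (inherits(x, "sic_events")) x$values else as.matrix(x)
}
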