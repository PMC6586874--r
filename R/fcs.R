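#' Read an FCS file
#'
#' Parses FCS 2.0, 3.0 and 3.1 files in list mode with floating point,
#' double or integer data. Channel names are taken from the $PnN keywords,
#' falling back to $PnS. All events and all parameters are returned with
#' transform state `"raw"`; rows containing non-finite values are dropped
#' and counted.
#'
#' @param path Path to an FCS file.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A [sic_events()] object.
#' @export
read_fcs <- function(path, sample_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58) stop("FCS format error: file too short for HEADER segment")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- trimws(substr(header, 1, 6))
  if (!grepl("^FCS[23]\\.[01]$", version)) {
    stop("FCS format error: unrecognized version string '", version, "'")
  }
  off <- function(a, b) {
    v <- suppressWarnings(as.numeric(trimws(substr(header, a, b))))
    if (is.na(v)) stop("FCS format error: non-numeric segment offset in HEADER")
    v
  }
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  if (text_end <= text_start || text_end > sz) {
    stop("FCS format error: invalid TEXT segment offsets in HEADER")
  }

  seek(con, text_start)
  text_raw <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  kw <- parse_fcs_text(text_raw)
  get_kw <- function(name, required = TRUE) {
    v <- kw[[toupper(name)]]
    if (is.null(v) && required) {
      stop("FCS format error: required keyword ", name, " missing")
    }
    v
  }

  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  if (is.na(n_par) || n_par < 1L) stop("FCS format error: invalid $PAR value")
  if (is.na(n_tot)) stop("FCS format error: invalid $TOT value")
  if (n_tot == 0L) stop("empty input: FCS file contains zero events ($TOT = 0)")
  mode <- get_kw("$MODE")
  if (toupper(mode) != "L") stop("FCS format error: unsupported $MODE '", mode, "'")
  dtype <- toupper(get_kw("$DATATYPE"))
  byteord <- get_kw("$BYTEORD")
  endian <- switch(byteord,
                   "1,2,3,4" = "little", "1,2" = "little",
                   "4,3,2,1" = "big", "2,1" = "big",
                   stop("FCS format error: unsupported $BYTEORD '", byteord, "'"))

  if (data_start == 0) data_start <- as.numeric(get_kw("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(get_kw("$ENDDATA"))
  if (is.na(data_start) || is.na(data_end) || data_end <= data_start ||
      data_end > sz) {
    stop("FCS format error: invalid DATA segment offsets ($BEGINDATA/$ENDDATA)")
  }

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(get_kw(sprintf("$P%dB", i)))
  }, integer(1))
  names <- vapply(seq_len(n_par), function(i) {
    nn <- get_kw(sprintf("$P%dN", i), required = FALSE)
    if (is.null(nn) || !nzchar(nn)) nn <- get_kw(sprintf("$P%dS", i), required = FALSE)
    if (is.null(nn) || !nzchar(nn)) nn <- paste0("P", i)
    nn
  }, character(1))

  seek(con, data_start)
  n_vals <- n_par * n_tot
  vals <- if (dtype == "F") {
    if (!all(bits == 32L)) stop("FCS format error: $PnB must be 32 for $DATATYPE F")
    readBin(con, "double", n = n_vals, size = 4L, endian = endian)
  } else if (dtype == "D") {
    if (!all(bits == 64L)) stop("FCS format error: $PnB must be 64 for $DATATYPE D")
    readBin(con, "double", n = n_vals, size = 8L, endian = endian)
  } else if (dtype == "I") {
    if (!all(bits %in% c(8L, 16L, 32L))) {
      stop("FCS format error: unsupported $PnB for $DATATYPE I")
    }
    if (length(unique(bits)) != 1L) {
      stop("FCS format error: mixed $PnB widths not supported")
    }
    b <- bits[1] %/% 8L
    raw_i <- readBin(con, "integer", n = n_vals, size = b, endian = endian,
                     signed = b > 2L)
    if (b == 4L) raw_i <- ifelse(raw_i < 0, raw_i + 2^32, raw_i)
    as.double(raw_i)
  } else {
    stop("FCS format error: unsupported $DATATYPE '", dtype, "'")
  }
  if (length(vals) < n_vals) {
    stop("FCS format error: DATA segment truncated (expected ", n_vals,
         " values, read ", length(vals), ")")
  }
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  sic_events(m, channel_names = names, sample_id = sample_id)
}

# Parse a TEXT segment: first byte is the delimiter; doubled delimiters
# inside values are literal. Returns a named list keyed by uppercase keyword.
parse_fcs_text <- function(text_raw) {
  delim <- substr(text_raw, 1, 1)
  body <- substr(text_raw, 2, nchar(text_raw))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop("FCS format error: empty TEXT segment")
  # Re-join empty segments arising from escaped (doubled) delimiters.
  toks <- character(0)
  cur <- parts[1]
  i <- 2L
  while (i <= length(parts)) {
    if (parts[i] == "" && i < length(parts)) {
      cur <- paste0(cur, delim, parts[i + 1L])
      i <- i + 2L
    } else {
      toks <- c(toks, cur)
      cur <- parts[i]
      i <- i + 1L
    }
  }
  toks <- c(toks, cur)
  if (length(toks) %% 2 == 1L) toks <- toks[-length(toks)]
  if (length(toks) == 0L) stop("FCS format error: empty TEXT segment")
  keys <- toupper(trimws(toks[seq(1, length(toks), by = 2)]))
  vals <- toks[seq(2, length(toks), by = 2)]
  stats::setNames(as.list(vals), keys)
}

#' Write an FCS 3.1 file
#'
#' Writes single-precision floating point list-mode data. Round-trips with
#' [read_fcs()] within float32 precision.
#'
#' @param events A [sic_events()] object or numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  m <- event_values(events)
  nms <- if (inherits(events, "sic_events")) events$channel_names else colnames(m)
  if (is.null(nms)) nms <- paste0("ch", seq_len(ncol(m)))
  if (nrow(m) == 0L) stop("empty input: cannot write an FCS file with zero events")
  if (ncol(m) == 0L) stop("empty input: cannot write an FCS file with zero channels")

  delim <- "\x0c"
  esc <- function(s) gsub(delim, paste0(delim, delim), s, fixed = TRUE)
  rng <- apply(m, 2, function(v) max(1, ceiling(max(v[is.finite(v)], 0))))
  kw <- c(
    "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
    "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
    "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
    "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
    "$NEXTDATA", "0",
    "$PAR", as.character(ncol(m)), "$TOT", as.character(nrow(m))
  )
  for (i in seq_len(ncol(m))) {
    kw <- c(kw, sprintf("$P%dN", i), esc(nms[i]),
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), format(rng[i], scientific = FALSE))
  }
  build_text <- function(bd, ed) {
    k <- kw
    k[k == "%BD%"] <- sprintf("%010d", bd)
    k[k == "%ED%"] <- sprintf("%010d", ed)
    paste0(delim, paste0(k, collapse = delim), delim)
  }
  text_start <- 58L
  text_len <- nchar(build_text(0L, 0L), type = "bytes")
  data_start <- text_start + text_len
  data_len <- 4L * nrow(m) * ncol(m)
  data_end <- data_start + data_len - 1L
  text <- build_text(data_start, data_end)
  text_end <- text_start + text_len - 1L

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (data_end <= 99999999) data_start else 0L,
                    if (data_end <= 99999999) data_end else 0L,
                    0L, 0L)
  stopifnot(nchar(header, type = "bytes") == 58L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.double(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read or write CSV event tables
#'
#' The CSV interchange dialect: comma separated, a header row of channel
#' names, one event per row.
#'
#' @param path File path.
#' @param events A [sic_events()] object or numeric matrix.
#' @param sample_id Sample identifier for the returned object.
#' @return `read_events_csv` returns a [sic_events()]; `write_events_csv`
#'   returns `path` invisibly.
#' @export
read_events_csv <- function(path, sample_id = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty input: CSV contains zero events")
  sic_events(as.matrix(df), channel_names = names(df), sample_id = sample_id)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  m <- event_values(events)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Read or write cluster label files
#'
#' Label CSVs have two columns: `event_index` (0-based) and `cluster_id`
#' (integer, `>= 1`; `0` means unassigned).
#'
#' @param path File path.
#' @param labels Integer vector of cluster ids, one per event.
#' @param n_events If given, validate that the file covers exactly this many
#'   events.
#' @return `read_labels_csv` returns an integer vector ordered by event
#'   index; `write_labels_csv` returns `path` invisibly.
#' @export
read_labels_csv <- function(path, n_events = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("event_index", "cluster_id") %in% names(df))) {
    stop("label CSV must have columns 'event_index' and 'cluster_id'")
  }
  idx <- as.integer(df$event_index)
  lab <- as.integer(df$cluster_id)
  if (anyNA(idx) || anyNA(lab) || any(lab < 0L)) {
    stop("label CSV contains invalid indices or cluster ids")
  }
  n <- if (is.null(n_events)) max(idx) + 1L else as.integer(n_events)
  if (any(idx < 0L) || any(idx >= n) || anyDuplicated(idx)) {
    stop("label CSV event indices do not match the event table (expected 0..",
         n - 1L, " exactly once)")
  }
  if (length(idx) != n) {
    stop("label CSV covers ", length(idx), " events but the event table has ", n)
  }
  out <- integer(n)
  out[idx + 1L] <- lab
  out
}

#' @rdname read_labels_csv
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(event_index = seq_along(labels) - 1L,
                   cluster_id = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
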