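#' Logicle transformation parameters
#'
#' The Logicle display scale is logarithmic for large signals and smoothly
#' linear through zero, which keeps compensated populations with negative
#' fluorescence values on scale. It is parameterized by the top-of-scale
#' data value `T`, the number of display decades `M`, the linearization
#' width `W` (decades) and additional negative decades `A`.
#'
#' @param T Top-of-scale data value, `> 0`.
#' @param M Total display decades, `> 0`.
#' @param W Linearization width in decades, `0 <= W <= M/2`.
#' @param A Additional negative display decades, `>= 0`.
#' @return A list of class `logicle_params` including the derived
#'   biexponential coefficients.
#' @export
#' @examples
#' p <- logicle_params(T = 262144, M = 4.5, W = 0.5)
#' logicle(262144, p)  # == M at top of scale
logicle_params <- function(T = 262144, M = 4.5, W = 0.5, A = 0) {
  if (!(is.finite(T) && T > 0)) stop("invalid Logicle parameter: T must be > 0")
  if (!(is.finite(M) && M > 0)) stop("invalid Logicle parameter: M must be > 0")
  if (!(is.finite(W) && W >= 0 && W <= M / 2)) {
    stop("invalid Logicle parameter: W must satisfy 0 <= W <= M/2")
  }
  if (!(is.finite(A) && A >= 0)) stop("invalid Logicle parameter: A must be >= 0")

  # Derived coefficients of the biexponential on the unit scale y in [0, 1]:
  # value(y) = a e^(b y) - c e^(-d y) - f  for y >= x1, odd-reflected below.
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * log(10)
  d <- if (w == 0) b else {
    # root of 2 ln(d/b) + w (b + d) = 0 on (0, b]
    stats::uniroot(function(dd) 2 * log(dd / b) + w * (b + dd),
                   lower = b * 1e-12, upper = b, tol = 1e-14)$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / (exp(b) - c_a * exp(-d) - mf_a)
  structure(
    list(T = T, M = M, W = W, A = A,
         a = a, b = b, c = c_a * a, d = d, f = mf_a * a, x1 = x1),
    class = "logicle_params"
  )
}

# Biexponential (inverse Logicle) on the unit scale y.
biexp_unit <- function(y, p) {
  out <- numeric(length(y))
  lo <- y < p$x1
  yy <- ifelse(lo, 2 * p$x1 - y, y)
  v <- p$a * exp(p$b * yy) - p$c * exp(-p$d * yy) - p$f
  ifelse(lo, -v, v)
}

# d/dy of biexp_unit; strictly positive, used for Newton refinement.
biexp_unit_deriv <- function(y, p) {
  yy <- ifelse(y < p$x1, 2 * p$x1 - y, y)
  p$a * p$b * exp(p$b * yy) + p$c * p$d * exp(-p$d * yy)
}

#' Logicle transform and its inverse
#'
#' `logicle()` maps data values to display units in decades: the top of
#' scale `T` maps to `M` and the display extends down to `-A`.
#' `logicle_inverse()` is the biexponential inverse;
#' `logicle_inverse(logicle(x))` recovers `x` to within `1e-6 * T`.
#'
#' @param x Numeric vector of data values (for `logicle`) or display values
#'   in decades (for `logicle_inverse`).
#' @param params A [logicle_params()] object.
#' @return Numeric vector of the same length.
#' @export
logicle <- function(x, params = logicle_params()) {
  if (!inherits(params, "logicle_params")) {
    params <- do.call(logicle_params, as.list(params))
  }
  p <- params
  scale_span <- p$M + p$A
  # Initial guess by monotone interpolation on a fixed grid, then Newton.
  grid_y <- seq(-0.5, 1.5, length.out = 513L)
  grid_v <- biexp_unit(grid_y, p)
  y <- stats::approx(grid_v, grid_y, xout = pmin(pmax(x, grid_v[1]),
                                                grid_v[length(grid_v)]),
                     ties = "ordered")$y
  for (i in 1:40) {
    step <- (biexp_unit(y, p) - x) / biexp_unit_deriv(y, p)
    y <- y - step
    if (all(abs(step) <= 1e-13)) break
  }
  y * scale_span - p$A
}

#' @rdname logicle
#' @export
logicle_inverse <- function(x, params = logicle_params()) {
  if (!inherits(params, "logicle_params")) {
    params <- do.call(logicle_params, as.list(params))
  }
  biexp_unit((x + params$A) / (params$M + params$A), params)
}

#' Estimate the Logicle linearization width from data
#'
#' Standard practice: `W = max(0, (M - log10(T / |r|)) / 2)` where `r` is
#' the 5th percentile of the channel's negative values. Channels without
#' negative values get `W = 0`.
#'
#' @param x Numeric vector of raw channel values.
#' @param T,M Logicle top of scale and decades.
#' @return Estimated `W` in decades, capped at `M/2`.
#' @export
estimate_logicle_w <- function(x, T = 262144, M = 4.5) {
  neg <- x[x < 0 & is.finite(x)]
  if (length(neg) == 0L) return(0)
  r <- abs(stats::quantile(neg, 0.05, names = FALSE, type = 7))
  if (r == 0) return(0)
  min(M / 2, max(0, (M - log10(T / r)) / 2))
}

#' Transform event channels to display scale
#'
#' Applies the Logicle transformation to fluorescence channels and a linear
#' rescale to `[0, M]` for scatter/time channels (names matching
#' `cfg$scatter_regex`, case-insensitively). Channels already transformed
#' are left untouched.
#'
#' @param events A [sic_events()] object.
#' @param channels Channels to transform (names or indices); default all.
#' @param cfg A [sic_config()] providing Logicle defaults; `logicle_w = NA`
#'   estimates W per channel via [estimate_logicle_w()].
#' @return The transformed [sic_events()] object with updated per-channel
#'   transform state.
#' @export
transform_events <- function(events, channels = NULL, cfg = sic_config()) {
  stopifnot(inherits(events, "sic_events"))
  idx <- resolve_channels(events, channels)
  vals <- events$values
  tr <- events$transformed
  for (j in idx) {
    if (tr[j] != "raw") next
    nm <- events$channel_names[j]
    if (grepl(cfg$scatter_regex, nm, ignore.case = TRUE)) {
      rng <- range(vals[, j])
      span <- if (diff(rng) > 0) diff(rng) else 1
      vals[, j] <- (vals[, j] - rng[1]) / span * cfg$logicle_m
      tr[j] <- "linear"
    } else {
      w <- if (is.na(cfg$logicle_w)) {
        estimate_logicle_w(vals[, j], T = cfg$logicle_t, M = cfg$logicle_m)
      } else {
        cfg$logicle_w
      }
      p <- logicle_params(T = cfg$logicle_t, M = cfg$logicle_m,
                          W = w, A = cfg$logicle_a)
      vals[, j] <- logicle(vals[, j], p)
      tr[j] <- "logicle"
    }
  }
  events$values <- vals
  events$transformed <- tr
  events
}
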