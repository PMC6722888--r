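#' @importFrom rlang %||% .data
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Derive a child RNG seed from a master seed and a path of labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (stage names, ROI identifiers, replicate numbers) into a 32-bit seed.
#' Used throughout the package so that every stage and every ROI of an
#' experiment draws from an independent, reproducible stream.
#'
#' @param master_seed Integer master seed.
#' @param ... Labels (coerced to character) identifying the consumer.
#' @return A positive integer seed strictly below 2^31.
#' @export
derive_seed <- function(master_seed, ...) {
  key <- paste(c(format(master_seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- as.numeric(digest::digest2int(key))
  as.integer(((h %% 2147483291) + 2147483291) %% 2147483291 + 1)
}

# Linear (column-major) indices of pixels whose centers fall inside an
# ellipse. Pixel (row r, col c) has center x = (c-1)*ps, y = (r-1)*ps;
# (cx, cy) in micrometres, (a, b) semi-axes, theta in radians.
ellipse_pixels <- function(cx, cy, a, b, theta, H, W, ps = 1) {
  r <- max(a, b)
  c0 <- max(1L, as.integer(floor((cx - r) / ps)) + 1L)
  c1 <- min(W, as.integer(ceiling((cx + r) / ps)) + 1L)
  r0 <- max(1L, as.integer(floor((cy - r) / ps)) + 1L)
  r1 <- min(H, as.integer(ceiling((cy + r) / ps)) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  rows <- r0:r1
  cols <- c0:c1
  dx <- rep((cols - 1) * ps - cx, each = length(rows))
  dy <- rep((rows - 1) * ps - cy, times = length(cols))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- which(u * u + v * v <= 1)
  if (length(keep) == 0L) return(integer(0))
  ri <- rows[(keep - 1L) %% length(rows) + 1L]
  ci <- cols[(keep - 1L) %/% length(rows) + 1L]
  (ci - 1L) * H + ri
}

# type-7 percentile clip: values above the p-th percentile are set to it;
# p = 100 disables clipping
clip_upper_percentile <- function(x, p) {
  if (p >= 100) return(x)
  cut <- stats::quantile(x, p / 100, names = FALSE, na.rm = TRUE)
  pmin(x, cut)
}

abort_if <- function(cond, ...) if (cond) stop(sprintf(...), call. = FALSE)
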