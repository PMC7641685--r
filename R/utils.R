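#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check that `x` is an image matrix with 8-bit grayscale values (0-255).
#' @noRd
check_image <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("%s must be a numeric matrix", what)
  if (length(x) && (anyNA(x) || min(x) < 0 || max(x) > 255))
    stopf("%s must contain values in [0, 255]", what)
  invisible(x)
}

#' Clip to [0, 255] and round to integer storage.
#' @noRd
quantize8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Otsu threshold on a vector of 8-bit values.
#'
#' Maximizes the between-class variance over the 256-level histogram. Written
#' against a plain value vector so callers can restrict it to a pixel mask
#' (e.g. breast-side nonzero pixels only).
#' @noRd
otsu_threshold <- function(values) {
  values <- as.integer(round(values))
  h <- as.numeric(tabulate(values + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0L) stopf("no pixels available for thresholding")
  levels <- 0:255
  w0 <- cumsum(h)
  mu0 <- cumsum(h * levels)
  mu_t <- mu0[256L]
  w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, 256L)
  between[ok] <- (mu_t * w0[ok] / n - mu0[ok])^2 / (w0[ok] * w1[ok] / n)
  levels[which.max(between)]
}

#' Summed-area table: entry (i+1, j+1) holds the sum of m over rows 1..i, cols 1..j.
#' @noRd
integral_image <- function(m) {
  s <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  s[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  s
}

#' Rectangle sum over rows [r0, r1) x cols [c0, c1), 0-based half-open.
#' Vectorized over equal-length bound vectors.
#' @noRd
rect_sum <- function(S, r0, r1, c0, c1) {
  S[cbind(r1 + 1L, c1 + 1L)] - S[cbind(r0 + 1L, c1 + 1L)] -
    S[cbind(r1 + 1L, c0 + 1L)] + S[cbind(r0 + 1L, c0 + 1L)]
}
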