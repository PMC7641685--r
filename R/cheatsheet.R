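#' Electronic biopsy of an ROI
#'
#' Samples pixels uniformly at random with replacement from the ROI crop and
#' averages their values — the "electronic biopsy" attribute encoded in the
#' outer cheat-sheet frame. With `enumerate = TRUE` the exact arithmetic mean
#' over all pixels is returned instead (useful as an unbiased reference and in
#' tests).
#'
#' @param roi_pixels Non-empty grayscale matrix (the ROI crop).
#' @param n_samples Number of random draws; defaults to 10% of the pixel
#'   count, but never fewer than 100.
#' @param seed Integer seed making the draw reproducible.
#' @param enumerate If `TRUE`, average every pixel instead of sampling.
#' @return An object of class `biopsy_result` with fields `mean_value`,
#'   `n_samples` and `seed`.
#' @export
electronic_biopsy <- function(roi_pixels, n_samples = NULL, seed = 1L,
                              enumerate = FALSE) {
  check_image(roi_pixels, "ROI")
  npix <- length(roi_pixels)
  if (npix == 0L) stopf("empty ROI")
  if (enumerate) {
    mean_value <- mean(roi_pixels)
    n_samples <- npix
  } else {
    if (is.null(n_samples)) n_samples <- max(100L, ceiling(0.1 * npix))
    if (n_samples < 1L) stopf("n_samples must be at least 1")
    idx <- withr::with_seed(seed, sample.int(npix, n_samples, replace = TRUE))
    mean_value <- mean(roi_pixels[idx])
  }
  structure(list(mean_value = mean_value, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)), class = "biopsy_result")
}

#' Encode the cheat-sheet frames around an ROI crop
#'
#' Draws two uniform frames, each `frame_width` (default 10) pixels wide, one
#' inside the other, around the crop: the outer frame carries the rounded
#' biopsy mean and the inner frame the rounded ROI radius (both clipped to
#' \[0, 255\] for 8-bit storage). The frames are appended around the crop —
#' the output grows by `4 * frame_width` per axis — so no ROI pixel is
#' overwritten.
#'
#' @param roi_crop Grayscale matrix (the ROI crop).
#' @param biopsy A `biopsy_result`, or a plain number taken as the mean.
#' @param radius ROI radius in pixels (at least 1).
#' @param frame_width Width of each frame band.
#' @return A list of class `encoded_image` with fields `pixels`,
#'   `frame_width`, `outer_value` and `inner_value`.
#' @export
encode_frames <- function(roi_crop, biopsy, radius, frame_width = 10L) {
  check_image(roi_crop, "crop")
  if (radius < 1) stopf("radius must be at least 1")
  mean_value <- if (inherits(biopsy, "biopsy_result")) biopsy$mean_value
                else as.numeric(biopsy)
  outer_value <- min(255L, max(0L, as.integer(round(mean_value))))
  inner_value <- min(255L, max(0L, as.integer(round(radius))))
  fw <- as.integer(frame_width)
  h <- nrow(roi_crop); w <- ncol(roi_crop)
  out <- matrix(outer_value, h + 4L * fw, w + 4L * fw)
  out[(fw + 1L):(h + 3L * fw), (fw + 1L):(w + 3L * fw)] <- inner_value
  out[(2L * fw + 1L):(h + 2L * fw), (2L * fw + 1L):(w + 2L * fw)] <- roi_crop
  storage.mode(out) <- "integer"
  structure(list(pixels = out, frame_width = fw, outer_value = outer_value,
                 inner_value = inner_value), class = "encoded_image")
}

#' Strip the two cheat-sheet frames from an encoded image
#'
#' Inverse of [encode_frames()]: drops the outermost `2 * frame_width` pixels
#' on every side, recovering the original crop exactly.
#'
#' @param encoded An `encoded_image`, or a pixel matrix.
#' @param frame_width Frame band width used at encoding time.
#' @return The interior pixel matrix.
#' @export
strip_frames <- function(encoded, frame_width = 10L) {
  px <- if (inherits(encoded, "encoded_image")) encoded$pixels else encoded
  fw <- if (inherits(encoded, "encoded_image")) encoded$frame_width
        else as.integer(frame_width)
  h <- nrow(px); w <- ncol(px)
  if (h <= 4L * fw || w <= 4L * fw) stopf("image too small to carry frames")
  px[(2L * fw + 1L):(h - 2L * fw), (2L * fw + 1L):(w - 2L * fw), drop = FALSE]
}
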