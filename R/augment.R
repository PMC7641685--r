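#' Rotate an image by 90 or 180 degrees
#'
#' Rotations by these angles are lossless pixel permutations (no
#' interpolation). With 0-based coordinates the 90-degree rotation maps
#' `(r, c)` to `(c, H - 1 - r)` where `H` is the input height.
#'
#' @param pixels Image matrix.
#' @param angle 90 or 180.
#' @return The rotated matrix.
#' @export
rotate_image <- function(pixels, angle) {
  check_image(pixels)
  if (angle == 90) t(pixels)[, nrow(pixels):1, drop = FALSE]
  else if (angle == 180) pixels[nrow(pixels):1, ncol(pixels):1, drop = FALSE]
  else stopf("unsupported rotation angle %s (only 90 and 180)", angle)
}

#' Augment a training set by rotation
#'
#' Each training image contributes itself plus its 90- and 180-degree
#' rotations, with labels inherited; 222 inputs therefore become 666 images,
#' 444 of them augmented. Provenance (source id and transform tag) is kept so
#' leakage checks can verify that no rotation of a test image ever enters
#' training.
#'
#' @param images List of image matrices.
#' @param labels Vector of labels, one per image.
#' @param ids Character ids, one per image.
#' @return A list of class `augmented_set` with `images` (length `3 * n`) and
#'   `meta`, a data frame with columns `id`, `source_id`, `transform`
#'   (`"orig"`, `"rot90"`, `"rot180"`) and `label`.
#' @export
augment_training_set <- function(images, labels,
                                 ids = sprintf("img%03d", seq_along(images))) {
  n <- length(images)
  if (n == 0L) stopf("empty training list")
  stopifnot(length(labels) == n, length(ids) == n)
  out_images <- vector("list", 3L * n)
  transforms <- c("orig", "rot90", "rot180")
  meta <- data.frame(id = character(3L * n), source_id = rep(ids, each = 3L),
                     transform = rep(transforms, n),
                     label = rep(labels, each = 3L))
  for (i in seq_len(n)) {
    j <- 3L * (i - 1L)
    out_images[[j + 1L]] <- images[[i]]
    out_images[[j + 2L]] <- rotate_image(images[[i]], 90)
    out_images[[j + 3L]] <- rotate_image(images[[i]], 180)
    meta$id[j + 1:3] <- paste0(ids[i], c("", "_rot90", "_rot180"))
  }
  structure(list(images = out_images, meta = meta), class = "augmented_set")
}

#' Resize an image by bilinear interpolation
#'
#' Resizes to the CNN input size (default 100 x 100). Interpolation preserves
#' constant images exactly; a same-size input is returned bit-identical.
#'
#' @param pixels Image matrix.
#' @param width,height Target size in pixels.
#' @return An integer matrix of the target size.
#' @export
resize_image <- function(pixels, width = 100L, height = 100L) {
  check_image(pixels)
  if (nrow(pixels) == height && ncol(pixels) == width) {
    storage.mode(pixels) <- "integer"
    return(pixels)
  }
  res <- EBImage::resize(EBImage::Image(t(pixels)), w = width, h = height,
                         filter = "bilinear")
  quantize8(t(EBImage::imageData(res)))
}
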