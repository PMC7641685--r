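#' GA chromosome for ROI refinement
#'
#' The genome has three genes: `H` and `W`, fractions in (0, 1] of the initial
#' ROI's longer side `R` giving the refined rectangle's height and width, and
#' `CutVal`, a pixel-intensity threshold in \[0, 255\] used to score candidate
#' placements.
#'
#' @param H,W Fractions in (0, 1].
#' @param CutVal Threshold in \[0, 255\].
#' @return An object of class `chromosome`.
#' @export
chromosome <- function(H, W, CutVal) {
  if (H <= 0 || H > 1 || W <= 0 || W > 1)
    stopf("H and W must lie in (0, 1]")
  if (CutVal < 0 || CutVal > 255) stopf("CutVal must lie in [0, 255]")
  structure(list(H = H, W = W, CutVal = CutVal), class = "chromosome")
}

roi_result <- function(row0, row1, col0, col1, R, fallback = FALSE) {
  h <- row1 - row0; w <- col1 - col0
  structure(list(
    bounds = c(row0 = row0, row1 = row1, col0 = col0, col1 = col1),
    center = c(row = row0 + h / 2, col = col0 + w / 2),
    radius = max(1, max(h, w) / 2), R = R, fallback = fallback
  ), class = "roi_result")
}

#' Detect which edge the breast is attached to
#'
#' In an MLO view the breast mass is attached to one vertical image edge and
#' the far side is mostly dark background (plus small label artifacts). The
#' side is decided by comparing the summed intensity of the outer 10% column
#' bands, which is invariant to adding a constant to all pixels.
#'
#' @param pixels Grayscale image matrix.
#' @return `"left"` or `"right"`.
#' @export
detect_side <- function(pixels) {
  check_image(pixels)
  if (max(pixels) == min(pixels))
    stopf("cannot detect side: image has constant intensity")
  band <- max(4L, round(0.1 * ncol(pixels)))
  left <- sum(pixels[, seq_len(band)])
  right <- sum(pixels[, (ncol(pixels) - band + 1L):ncol(pixels)])
  if (left >= right) "left" else "right"
}

#' Remove background artifacts (label strips)
#'
#' Scans columns outward from the breast edge for the dark gap separating the
#' breast from any background artifact: a column whose maximum intensity falls
#' below 10% of the image maximum. Everything on the far side of the gap is
#' set to 0; breast-side pixels are untouched. When nothing bright lies beyond
#' the gap the image is returned unchanged (no-op).
#'
#' @param pixels Grayscale image matrix.
#' @param side `"left"` or `"right"`, from [detect_side()].
#' @return The cleaned image.
#' @export
remove_artifacts <- function(pixels, side = detect_side(pixels)) {
  check_image(pixels)
  col_max <- apply(pixels, 2L, max)
  dark <- col_max < 0.1 * max(pixels)
  order_out <- if (side == "left") seq_len(ncol(pixels)) else rev(seq_len(ncol(pixels)))
  dark_o <- dark[order_out]
  gap <- which(dark_o)[1]
  if (is.na(gap)) return(pixels)
  beyond <- order_out[gap:length(order_out)]
  if (all(dark[beyond])) return(pixels)        # nothing bright past the gap
  pixels[, beyond] <- 0L
  pixels
}

#' Remove the pectoral-muscle wedge
#'
#' The pectoral muscle is denser than the rest of the breast and images as a
#' bright wedge touching the upper corner on the breast side. An Otsu
#' threshold is computed on the tissue pixels (those above 10% of the image
#' maximum, excluding the dark background) of the top-quarter, breast-side
#' half of the image, and the connected component of supra-threshold pixels
#' containing that corner is set to 0. If the corner is not supra-threshold
#' (no wedge) the image is returned unchanged.
#'
#' @param pixels Grayscale image, artifacts already removed.
#' @param side `"left"` or `"right"`.
#' @return The image with the wedge zeroed.
#' @export
remove_pectoral <- function(pixels, side = detect_side(pixels)) {
  check_image(pixels)
  h <- nrow(pixels); w <- ncol(pixels)
  cols <- if (side == "left") seq_len(ceiling(w / 2)) else
    (w - ceiling(w / 2) + 1L):w
  region <- pixels[seq_len(ceiling(h / 4)), cols]
  vals <- region[region > 0.1 * max(pixels)]   # ignore background/noise floor
  if (length(vals) == 0L) return(pixels)
  thr <- otsu_threshold(vals)
  corner_col <- if (side == "left") 1L else w
  if (pixels[1L, corner_col] <= thr) return(pixels)
  mask <- pixels > thr
  labels <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  wedge_lab <- labels[1L, corner_col]
  pixels[labels == wedge_lab] <- 0L
  pixels
}

#' Initial region of interest (IROI)
#'
#' After artifact and pectoral removal, the tight bounding rectangle of all
#' nonzero pixels encloses the central breast tissue. Its longer side length
#' `R` parameterizes the GA refinement.
#'
#' @param pixels Cleaned grayscale image.
#' @return An `roi_result` whose bounds are 0-based half-open, with `R` the
#'   longer side of the rectangle.
#' @export
initial_roi <- function(pixels) {
  check_image(pixels)
  nz <- which(pixels > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stopf("empty ROI: image has no nonzero pixels")
  r0 <- min(nz[, 1]) - 1L; r1 <- max(nz[, 1])
  c0 <- min(nz[, 2]) - 1L; c1 <- max(nz[, 2])
  roi_result(r0, r1, c0, c1, R = max(r1 - r0, c1 - c0))
}

#' Refine the ROI with a chromosome
#'
#' Zooms the IROI down to a rectangle of height `H * R` and width `W * R`
#' (clipped to the IROI), placed on a stride grid inside the IROI so as to
#' maximize the number of pixels with intensity at least `CutVal`. Ties are
#' broken toward the top-left placement. If no IROI pixel reaches `CutVal`
#' the IROI itself is returned, flagged with `fallback = TRUE`.
#'
#' @param pixels Cleaned grayscale image.
#' @param iroi An `roi_result` from [initial_roi()].
#' @param chrom A [chromosome()].
#' @param stride Placement grid stride in pixels.
#' @return An `roi_result`; `R` is inherited from the IROI.
#' @export
refine_roi <- function(pixels, iroi, chrom, stride = 4L) {
  check_image(pixels)
  stopifnot(inherits(iroi, "roi_result"), inherits(chrom, "chromosome"))
  b <- iroi$bounds
  ih <- b["row1"] - b["row0"]; iw <- b["col1"] - b["col0"]
  th <- min(ih, max(1L, round(chrom$H * iroi$R)))
  tw <- min(iw, max(1L, round(chrom$W * iroi$R)))
  sub <- pixels[(b["row0"] + 1L):b["row1"], (b["col0"] + 1L):b["col1"],
                drop = FALSE]
  hit <- sub >= chrom$CutVal
  if (!any(hit)) {                     # nothing to score: keep the IROI
    out <- iroi
    out$fallback <- TRUE
    return(out)
  }
  S <- integral_image(hit)
  r_off <- unique(c(seq(0L, ih - th, by = stride), ih - th))
  c_off <- unique(c(seq(0L, iw - tw, by = stride), iw - tw))
  scores <- outer(r_off, c_off,
                  function(r, c) rect_sum(S, r, r + th, c, c + tw))
  best <- which(t(scores) == max(scores), arr.ind = TRUE)[1L, ] # row-major tie-break
  r0 <- b[["row0"]] + r_off[best[2L]]
  c0 <- b[["col0"]] + c_off[best[1L]]
  roi_result(r0, r0 + th, c0, c0 + tw, R = iroi$R)
}

#' Crop an image to ROI bounds
#'
#' @param pixels Image matrix.
#' @param roi An `roi_result`.
#' @return The sub-matrix covered by the ROI bounds.
#' @export
crop_roi <- function(pixels, roi) {
  b <- roi$bounds
  pixels[(b[["row0"]] + 1L):b[["row1"]], (b[["col0"]] + 1L):b[["col1"]],
         drop = FALSE]
}

#' Full ROI extraction pipeline
#'
#' Runs side detection, artifact removal, pectoral removal, IROI and
#' chromosome-guided refinement in order.
#'
#' @param pixels Raw grayscale image.
#' @param chrom A [chromosome()]; the default identity chromosome
#'   (`H = W = 1`, `CutVal = 0`) makes the refined ROI equal the IROI.
#' @param stride Placement stride for [refine_roi()].
#' @return A list with `roi` (the refined `roi_result`), `crop` (the ROI
#'   pixel crop), `side`, and `cleaned` (the artifact/pectoral-free image).
#' @export
extract_roi <- function(pixels, chrom = chromosome(1, 1, 0), stride = 4L) {
  side <- detect_side(pixels)
  cleaned <- remove_pectoral(remove_artifacts(pixels, side), side)
  iroi <- initial_roi(cleaned)
  roi <- refine_roi(cleaned, iroi, chrom, stride = stride)
  list(roi = roi, crop = crop_roi(cleaned, roi), side = side,
       cleaned = cleaned)
}
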