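#' Phantom specification
#'
#' Describes one synthetic mediolateral-oblique (MLO) phantom mammogram. The
#' phantom emulates the gross structure an MLO view presents to the ROI
#' pipeline: a breast-shaped bright region attached to one vertical image
#' edge, a brighter triangular pectoral-muscle wedge in the upper corner of
#' that edge, a dark gap, an optional bright label strip near the opposite
#' edge (the "artifact"), and an optional Gaussian-profile lesion blob.
#'
#' @param image_size Pixels per side (square image), at least 64.
#' @param side Which vertical edge the breast is attached to, `"left"` or
#'   `"right"`.
#' @param has_lesion Logical; plant a lesion blob?
#' @param lesion_radius Lesion radius in pixels.
#' @param lesion_intensity Peak lesion intensity, 0-255.
#' @param pectoral_fraction Fraction of the image width covered by the base of
#'   the pectoral wedge, in (0, 0.5).
#' @param artifact Logical; add a bright background label strip?
#' @param noise_sd Standard deviation of additive Gaussian pixel noise, in
#'   grayscale units.
#' @param breast_intensity,pectoral_intensity,artifact_intensity Base
#'   intensities of the three structures. The pectoral wedge must be brighter
#'   than the breast (it models denser tissue).
#'
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [cohort_spec()]
#' @export
phantom_spec <- function(image_size = 256L, side = c("left", "right"),
                         has_lesion = FALSE, lesion_radius = 12,
                         lesion_intensity = 200, pectoral_fraction = 0.35,
                         artifact = TRUE, noise_sd = 2,
                         breast_intensity = 140, pectoral_intensity = 230,
                         artifact_intensity = 200) {
  side <- match.arg(side)
  if (image_size < 64) stopf("image_size must be at least 64")
  if (lesion_intensity < 0 || lesion_intensity > 255)
    stopf("lesion_intensity must be in [0, 255]")
  if (pectoral_fraction <= 0 || pectoral_fraction >= 0.5)
    stopf("pectoral_fraction must be in (0, 0.5)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (lesion_radius <= 0) stopf("lesion_radius must be positive")
  structure(list(
    image_size = as.integer(image_size), side = side,
    has_lesion = isTRUE(has_lesion), lesion_radius = lesion_radius,
    lesion_intensity = lesion_intensity,
    pectoral_fraction = pectoral_fraction, artifact = isTRUE(artifact),
    noise_sd = noise_sd, breast_intensity = breast_intensity,
    pectoral_intensity = pectoral_intensity,
    artifact_intensity = artifact_intensity
  ), class = "phantom_spec")
}

#' Generate one phantom mammogram with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]. The geometry is fully
#' analytic, so with `noise_sd = 0` every pixel is predictable from the spec;
#' the returned ground truth exposes the exact masks each removal stage of the
#' ROI pipeline is expected to recover.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the pixel noise; generation is deterministic
#'   for a fixed spec and seed.
#' @param id Identifier stored on the record.
#'
#' @return A list with elements
#' \describe{
#'   \item{record}{list with `id`, `pixels` (integer matrix), `side`,
#'     `class_raw` (`NA`, set by [generate_cohort()]), `label` (`NA`).}
#'   \item{truth}{list with logical `breast_mask` and `pectoral_mask`,
#'     `artifact_bounds` (0-based half-open `c(row0, row1, col0, col1)` or
#'     `NULL`), `lesion_center` (`c(row, col)`, 1-based, or `NULL`) and
#'     `lesion_radius`.}
#' }
#' @export
generate_phantom <- function(spec, seed = 1L, id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$image_size
  row <- matrix(seq_len(n), n, n)          # row index of each pixel
  col <- matrix(seq_len(n), n, n, byrow = TRUE)

  # Geometry is drawn for a left-sided view and mirrored afterwards.
  a <- 0.52 * n                            # breast horizontal semi-axis
  b <- 0.42 * n                            # breast vertical semi-axis
  breast <- ((col - 1) / a)^2 + ((row - n / 2) / b)^2 <= 1
  pect_h <- 0.42 * n
  pect_w <- spec$pectoral_fraction * n
  pectoral <- (row - 1) / pect_h + (col - 1) / pect_w <= 1

  img <- matrix(0, n, n)
  img[breast] <- spec$breast_intensity
  img[pectoral] <- spec$pectoral_intensity
  breast_only <- breast & !pectoral

  lesion_center <- NULL
  if (spec$has_lesion) {
    cr <- round(0.58 * n)
    cc <- round(0.28 * n)
    sigma <- spec$lesion_radius / 2
    d2 <- (row - cr)^2 + (col - cc)^2
    blob <- spec$lesion_intensity * exp(-d2 / (2 * sigma^2))
    img <- pmax(img, blob)
    lesion_center <- c(cr, cc)
  }

  artifact_bounds <- NULL
  if (spec$artifact) {
    r0 <- round(0.08 * n); r1 <- round(0.16 * n)
    c0 <- round(0.86 * n); c1 <- round(0.94 * n)
    img[(r0 + 1):r1, (c0 + 1):c1] <- spec$artifact_intensity
    artifact_bounds <- c(r0, r1, c0, c1)
  }

  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(n * n, sd = spec$noise_sd))
    img <- img + matrix(noise, n, n)
  }
  img <- quantize8(img)

  mirror <- function(m) m[, ncol(m):1, drop = FALSE]
  if (spec$side == "right") {
    img <- mirror(img)
    breast_only <- mirror(breast_only)
    pectoral <- mirror(pectoral)
    if (!is.null(lesion_center))
      lesion_center[2] <- n + 1 - lesion_center[2]
    if (!is.null(artifact_bounds))
      artifact_bounds[3:4] <- c(n - artifact_bounds[4], n - artifact_bounds[3])
  }

  list(
    record = list(id = id, pixels = img, side = spec$side,
                  class_raw = NA_character_, label = NA_integer_),
    truth = list(breast_mask = breast_only, pectoral_mask = pectoral,
                 artifact_bounds = artifact_bounds,
                 lesion_center = lesion_center,
                 lesion_radius = if (spec$has_lesion) spec$lesion_radius)
  )
}

#' Cohort specification
#'
#' Describes a synthetic cohort mirroring the MIAS class composition
#' (322 = 208 normal + 63 benign + 51 malignant in the reference database).
#' Benign phantoms carry a smaller, dimmer lesion; malignant phantoms carry a
#' larger, brighter one, so a small classifier can learn the separation.
#'
#' @param n_normal,n_benign,n_malignant Non-negative class counts.
#' @param seed Integer seed; the cohort is fully reproducible from the spec.
#' @param image_size Pixels per side of each phantom.
#' @param noise_sd Gaussian pixel-noise standard deviation.
#' @param benign_radius,benign_intensity Lesion geometry for benign phantoms;
#'   defaults scale with `image_size`.
#' @param malignant_radius,malignant_intensity Lesion geometry for malignant
#'   phantoms.
#' @param artifact Logical; add label strips to the phantoms?
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 208L, n_benign = 63L, n_malignant = 51L,
                        seed = 1L, image_size = 256L, noise_sd = 2,
                        benign_radius = round(0.047 * image_size),
                        benign_intensity = 185,
                        malignant_radius = round(0.09 * image_size),
                        malignant_intensity = 250, artifact = TRUE) {
  counts <- c(n_normal, n_benign, n_malignant)
  if (any(counts < 0)) stopf("class counts must be non-negative")
  structure(list(
    n_normal = as.integer(n_normal), n_benign = as.integer(n_benign),
    n_malignant = as.integer(n_malignant), seed = as.integer(seed),
    image_size = as.integer(image_size), noise_sd = noise_sd,
    benign_radius = benign_radius, benign_intensity = benign_intensity,
    malignant_radius = malignant_radius,
    malignant_intensity = malignant_intensity, artifact = isTRUE(artifact)
  ), class = "cohort_spec")
}

#' Generate a phantom cohort with metadata
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `phantom_cohort` with elements `records` (list of
#'   mammogram records), `truth` (per-record ground truth) and `metadata`, a
#'   data frame with columns `id`, `class`, and ground-truth lesion `x`, `y`
#'   (0-based column/row of the center) and `radius` (`NA` for normals).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_normal + spec$n_benign + spec$n_malignant
  classes <- rep(c("normal", "benign", "malignant"),
                 times = c(spec$n_normal, spec$n_benign, spec$n_malignant))
  draws <- withr::with_seed(spec$seed, list(
    sides = sample(c("left", "right"), n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max - 1L, max(n, 1L))
  ))
  records <- vector("list", n)
  truth <- vector("list", n)
  meta <- data.frame(id = character(n), class = character(n),
                     x = rep(NA_real_, n), y = rep(NA_real_, n),
                     radius = rep(NA_real_, n))
  for (i in seq_len(n)) {
    cls <- classes[i]
    ps <- phantom_spec(
      image_size = spec$image_size, side = draws$sides[i],
      has_lesion = cls != "normal",
      lesion_radius = if (cls == "malignant") spec$malignant_radius
                      else spec$benign_radius,
      lesion_intensity = if (cls == "malignant") spec$malignant_intensity
                         else spec$benign_intensity,
      artifact = spec$artifact, noise_sd = spec$noise_sd
    )
    id <- sprintf("phm%03d", i)
    ph <- generate_phantom(ps, seed = draws$seeds[i], id = id)
    ph$record$class_raw <- cls
    records[[i]] <- ph$record
    truth[[i]] <- ph$truth
    meta$id[i] <- id
    meta$class[i] <- cls
    if (cls != "normal") {
      meta$x[i] <- ph$truth$lesion_center[2] - 1
      meta$y[i] <- ph$truth$lesion_center[1] - 1
      meta$radius[i] <- ph$truth$lesion_radius
    }
  }
  structure(list(records = records, truth = truth, metadata = meta),
            class = "phantom_cohort")
}

#' Write a cohort to disk as PGM images plus a metadata table
#'
#' Images are written as binary (P5) PGM files named `<id>.pgm`; the metadata
#' table is whitespace-delimited with columns id, class, x, y, radius
#' (lesion fields blank for normals), mirroring the MIAS reference-list style.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the metadata file.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$records)
    write_pgm(rec$pixels, file.path(dir, paste0(rec$id, ".pgm")))
  path <- file.path(dir, "metadata.txt")
  write_mias_metadata(cohort$metadata, path)
  invisible(path)
}
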