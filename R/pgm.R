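#' Read a PGM (portable graymap) image
#'
#' Supports both the ASCII (`P2`) and binary (`P5`) dialects with
#' `maxval <= 255`, as both circulate in MIAS mirrors. Pixels are returned
#' exactly as stored: an integer matrix with one row per image row, origin at
#' the top-left, no rescaling.
#'
#' @param path Path to a `.pgm` file.
#' @return An integer matrix of grayscale values in `[0, maxval]`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  pos <- 1L
  n <- length(raw)
  next_token <- function() {
    repeat {
      while (pos <= n && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= n && raw[pos] == as.raw(0x23)) {       # '#' comment
        while (pos <= n && !raw[pos] %in% as.raw(c(0x0a, 0x0d)))
          pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= n && !is_space(raw[pos])) pos <<- pos + 1L
    if (start > n) stopf("malformed PGM header in %s", path)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5"))
    stopf("not a P2/P5 PGM file (magic '%s'): %s", magic, path)
  width <- suppressWarnings(as.integer(next_token()))
  height <- suppressWarnings(as.integer(next_token()))
  maxval <- suppressWarnings(as.integer(next_token()))
  if (anyNA(c(width, height, maxval)) || width < 1 || height < 1)
    stopf("malformed PGM header in %s", path)
  if (maxval > 255) stopf("unsupported PGM depth (maxval %d > 255)", maxval)
  npix <- width * height
  if (magic == "P5") {
    pos <- pos + 1L                                     # one whitespace byte
    if (n - pos + 1L < npix) stopf("truncated PGM pixel data in %s", path)
    v <- as.integer(raw[pos:(pos + npix - 1L)])
  } else {
    txt <- rawToChar(raw[pos:n])
    v <- suppressWarnings(as.integer(strsplit(trimws(txt), "\\s+")[[1]]))
    if (length(v) < npix || anyNA(v[seq_len(npix)]))
      stopf("truncated or malformed P2 pixel data in %s", path)
    v <- v[seq_len(npix)]
  }
  matrix(v, nrow = height, ncol = width, byrow = TRUE)
}

#' Write a PGM image
#'
#' @param pixels Integer matrix with values in `[0, 255]`.
#' @param path Output path.
#' @param format `"P5"` (binary, default) or `"P2"` (ASCII).
#' @return Invisibly, `path`.
#' @export
write_pgm <- function(pixels, path, format = c("P5", "P2")) {
  format <- match.arg(format)
  check_image(pixels)
  if (any(pixels != round(pixels))) stopf("pixels must be integers")
  h <- nrow(pixels); w <- ncol(pixels)
  v <- as.integer(t(pixels))                            # row-major order
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", format, w, h), con, eos = NULL)
  if (format == "P5") {
    writeBin(as.raw(v), con)
  } else {
    writeChar(paste(v, collapse = " "), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  }
  invisible(path)
}

#' Read a MIAS-style metadata table
#'
#' Whitespace-delimited text, one record per line: `id class [x y radius]`,
#' where the three lesion fields are absent or blank for normals.
#'
#' @param path Path to the table.
#' @return A data frame with columns `id`, `class`, `x`, `y`, `radius`.
#' @export
read_mias_metadata <- function(path) {
  cols <- c("id", "class", "x", "y", "radius")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- data.frame(id = character(), class = character(),
                      x = numeric(), y = numeric(), radius = numeric())
    return(out)
  }
  parts <- strsplit(trimws(lines), "\\s+")
  out <- data.frame(
    id = vapply(parts, `[`, "", 1L),
    class = vapply(parts, `[`, "", 2L),
    x = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L))),
    y = suppressWarnings(as.numeric(vapply(parts, `[`, "", 4L))),
    radius = suppressWarnings(as.numeric(vapply(parts, `[`, "", 5L)))
  )
  names(out) <- cols
  out
}

#' Write a MIAS-style metadata table
#'
#' @param metadata Data frame with columns `id`, `class`, `x`, `y`, `radius`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mias_metadata <- function(metadata, path) {
  m <- metadata[, c("id", "class", "x", "y", "radius")]
  lines <- vapply(seq_len(nrow(m)), function(i) {
    base <- paste(m$id[i], m$class[i])
    if (is.na(m$x[i])) base
    else paste(base, m$x[i], m$y[i], m$radius[i])
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Assign binary labels to a metadata table
#'
#' Maps the three-way pathology class to the binary task: `normal` and
#' `benign` become label 0, `malignant` becomes label 1. The mapping is total
#' and idempotent.
#'
#' @param metadata Data frame with a `class` (or `class_raw`) column.
#' @return The input with an integer `label` column added (or overwritten).
#' @export
assign_labels <- function(metadata) {
  col <- if ("class" %in% names(metadata)) "class" else "class_raw"
  if (!col %in% names(metadata)) stopf("metadata has no class column")
  cls <- metadata[[col]]
  map <- c(normal = 0L, benign = 0L, malignant = 1L)
  if (length(cls) && any(!cls %in% names(map)))
    stopf("unknown class value(s): %s",
          paste(unique(cls[!cls %in% names(map)]), collapse = ", "))
  metadata$label <- unname(map[cls])
  if (length(cls) == 0L) metadata$label <- integer(0)
  metadata
}
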