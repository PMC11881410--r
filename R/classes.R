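#' @title Core raster containers
#' @description Lightweight S3 containers used throughout the pipeline:
#'   `SlideImage` (an 8-bit RGB raster with a physical pixel size) and
#'   `LabelMask` (an integer instance raster or a binary semantic raster on
#'   the same grid).
#'
#' Conventions: rasters are stored row-major as base R matrices/arrays with
#' dimension `[row, col(, channel)]`; pixel indices are 0-based in all
#' physical-coordinate computations, `x` is the column index and `y` the row
#' index, and physical coordinates are `index * pixel_size_um`.
#' @name histonox-classes
NULL

#' Construct a SlideImage
#'
#' @param pixels numeric or integer array `H x W x 3` with values in
#'   `[0, 255]` (8-bit RGB; channel order red, green, blue).
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @param source_path optional provenance string.
#' @return an object of class `SlideImage`.
#' @export
slide_image <- function(pixels, pixel_size_um, source_path = "<memory>") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < 64L || w < 64L)
    stop(sprintf("image too small: %d x %d (minimum 64 x 64)", h, w))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 255)
    stop("pixel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
         source_path = as.character(source_path)),
    class = "SlideImage")
}

#' @export
print.SlideImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<SlideImage %d x %d px, %.3f um/px, source: %s>\n",
              d[1], d[2], x$pixel_size_um, x$source_path))
  invisible(x)
}

#' @export
dim.SlideImage <- function(x) dim(x$pixels)

#' Construct a LabelMask
#'
#' @param labels integer matrix `H x W`; 0 is background. For binary kinds
#'   only values 0 and 1 are allowed.
#' @param kind one of `"nuclei-instances"`, `"tissue-binary"`,
#'   `"epidermis-binary"`.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @return an object of class `LabelMask`.
#' @export
label_mask <- function(labels,
                       kind = c("nuclei-instances", "tissue-binary",
                                "epidermis-binary"),
                       pixel_size_um) {
  kind <- match.arg(kind)
  if (!is.matrix(labels)) stop("labels must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  if (kind != "nuclei-instances" && any(labels > 1L))
    stop(sprintf("binary mask of kind '%s' may only contain 0/1", kind))
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar")
  structure(list(labels = labels, kind = kind,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("<LabelMask [%s] %d x %d px, %d instance(s), %.3f um/px>\n",
              x$kind, nrow(x$labels), ncol(x$labels),
              n_instances(x), x$pixel_size_um))
  invisible(x)
}

#' Number of labelled instances in a mask
#' @param mask a `LabelMask`.
#' @return integer instance count (`max(labels)` for consecutive labels).
#' @export
n_instances <- function(mask) {
  stopifnot(inherits(mask, "LabelMask"))
  as.integer(max(mask$labels))
}

#' Relabel instances consecutively 1..N preserving first-pixel order
#' @param mask a `LabelMask` of kind `nuclei-instances`.
#' @return a `LabelMask` whose positive labels are exactly `1..N`, ordered
#'   by original label value.
#' @export
relabel_consecutive <- function(mask) {
  stopifnot(inherits(mask, "LabelMask"))
  lv <- sort(unique(as.vector(mask$labels)))
  lv <- lv[lv > 0L]
  if (length(lv) == 0L) return(mask)
  map <- integer(max(lv))
  map[lv] <- seq_along(lv)
  out <- mask$labels
  pos <- out > 0L
  out[pos] <- map[out[pos]]
  label_mask(out, mask$kind, mask$pixel_size_um)
}

#' Per-instance centroids of a label mask
#'
#' @param mask a `LabelMask` of kind `nuclei-instances`.
#' @param units `"px"` (0-based pixel indices) or `"um"`.
#' @return data.frame with columns `label`, `x`, `y` (x = column, y = row).
#' @export
mask_centroids <- function(mask, units = c("px", "um")) {
  units <- match.arg(units)
  lab <- mask$labels
  idx <- which(lab > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), x = numeric(), y = numeric()))
  h <- nrow(lab)
  rows <- (idx - 1L) %% h          # 0-based row
  cols <- (idx - 1L) %/% h         # 0-based col
  l <- lab[idx]
  cx <- tapply(cols, l, mean)
  cy <- tapply(rows, l, mean)
  out <- data.frame(label = as.integer(names(cx)),
                    x = as.numeric(cx), y = as.numeric(cy))
  out <- out[order(out$label), , drop = FALSE]
  if (units == "um") {
    out$x <- out$x * mask$pixel_size_um
    out$y <- out$y * mask$pixel_size_um
  }
  rownames(out) <- NULL
  out
}

# internal: luminance plane (0..255) from a SlideImage, ITU-R BT.601 weights
luminance <- function(image) {
  p <- image$pixels
  0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
}
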