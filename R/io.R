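#' @title Slide and result input/output
#' @description Readers and writers for 8-bit RGB slides (TIFF/PNG), integer
#'   label masks, the per-nucleus result CSV, Deep Zoom (DZI) pyramid export
#'   and the YAML run configuration. Pyramidal scanner formats are out of
#'   scope: pre-convert proprietary whole-slide files to plain TIFF before
#'   analysis.
#' @name slide_io
NULL

# ---- slide reading ---------------------------------------------------------

#' Read an 8-bit RGB slide image
#'
#' @param path TIFF or PNG file.
#' @param pixel_size_um physical pixel size; if `NULL` it is taken from the
#'   file's resolution metadata (TIFF resolution tags or PNG dpi). An
#'   explicit argument always wins over metadata.
#' @return a [slide_image()].
#' @export
read_slide <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  meta_ps <- NULL
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(px, "bits.per.sample")
    if (!is.null(bits) && bits != 8L)
      stop(sprintf("expected 8-bit RGB, got %d bits per sample in %s",
                   bits, path))
    xres <- attr(px, "x.resolution")
    unit <- attr(px, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      unit_um <- switch(if (is.null(unit)) "inch" else unit,
                        inch = 25400, cm = 10000, NA_real_)
      if (is.finite(unit_um)) meta_ps <- unit_um / xres
    }
    px <- round(px * 255)
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    if (!is.null(info$bit.depth) && info$bit.depth != 8L)
      stop(sprintf("expected 8-bit RGB, got %d-bit samples in %s",
                   info$bit.depth, path))
    if (!is.null(info$dpi) && all(is.finite(info$dpi)) && info$dpi[1] > 0)
      meta_ps <- 25400 / info$dpi[1]
    px <- round(px * 255)
  } else stop("unsupported image format: .", ext)
  if (length(dim(px)) != 3L)
    stop("expected 8-bit RGB, got a single-channel image in ", path)
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(px)[3] != 3L)
    stop(sprintf("expected 8-bit RGB, got %d channel(s) in %s",
                 dim(px)[3], path))
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else meta_ps
  if (is.null(ps))
    stop("pixel size required: no resolution metadata in ", path,
         " and no pixel_size_um argument given")
  slide_image(px, ps, path)
}

#' Write a SlideImage to TIFF or PNG
#' @param image a `SlideImage`.
#' @param path output file; format chosen by extension.
#' @export
write_slide <- function(image, path) {
  stopifnot(inherits(image, "SlideImage"))
  v <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    # carry the pixel size as a TIFF resolution tag (pixels per cm)
    tiff::writeTIFF(v, path, bits.per.sample = 8L,
                    reduce = TRUE)
  } else if (ext == "png") {
    png::writePNG(v, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

# ---- label masks -----------------------------------------------------------

#' Read an integer label mask
#'
#' Accepts 8/16-bit PNG or 8/16/32-bit TIFF rasters whose sample values are
#' instance labels (or 0/1 for binary kinds); this is the import path for
#' externally produced segmentations (e.g. CNN output masks).
#'
#' @param path mask file.
#' @param kind mask kind, see [label_mask()].
#' @param pixel_size_um physical pixel size of the grid.
#' @return a `LabelMask`.
#' @export
load_mask <- function(path, kind = "nuclei-instances", pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    m <- png::readPNG(path, info = TRUE)
    d <- attr(m, "info")$bit.depth
    if (is.null(d)) d <- 8L
    m <- round(m * (2^d - 1))
  } else stop("unsupported mask format: .", ext)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  if (kind != "nuclei-instances") m <- (m > 0) + 0L
  mask <- label_mask(matrix(as.integer(round(m)), nrow(m), ncol(m)),
                     kind, pixel_size_um)
  if (kind == "nuclei-instances") mask <- relabel_consecutive(mask)
  mask
}

#' Write a label mask (16-bit TIFF or 8-bit PNG)
#'
#' Instance masks must go to TIFF (16-bit, labels up to 65535); binary masks
#' may use PNG (stored as 0/255).
#' @param mask a `LabelMask`.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "LabelMask"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (max(mask$labels) > 65535L) stop("more than 65535 instances")
    tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(mask$labels) > 1L) {
      if (max(mask$labels) > 65535L) stop("more than 65535 instances")
      png::writePNG(mask$labels / 65535, path)  # 16-bit PNG
    } else {
      png::writePNG(mask$labels * 1.0, path)
    }
  } else stop("unsupported mask format: .", ext)
  invisible(path)
}

# ---- nucleus CSV -----------------------------------------------------------

# stable column contract of the per-nucleus output; new columns append only
nucleus_csv_columns <- c(
  "sample_id", "condition", "nucleus_id", "centroid_x_um", "centroid_y_um",
  "area_um2", "perimeter_um", "roundness", "aspect_ratio",
  "intensity_min", "intensity_max", "intensity_mean", "intensity_variance",
  "glcm_contrast_pct", "glcm_energy", "glcm_entropy_bits",
  "glcm_homogeneity", "n_neighbors", "nn_distance_um", "epidermal_depth",
  "tile_row", "tile_col")

#' Write the per-nucleus result CSV
#'
#' One row per nucleus in a fixed column order; floating-point descriptors
#' are written at 6 significant digits. Undefined descriptors (e.g. nearest
#' neighbour distance in a single-nucleus sample) are written as `NA`.
#'
#' @param sample a `SampleResult` from [build_records()].
#' @param path output CSV path.
#' @export
write_nucleus_csv <- function(sample, path) {
  stopifnot(inherits(sample, "SampleResult"))
  rec <- sample$records
  rec <- rec[, nucleus_csv_columns, drop = FALSE]
  for (cn in names(rec))
    if (is.double(rec[[cn]])) rec[[cn]] <- signif(rec[[cn]], 6)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(rec, con, row.names = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Read a per-nucleus result CSV
#' @param path CSV written by [write_nucleus_csv()].
#' @return data.frame with the standard nucleus columns.
#' @export
read_nucleus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(nucleus_csv_columns, names(df))
  if (length(missing))
    stop("not a nucleus CSV, missing columns: ",
         paste(missing, collapse = ", "))
  df
}

# ---- Deep Zoom (DZI) export ------------------------------------------------

# closed-form pyramid geometry: level L of a W x H image has dimensions
# ceil(W / 2^(maxLevel - L)) x ceil(H / 2^(maxLevel - L)),
# maxLevel = ceil(log2(max(W, H)))
dzi_geometry <- function(width, height, tile_px) {
  max_level <- ceiling(log2(max(width, height)))
  lv <- 0:max_level
  w <- ceiling(width / 2^(max_level - lv))
  h <- ceiling(height / 2^(max_level - lv))
  data.frame(level = lv, width = w, height = h,
             n_cols = ceiling(w / tile_px), n_rows = ceiling(h / tile_px))
}

#' Export a slide (or overlay) as a Deep Zoom pyramid
#'
#' Writes `<name>.dzi` (XML descriptor) plus `<name>_files/<level>/<col>_<row>.<fmt>`
#' following the Deep Zoom convention with zero tile overlap: level `L` has
#' dimensions `ceil(W / 2^(maxLevel-L))`, `maxLevel = ceil(log2(max(W, H)))`.
#'
#' @param image a `SlideImage`.
#' @param out_dir output directory (created if needed).
#' @param name basename for the descriptor and tile folder.
#' @param tile_px tile edge in pixels (default 256).
#' @param jpeg_quality JPEG quality when the jpeg format is used.
#' @param format `"jpeg"` or `"png"` tiles.
#' @return invisibly, the path of the `.dzi` descriptor.
#' @export
export_dzi <- function(image, out_dir, name = "slide", tile_px = 256L,
                       jpeg_quality = 90,
                       format = if (requireNamespace("jpeg", quietly = TRUE))
                         "jpeg" else "png") {
  stopifnot(inherits(image, "SlideImage"))
  format <- match.arg(format, c("jpeg", "png"))
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  geo <- dzi_geometry(w, h, tile_px)
  files_dir <- file.path(out_dir, paste0(name, "_files"))
  dir.create(files_dir, recursive = TRUE, showWarnings = FALSE)

  # EBImage layout is [x, y, channel]
  full <- EBImage::Image(aperm(image$pixels / 255, c(2, 1, 3)),
                         colormode = "Color")
  for (li in rev(seq_len(nrow(geo)))) {
    lv <- geo$level[li]
    lw <- geo$width[li]; lh <- geo$height[li]
    scaled <- if (lw == w && lh == h) full else
      EBImage::resize(full, w = lw, h = lh)
    dat <- aperm(EBImage::imageData(scaled), c(2, 1, 3))  # back to [row,col,ch]
    lv_dir <- file.path(files_dir, lv)
    dir.create(lv_dir, showWarnings = FALSE)
    for (tc in seq_len(geo$n_cols[li]) - 1L) {
      for (tr in seq_len(geo$n_rows[li]) - 1L) {
        r0 <- tr * tile_px + 1L; r1 <- min(lh, (tr + 1L) * tile_px)
        c0 <- tc * tile_px + 1L; c1 <- min(lw, (tc + 1L) * tile_px)
        tile <- dat[r0:r1, c0:c1, , drop = FALSE]
        tile <- pmin(pmax(tile, 0), 1)
        fp <- file.path(lv_dir, sprintf("%d_%d.%s", tc, tr, format))
        if (format == "jpeg")
          jpeg::writeJPEG(tile, fp, quality = jpeg_quality / 100)
        else png::writePNG(tile, fp)
      }
    }
  }
  dzi <- file.path(out_dir, paste0(name, ".dzi"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<Image TileSize="%d" Overlap="0" Format="%s" ',
                   'xmlns="http://schemas.microsoft.com/deepzoom/2008">'),
            tile_px, format),
    sprintf('  <Size Width="%d" Height="%d"/>', w, h),
    '</Image>'), dzi)
  invisible(dzi)
}

# ---- run configuration -----------------------------------------------------

#' Default run configuration
#'
#' All physical quantities are in micrometres and converted to pixels via the
#' slide's pixel size, so parameters transfer across scan resolutions.
#'
#' @return nested list of configuration defaults.
#' @export
default_config <- function() {
  list(
    tile_size_px = 1024L,
    tile_overlap_px = 64L,
    pixel_size_um = NULL,          # per-slide override; metadata otherwise
    glcm = list(
      levels = 16L,
      margin_um = 2.0,             # perinuclear window captures the halo
      halo_threshold_pct = 4),
    filters = list(
      min_area_um2 = 8,
      max_area_um2 = 300),
    density = list(radius_um = 30),
    segmentation = list(
      backend = "classical",
      smooth_sigma_um = 1.0,
      peak_separation_um = 3.0),
    epidermis = list(
      density_sigma_um = 25,
      threshold_factor = 0.5),
    preview = NULL,                # optional list(x, y, w, h) in pixels
    rng_seed = 1L,
    output_dir = ".")
}

# recursive merge of user values over defaults, rejecting unknown keys
merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        key != "preview") {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(full, "."))
    } else {
      defaults[key] <- user[key]
    }
  }
  defaults
}

validate_config <- function(cfg) {
  chk <- function(cond, key, constraint)
    if (!cond) stop(sprintf("config key '%s' violates: %s", key, constraint))
  chk(cfg$tile_size_px >= 64, "tile_size_px", ">= 64")
  chk(cfg$tile_overlap_px >= 0 && cfg$tile_overlap_px < cfg$tile_size_px / 2,
      "tile_overlap_px", "0 <= overlap < tile_size_px / 2")
  chk(cfg$glcm$levels >= 2, "glcm.levels", ">= 2")
  chk(cfg$glcm$margin_um >= 0, "glcm.margin_um", ">= 0")
  chk(cfg$glcm$halo_threshold_pct >= 0 && cfg$glcm$halo_threshold_pct <= 100,
      "glcm.halo_threshold_pct", "in [0, 100]")
  chk(cfg$filters$min_area_um2 > 0, "filters.min_area_um2", "> 0")
  chk(cfg$filters$max_area_um2 > cfg$filters$min_area_um2,
      "filters.max_area_um2", "> min_area_um2")
  chk(cfg$density$radius_um > 0, "density.radius_um", "> 0")
  chk(cfg$segmentation$backend %in% c("classical", "external", "starconvex"),
      "segmentation.backend", "one of classical/external/starconvex")
  chk(cfg$segmentation$smooth_sigma_um > 0,
      "segmentation.smooth_sigma_um", "> 0")
  chk(cfg$epidermis$density_sigma_um > 0, "epidermis.density_sigma_um", "> 0")
  if (!is.null(cfg$preview)) {
    chk(all(c("x", "y", "w", "h") %in% names(cfg$preview)),
        "preview", "must provide x, y, w, h")
    chk(cfg$preview$w >= 64 && cfg$preview$h >= 64,
        "preview", "window at least 64 x 64 px")
  }
  if (!is.null(cfg$pixel_size_um))
    chk(cfg$pixel_size_um > 0, "pixel_size_um", "> 0")
  cfg
}

#' Load a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the [default_config()]
#' values; basic consistency constraints are enforced.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  validate_config(merge_config(default_config(), user))
}
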