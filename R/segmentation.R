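#' @title Tissue, nucleus and epidermis segmentation
#' @description Classical segmentation backend plus tiled execution with
#'   cross-tile label merging. The nucleus segmenter operates on the
#'   hematoxylin optical-density plane obtained by color deconvolution;
#'   backends are pluggable so externally produced instance masks (e.g. from
#'   a U-Net or star-convex CNN) can be imported in place of the classical
#'   watershed baseline.
#' @name segmentation
NULL

# Ruifrok-Johnston H&E(+residual) stain matrix; rows are unit OD vectors.
he_stain_matrix <- function() {
  m <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             r = c(0.268, 0.570, 0.776))
  m / sqrt(rowSums(m^2))
}

#' Color deconvolution into hematoxylin / eosin / residual optical density
#'
#' Per-pixel optical density `OD = -log10((I + 1) / 256)` is unmixed with
#' the fixed Ruifrok-Johnston H&E stain matrix; negative stain
#' concentrations are clipped at 0. The `+1` offset keeps black pixels
#' finite.
#'
#' @param image a `SlideImage`.
#' @return list of numeric `H x W` matrices `hematoxylin`, `eosin`,
#'   `residual` (stain concentrations in OD units).
#' @export
deconvolve_hed <- function(image) {
  stopifnot(inherits(image, "SlideImage"))
  p <- image$pixels
  h <- dim(p)[1]; w <- dim(p)[2]
  od <- -log10((matrix(p, h * w, 3) + 1) / 256)
  conc <- od %*% solve(he_stain_matrix())
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1], h, w),
       eosin = matrix(conc[, 2], h, w),
       residual = matrix(conc[, 3], h, w))
}

# helpers to hop between base matrices [row, col] and EBImage [x, y]
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(img) t(EBImage::imageData(img))

# Gaussian blur with replicated boundary whose kernel never exceeds the
# image (small preview windows with a large sigma would otherwise fail)
gblur_safe <- function(m, sigma) {
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- min(dim(m))
  if (cap %% 2L == 0L) cap <- cap - 1L
  radius <- min(radius, cap)
  from_ebi(EBImage::gblur(as_ebi(m), sigma = sigma, radius = radius,
                          boundary = "replicate"))
}

#' Detect the tissue region of interest
#'
#' Tissue is taken as pixels whose HSV saturation exceeds an Otsu threshold
#' or whose brightness falls below 92% of white, followed by morphological
#' closing (disk, 5 px) and removal of connected components smaller than
#' 1000 square micrometres. On an all-background image an empty mask is
#' returned with a warning.
#'
#' @param image a `SlideImage`.
#' @return binary `LabelMask` of kind `tissue-binary`.
#' @export
detect_tissue_roi <- function(image) {
  stopifnot(inherits(image, "SlideImage"))
  p <- image$pixels
  mx <- pmax(p[, , 1], p[, , 2], p[, , 3])
  mn <- pmin(p[, , 1], p[, , 2], p[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  val <- mx / 255
  # Otsu needs a bimodal histogram; near-constant saturation (blank slide
  # or wall-to-wall tissue) falls back to a fixed colorfulness floor
  thr <- if (diff(range(sat)) < 0.05) 0.15 else
    EBImage::otsu(as_ebi(sat), range = c(0, 1))
  tissue <- sat > thr | val < 0.92
  ps <- image$pixel_size_um
  tb <- EBImage::closing(as_ebi(tissue + 0),
                         EBImage::makeBrush(11, "disc"))  # disk radius 5 px
  lab <- EBImage::bwlabel(tb)
  min_px <- 1000 / ps^2
  sizes <- tabulate(EBImage::imageData(lab))
  keep <- which(sizes >= min_px)
  out <- matrix(0L, nrow(sat), ncol(sat))
  if (length(keep)) {
    lm <- from_ebi(lab)
    out[lm %in% keep] <- 1L
  }
  if (sum(out) == 0L)
    warning("no tissue detected; returning an empty tissue mask")
  label_mask(out, "tissue-binary", ps)
}

#' Otsu threshold of the hematoxylin plane
#'
#' Computed over a whole slide once so that tile-wise segmentation uses the
#' same global threshold as an untiled run.
#' @param hema hematoxylin OD matrix.
#' @return scalar threshold in OD units.
#' @export
hematoxylin_threshold <- function(hema) {
  rng <- range(hema)
  if (diff(rng) < 1e-9) return(Inf)
  # otsu expects [0,1]; rescale and map the threshold back
  sc <- (hema - rng[1]) / diff(rng)
  EBImage::otsu(as_ebi(sc), range = c(0, 1)) * diff(rng) + rng[1]
}

#' Segment nucleus instances in one tile (classical backend)
#'
#' Hematoxylin OD plane, Gaussian smoothing (sigma 1 um), Otsu threshold,
#' hole filling, distance transform, peak markers with a minimum separation
#' of about 3 um, and watershed splitting.
#'
#' @param tile a `SlideImage` (a full slide is just a big tile).
#' @param cfg run configuration ([default_config()]).
#' @param threshold optional precomputed hematoxylin threshold (OD units);
#'   when `NULL` an Otsu threshold over this tile is used.
#' @return instance `LabelMask` with labels `1..N`.
#' @export
segment_nuclei_tile <- function(tile, cfg = default_config(),
                                threshold = NULL) {
  stopifnot(inherits(tile, "SlideImage"))
  ps <- tile$pixel_size_um
  hema <- deconvolve_hed(tile)$hematoxylin
  sigma <- cfg$segmentation$smooth_sigma_um / ps
  # replicated boundary so a tile window and the full slide agree at edges
  sm <- gblur_safe(hema, sigma)
  if (is.null(threshold)) threshold <- hematoxylin_threshold(sm)
  fg <- sm > threshold
  if (!any(fg))
    return(label_mask(matrix(0L, nrow(hema), ncol(hema)),
                      "nuclei-instances", ps))
  fg <- EBImage::fillHull(as_ebi(fg + 0))
  dm <- EBImage::distmap(fg)
  ext <- max(1L, round(cfg$segmentation$peak_separation_um / ps / 2))
  ws <- EBImage::watershed(dm, tolerance = 0.5, ext = ext)
  relabel_consecutive(
    label_mask(matrix(as.integer(from_ebi(ws)), nrow(hema), ncol(hema)),
               "nuclei-instances", ps))
}

#' Segment the epidermis (density-band baseline)
#'
#' The epidermis is the nucleus-dense band at the outer tissue surface. A
#' nuclear-centroid density map (Gaussian kernel, sigma 25 um) is
#' thresholded at 0.5 times its 99th percentile, intersected with the
#' tissue, restricted to the connected band reaching the tissue's outer
#' (top) boundary, and morphologically closed.
#'
#' @param image `SlideImage` (used for the grid only).
#' @param nuclei instance `LabelMask`.
#' @param tissue binary tissue `LabelMask`.
#' @param cfg run configuration.
#' @return binary `LabelMask` of kind `epidermis-binary`.
#' @export
segment_epidermis <- function(image, nuclei, tissue, cfg = default_config()) {
  ps <- nuclei$pixel_size_um
  h <- nrow(nuclei$labels); w <- ncol(nuclei$labels)
  empty <- function() {
    warning("no epidermal band found; returning an empty epidermis mask")
    label_mask(matrix(0L, h, w), "epidermis-binary", ps)
  }
  cent <- mask_centroids(nuclei)
  if (nrow(cent) == 0L) return(empty())
  dens <- matrix(0, h, w)
  ri <- pmin(h, pmax(1L, floor(cent$y + 0.5) + 1L))
  ci <- pmin(w, pmax(1L, floor(cent$x + 0.5) + 1L))
  for (k in seq_along(ri)) dens[ri[k], ci[k]] <- dens[ri[k], ci[k]] + 1
  sigma <- cfg$epidermis$density_sigma_um / ps
  dens <- gblur_safe(dens, sigma)
  thr <- cfg$epidermis$threshold_factor * stats::quantile(dens, 0.99)
  band <- dens > thr & tissue$labels == 1L
  if (!any(band)) return(empty())

  # outer surface: first tissue pixel from the top in each column
  surf <- matrix(FALSE, h, w)
  first_row <- apply(tissue$labels == 1L, 2, function(col)
    if (any(col)) which(col)[1] else NA_integer_)
  ok <- which(!is.na(first_row))
  surf[cbind(first_row[ok], ok)] <- TRUE
  # distance of every pixel to the outer surface
  dsurf <- from_ebi(EBImage::distmap(as_ebi((!surf) + 0)))

  lab <- EBImage::bwlabel(as_ebi(band + 0))
  labm <- from_ebi(lab)
  reach <- 2 * sigma
  comp_min <- tapply(dsurf[labm > 0], labm[labm > 0], min)
  keep <- as.integer(names(comp_min))[comp_min <= reach]
  if (length(keep) == 0L) return(empty())
  band <- matrix(0L, h, w)
  band[labm %in% keep] <- 1L
  closed <- from_ebi(EBImage::closing(
    as_ebi(band), EBImage::makeBrush(2L * max(1L, round(sigma / 5)) + 1L,
                                     "disc")))
  label_mask(matrix(as.integer(closed > 0), h, w), "epidermis-binary", ps)
}

# ---- tiling ----------------------------------------------------------------

#' Tile grid with overlapping windows and exclusive cores
#'
#' The slide is partitioned into non-overlapping core regions of
#' `tile_size_px`; each tile's processing window is its core expanded by
#' `overlap_px` on interior edges. Every pixel belongs to exactly one core.
#'
#' @param height,width slide size in pixels.
#' @param tile_size_px core edge length.
#' @param overlap_px window expansion on interior edges.
#' @return data.frame of tile windows and cores (0-based, half-open
#'   intervals): `tile_row`, `tile_col`, `win_r0`, `win_r1`, `win_c0`,
#'   `win_c1`, `core_r0`, `core_r1`, `core_c0`, `core_c1`.
#' @export
tile_grid <- function(height, width, tile_size_px = 1024L,
                      overlap_px = 64L) {
  stopifnot(overlap_px < tile_size_px / 2)
  nr <- max(1L, ceiling(height / tile_size_px))
  nc <- max(1L, ceiling(width / tile_size_px))
  g <- expand.grid(tile_row = seq_len(nr), tile_col = seq_len(nc))
  g$core_r0 <- (g$tile_row - 1L) * tile_size_px
  g$core_r1 <- pmin(height, g$tile_row * tile_size_px)
  g$core_c0 <- (g$tile_col - 1L) * tile_size_px
  g$core_c1 <- pmin(width, g$tile_col * tile_size_px)
  g$win_r0 <- pmax(0L, g$core_r0 - overlap_px)
  g$win_r1 <- pmin(height, g$core_r1 + overlap_px)
  g$win_c0 <- pmax(0L, g$core_c0 - overlap_px)
  g$win_c1 <- pmin(width, g$core_c1 + overlap_px)
  g
}

# tile index owning a (fractional) 0-based coordinate; a centroid exactly on
# a core boundary goes to the lower tile index
core_index <- function(coord, tile_size_px) {
  pmax(1L, as.integer(ceiling(coord / tile_size_px)))
}

#' Tiled nucleus segmentation with cross-tile label merging
#'
#' Each tile is segmented independently on its overlap-expanded window using
#' a single slide-global hematoxylin threshold; an instance is kept iff its
#' centroid lies in the tile's exclusive core (ties on a core boundary go to
#' the lower tile index), and kept instances are relabelled globally. For
#' slides whose nuclei are smaller than the overlap this reproduces the
#' untiled segmentation exactly.
#'
#' @param image a `SlideImage`.
#' @param cfg run configuration.
#' @param backend `"classical"` or a function `(tile, cfg, threshold) ->
#'   LabelMask`.
#' @return instance `LabelMask` over the whole slide.
#' @export
run_tiled <- function(image, cfg = default_config(), backend = "classical") {
  stopifnot(inherits(image, "SlideImage"))
  ps <- image$pixel_size_um
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  ts <- cfg$tile_size_px; ov <- cfg$tile_overlap_px
  max_diam_px <- 2 * sqrt(cfg$filters$max_area_um2 / pi) / ps
  if (ov > 0 && ov < max_diam_px)
    warning(sprintf(paste0("tile overlap (%d px) is smaller than the ",
                           "maximum expected nucleus diameter (%.0f px); ",
                           "cross-tile merging may split nuclei"),
                    ov, max_diam_px))
  seg_fun <- if (is.function(backend)) backend else switch(
    backend,
    classical = segment_nuclei_tile,
    stop("unknown segmentation backend: ", backend))

  # slide-global threshold so tiling does not change the decision rule
  hema <- deconvolve_hed(image)$hematoxylin
  sm <- gblur_safe(hema, cfg$segmentation$smooth_sigma_um / ps)
  thr <- hematoxylin_threshold(sm)

  grid <- tile_grid(h, w, ts, ov)
  canvas <- matrix(0L, h, w)
  next_label <- 0L
  for (gi in seq_len(nrow(grid))) {
    gr <- grid[gi, ]
    win <- image$pixels[(gr$win_r0 + 1L):gr$win_r1,
                        (gr$win_c0 + 1L):gr$win_c1, , drop = FALSE]
    tile <- slide_image(win, ps, image$source_path)
    lm <- seg_fun(tile, cfg, threshold = thr)
    cent <- mask_centroids(lm)
    if (nrow(cent) == 0L) next
    gy <- cent$y + gr$win_r0
    gx <- cent$x + gr$win_c0
    keep <- cent$label[core_index(gy, ts) == gr$tile_row &
                       core_index(gx, ts) == gr$tile_col]
    if (length(keep) == 0L) next
    sub <- lm$labels
    rows <- (gr$win_r0 + 1L):gr$win_r1
    cols <- (gr$win_c0 + 1L):gr$win_c1
    patch <- canvas[rows, cols]
    for (lb in keep) {
      next_label <- next_label + 1L
      sel <- sub == lb & patch == 0L
      patch[sel] <- next_label
    }
    canvas[rows, cols] <- patch
  }
  relabel_consecutive(label_mask(canvas, "nuclei-instances", ps))
}

#' Remove non-epidermal and out-of-size nuclei
#'
#' Drops instances whose centroid lies outside the epidermis mask and
#' instances whose area falls outside the configured physical bounds, then
#' relabels the survivors consecutively.
#'
#' @param nuclei instance `LabelMask`.
#' @param epidermis binary `LabelMask`, or `NULL` to skip the location
#'   filter.
#' @param cfg run configuration (area bounds under `filters`).
#' @return filtered instance `LabelMask`.
#' @export
filter_nuclei <- function(nuclei, epidermis = NULL, cfg = default_config()) {
  stopifnot(inherits(nuclei, "LabelMask"))
  lab <- nuclei$labels
  n <- max(lab)
  if (n == 0L) return(nuclei)
  ps <- nuclei$pixel_size_um
  areas <- tabulate(lab[lab > 0L], n) * ps^2
  keep <- areas >= cfg$filters$min_area_um2 &
          areas <= cfg$filters$max_area_um2
  if (!is.null(epidermis)) {
    stopifnot(identical(dim(epidermis$labels), dim(lab)))
    cent <- mask_centroids(nuclei)
    ri <- pmin(nrow(lab), pmax(1L, floor(cent$y + 0.5) + 1L))
    ci <- pmin(ncol(lab), pmax(1L, floor(cent$x + 0.5) + 1L))
    inside <- epidermis$labels[cbind(ri, ci)] == 1L
    keep[cent$label[!inside]] <- FALSE
  }
  out <- lab
  out[!(lab %in% which(keep))] <- 0L
  relabel_consecutive(label_mask(out, "nuclei-instances", ps))
}
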