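#' @title Per-nucleus morphometric descriptors
#' @description Shape, intensity, texture, density and epidermal-location
#'   descriptors for segmented nuclei. The texture block computes gray-level
#'   co-occurrence (GLCM) features over a window consisting of the nucleus
#'   mask dilated by a fixed physical margin, so that the perinuclear space
#'   -- where the bright "halo" of damaged nuclei lives -- contributes to
#'   the score. The normalized GLCM contrast of that window, expressed as a
#'   percentage, is the per-nucleus high-contrast score whose sample mean is
#'   the high contrast mean (HCM).
#' @name morphometry
NULL

#' GLCM configuration
#'
#' @param levels number of gray levels `G` (quantization
#'   `level = floor(I * G / 256)` over the fixed range `[0, 255]`).
#' @param margin_um radius of the disk by which the nucleus mask is dilated
#'   to form the texture window (captures the perinuclear halo).
#' @param halo_threshold_pct per-nucleus contrast percentage above which a
#'   nucleus counts as "haloed" in sample summaries.
#' @return a `GlcmConfig` list. Offsets are fixed at the four distance-1
#'   directions (0,1), (1,0), (1,1), (1,-1), symmetrized; entropy is in
#'   bits (log base 2).
#' @export
glcm_config <- function(levels = 16L, margin_um = 2.0,
                        halo_threshold_pct = 4) {
  stopifnot(levels >= 2L, margin_um >= 0)
  list(levels = as.integer(levels), margin_um = margin_um,
       halo_threshold_pct = halo_threshold_pct)
}

glcm_offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

# symmetrized, normalized co-occurrence matrix for one offset; NULL when the
# offset yields no in-window pair
glcm_matrix_g <- function(q, win, dr, dc, G) {
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 > r1 || c0 > c1) return(NULL)
  ra <- r0:r1; ca <- c0:c1
  rb <- ra + dr; cb <- ca + dc
  ok <- win[ra, ca, drop = FALSE] & win[rb, cb, drop = FALSE]
  if (!any(ok)) return(NULL)
  qa <- q[ra, ca, drop = FALSE][ok]
  qb <- q[rb, cb, drop = FALSE][ok]
  counts <- tabulate(qa * G + qb + 1L, nbins = G * G)
  m <- matrix(counts, G, G, byrow = TRUE)   # rows = level of first pixel
  m <- m + t(m)                             # symmetric
  list(P = m / sum(m), npairs = length(qa))
}

glcm_features_from_p <- function(P, G) {
  i <- row(P) - 1L; j <- col(P) - 1L
  pos <- P > 0
  c(contrast = sum((i - j)^2 * P),
    energy = sum(P^2),
    entropy_bits = -sum(P[pos] * log2(P[pos])),
    homogeneity = sum(P / (1 + abs(i - j))))
}

#' GLCM texture features of a masked window
#'
#' Gray values are quantized to `G` levels over the fixed range `[0, 255]`
#' (`level = floor(I * G / 256)`); co-occurrence counts are accumulated over
#' all pixel pairs with both pixels inside the window, for each of the four
#' distance-1 offsets, symmetrized and normalized per offset; the four
#' offsets' features are averaged. Contrast is reported as a percentage of
#' its maximum `(G - 1)^2`, making it bounded in `[0, 100]` and comparable
#' across quantization choices.
#'
#' @param gray numeric matrix of intensities in `[0, 255]`.
#' @param window logical/0-1 matrix, same size: the texture window (nucleus
#'   mask dilated by the margin; see [glcm_window()]).
#' @param cfg a [glcm_config()].
#' @param offsets list of `(row, col)` offset pairs (defaults to the four
#'   standard distance-1 directions).
#' @return named numeric vector `contrast_pct`, `energy`, `entropy_bits`,
#'   `homogeneity`; all `NA` (undefined) when no offset yields at least two
#'   in-window pixel pairs.
#' @export
glcm_features <- function(gray, window, cfg = glcm_config(),
                          offsets = glcm_offsets) {
  stopifnot(identical(dim(gray), dim(window)))
  G <- cfg$levels
  q <- pmin(floor(gray * G / 256), G - 1L)
  storage.mode(q) <- "integer"
  win <- window > 0
  feats <- list(); max_pairs <- 0L
  for (off in offsets) {
    m <- glcm_matrix_g(q, win, off[1], off[2], G)
    if (!is.null(m)) {
      feats[[length(feats) + 1L]] <- glcm_features_from_p(m$P, G)
      max_pairs <- max(max_pairs, m$npairs)
    }
  }
  if (length(feats) == 0L || max_pairs < 2L)
    return(c(contrast_pct = NA_real_, energy = NA_real_,
             entropy_bits = NA_real_, homogeneity = NA_real_))
  f <- colMeans(do.call(rbind, feats))
  c(contrast_pct = 100 * f[["contrast"]] / (G - 1)^2,
    energy = f[["energy"]],
    entropy_bits = f[["entropy_bits"]],
    homogeneity = f[["homogeneity"]])
}

#' Texture window for a nucleus: the mask dilated by a physical margin
#' @param mask logical/0-1 instance mask.
#' @param pixel_size_um pixel size.
#' @param margin_um dilation radius in micrometres.
#' @return logical matrix.
#' @export
glcm_window <- function(mask, pixel_size_um, margin_um = 2.0) {
  r <- round(margin_um / pixel_size_um)
  if (r < 1) return(mask > 0)
  br <- EBImage::makeBrush(2L * r + 1L, "disc")
  from_ebi(EBImage::dilate(as_ebi((mask > 0) + 0), br)) > 0
}

# ---- shape -----------------------------------------------------------------

# marching-squares contour length of a binary mask, with one pass of
# circular vertex smoothing to remove the staircase bias of the raw contour
ms_perimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  total <- 0
  for (cc in cl) {
    v <- cbind(cc$x, cc$y)
    if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    n <- nrow(v)
    if (n < 2) next
    # circular moving average (window 3)
    up <- v[c(2:n, 1), , drop = FALSE]
    dn <- v[c(n, 1:(n - 1)), , drop = FALSE]
    vs <- (up + v + dn) / 3
    d <- vs[c(2:n, 1), , drop = FALSE] - vs
    total <- total + sum(sqrt(rowSums(d^2)))
  }
  total
}

#' Shape descriptors of one instance mask
#'
#' Area is the pixel count scaled to square micrometres; the perimeter is a
#' smoothed marching-squares contour length; roundness is
#' `4 * pi * area / perimeter^2` clipped to 1; the aspect ratio is the
#' major/minor axis ratio of the best-fit ellipse from second-order central
#' moments (degenerate line-like masks report the sentinel `1e6`).
#'
#' @param mask logical/0-1 matrix covering (at least) the instance.
#' @param pixel_size_um pixel size.
#' @return named vector `area_um2`, `perimeter_um`, `roundness`,
#'   `aspect_ratio`.
#' @export
shape_features <- function(mask, pixel_size_um) {
  idx <- which(mask > 0)
  if (length(idx) < 4L) stop("instance must have at least 4 pixels")
  h <- nrow(mask)
  ys <- (idx - 1L) %% h
  xs <- (idx - 1L) %/% h
  area <- length(idx) * pixel_size_um^2
  per <- ms_perimeter(mask) * pixel_size_um
  roundness <- min(1, 4 * pi * area / per^2)
  mu <- cbind(xs - mean(xs), ys - mean(ys))
  # +1/12 diagonal term: variance of a unit pixel, stabilizes thin shapes
  cv <- crossprod(mu) / length(idx) + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  aspect <- if (ev[2] <= 1e-12) 1e6 else sqrt(ev[1] / ev[2])
  c(area_um2 = area, perimeter_um = per, roundness = roundness,
    aspect_ratio = aspect)
}

# ---- intensity -------------------------------------------------------------

#' Intensity statistics inside an instance mask
#'
#' Statistics of the luminance plane (`0.299 R + 0.587 G + 0.114 B`) over
#' pixels strictly inside the mask; the variance is the population variance.
#'
#' @param gray numeric matrix (luminance, 0-255).
#' @param mask logical/0-1 instance mask.
#' @return named vector `min`, `max`, `mean`, `variance`.
#' @export
intensity_features <- function(gray, mask) {
  v <- gray[mask > 0]
  if (length(v) == 0L) stop("empty instance mask")
  m <- mean(v)
  c(min = min(v), max = max(v), mean = m,
    variance = mean((v - m)^2))
}

# ---- density ---------------------------------------------------------------

#' Neighbourhood density features for all nuclei of a sample
#'
#' @param centroids_um data.frame/matrix with columns `x`, `y` in
#'   micrometres (one row per nucleus).
#' @param radius_um neighbourhood radius for the neighbour count.
#' @return data.frame `n_neighbors`, `nn_distance_um` (the latter `NA` for a
#'   single-nucleus sample).
#' @export
density_features <- function(centroids_um, radius_um = 30) {
  x <- centroids_um[["x"]]; y <- centroids_um[["y"]]
  n <- length(x)
  stopifnot(n >= 1L)
  if (n == 1L)
    return(data.frame(n_neighbors = 0L, nn_distance_um = NA_real_))
  nn <- integer(n); nnd <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    nn[i] <- sum(d <= radius_um)
    nnd[i] <- min(d)
  }
  data.frame(n_neighbors = nn, nn_distance_um = nnd)
}

# ---- epidermal depth -------------------------------------------------------

# distance maps (px) to the epidermis' outer surface and to its dermal
# boundary; used to express a nucleus position as a relative depth
epidermal_depth_maps <- function(epidermis, tissue) {
  e <- epidermis$labels == 1L
  t <- tissue$labels == 1L
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  pad_true <- function(m, dr, dc) {  # out-of-frame counts as non-tissue
    out <- matrix(TRUE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
    okr <- rs >= 1 & rs <= nrow(m); okc <- cs >= 1 & cs <= ncol(m)
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  non_tissue_adj <- matrix(FALSE, nrow(e), ncol(e))
  dermal_adj <- matrix(FALSE, nrow(e), ncol(e))
  for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    non_tissue_adj <- non_tissue_adj | pad_true(!t, d[1], d[2])
    dermal_adj <- dermal_adj | shift(t & !e, d[1], d[2])
  }
  outer_surface <- e & non_tissue_adj
  dermal_boundary <- e & dermal_adj
  dist_to <- function(set) {
    if (!any(set)) return(matrix(Inf, nrow(e), ncol(e)))
    from_ebi(EBImage::distmap(as_ebi((!set) + 0)))
  }
  list(d_top = dist_to(outer_surface), d_bot = dist_to(dermal_boundary))
}

#' Relative depth of a nucleus within the epidermis
#'
#' `depth = d_top / (d_top + d_bot)` where `d_top` is the Euclidean distance
#' to the epidermis' outer surface (pixels adjacent to non-tissue) and
#' `d_bot` the distance to its dermal boundary; 0 is the surface (stratum
#' corneum side), 1 the basal side. Centroids outside the epidermis are
#' undefined (`NA`).
#'
#' @param centroid numeric `(x, y)` in 0-based pixel coordinates.
#' @param epidermis binary epidermis `LabelMask`.
#' @param tissue binary tissue `LabelMask`.
#' @param maps optional precomputed [epidermal_depth_maps()] output.
#' @return depth in `[0, 1]`, or `NA`.
#' @export
epidermal_depth <- function(centroid, epidermis, tissue, maps = NULL) {
  r <- floor(centroid[2] + 0.5) + 1L
  c <- floor(centroid[1] + 0.5) + 1L
  lab <- epidermis$labels
  if (r < 1 || r > nrow(lab) || c < 1 || c > ncol(lab) ||
      lab[r, c] != 1L) return(NA_real_)
  if (is.null(maps)) maps <- epidermal_depth_maps(epidermis, tissue)
  dt <- maps$d_top[r, c]; db <- maps$d_bot[r, c]
  if (!is.finite(dt) && !is.finite(db)) return(NA_real_)
  if (!is.finite(db)) return(0)
  if (!is.finite(dt)) return(1)
  if (dt + db == 0) return(0)
  dt / (dt + db)
}

# ---- record assembly -------------------------------------------------------

#' Compute all descriptors for every nucleus of a sample
#'
#' Produces one record per instance with every descriptor populated or
#' explicitly `NA`-flagged (never silently dropped), ordered by label id.
#'
#' @param image `SlideImage`.
#' @param nuclei instance `LabelMask` (post-filter).
#' @param epidermis binary epidermis `LabelMask`, or `NULL` (depth
#'   undefined).
#' @param cfg run configuration ([default_config()]).
#' @param sample_id,condition metadata copied into every record.
#' @param tissue binary tissue `LabelMask`; defaults to "everything is
#'   tissue" when `NULL` (depth then measures distance to the epidermis
#'   boundary on both sides).
#' @return a `SampleResult`: list with `sample_id`, `condition`, `records`
#'   (data.frame in the nucleus CSV schema), `hcm_mean_pct`,
#'   `haloed_fraction_pct`, `n_nuclei`.
#' @export
build_records <- function(image, nuclei, epidermis = NULL,
                          cfg = default_config(),
                          sample_id = "sample", condition = "",
                          tissue = NULL) {
  stopifnot(inherits(image, "SlideImage"), inherits(nuclei, "LabelMask"))
  ps <- nuclei$pixel_size_um
  lab <- nuclei$labels
  n <- max(lab)
  gray <- luminance(image)
  gcfg <- glcm_config(cfg$glcm$levels, cfg$glcm$margin_um,
                      cfg$glcm$halo_threshold_pct)
  empty_rec <- function() {
    df <- data.frame(matrix(nrow = 0, ncol = length(nucleus_csv_columns)))
    names(df) <- nucleus_csv_columns
    df
  }
  if (n == 0L)
    return(structure(list(sample_id = sample_id, condition = condition,
                          records = empty_rec(), hcm_mean_pct = NA_real_,
                          haloed_fraction_pct = NA_real_, n_nuclei = 0L),
                     class = "SampleResult"))

  h <- nrow(lab); w <- ncol(lab)
  idx_by_label <- split(which(lab > 0L), lab[lab > 0L])
  cent <- mask_centroids(nuclei)
  dens <- density_features(
    data.frame(x = cent$x * ps, y = cent$y * ps),
    radius_um = cfg$density$radius_um)
  maps <- if (!is.null(epidermis)) {
    tis <- if (is.null(tissue))
      label_mask(matrix(1L, h, w), "tissue-binary", ps) else tissue
    epidermal_depth_maps(epidermis, tis)
  } else NULL

  mr <- max(1L, round(gcfg$margin_um / ps))
  rows <- vector("list", n)
  for (li in seq_len(n)) {
    idx <- idx_by_label[[as.character(li)]]
    ys <- (idx - 1L) %% h
    xs <- (idx - 1L) %/% h
    r0 <- max(0L, min(ys) - mr - 1L); r1 <- min(h - 1L, max(ys) + mr + 1L)
    c0 <- max(0L, min(xs) - mr - 1L); c1 <- min(w - 1L, max(xs) + mr + 1L)
    sub_lab <- lab[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE]
    m <- sub_lab == li
    sub_gray <- gray[(r0 + 1L):(r1 + 1L), (c0 + 1L):(c1 + 1L), drop = FALSE]
    sh <- if (length(idx) >= 4L) shape_features(m, ps) else
      c(area_um2 = length(idx) * ps^2, perimeter_um = NA_real_,
        roundness = NA_real_, aspect_ratio = NA_real_)
    it <- intensity_features(sub_gray, m)
    win <- glcm_window(m, ps, gcfg$margin_um)
    gl <- glcm_features(sub_gray, win, gcfg)
    cx <- cent$x[cent$label == li]; cy <- cent$y[cent$label == li]
    depth <- if (!is.null(maps))
      epidermal_depth(c(cx, cy), epidermis,
                      if (is.null(tissue))
                        label_mask(matrix(1L, h, w), "tissue-binary", ps)
                      else tissue, maps)
    else NA_real_
    rows[[li]] <- data.frame(
      sample_id = sample_id, condition = condition, nucleus_id = li,
      centroid_x_um = cx * ps, centroid_y_um = cy * ps,
      area_um2 = sh[["area_um2"]], perimeter_um = sh[["perimeter_um"]],
      roundness = sh[["roundness"]], aspect_ratio = sh[["aspect_ratio"]],
      intensity_min = it[["min"]], intensity_max = it[["max"]],
      intensity_mean = it[["mean"]], intensity_variance = it[["variance"]],
      glcm_contrast_pct = gl[["contrast_pct"]],
      glcm_energy = gl[["energy"]],
      glcm_entropy_bits = gl[["entropy_bits"]],
      glcm_homogeneity = gl[["homogeneity"]],
      n_neighbors = dens$n_neighbors[li],
      nn_distance_um = dens$nn_distance_um[li],
      epidermal_depth = depth,
      tile_row = core_index(cy, cfg$tile_size_px),
      tile_col = core_index(cx, cfg$tile_size_px))
  }
  records <- do.call(rbind, rows)
  summ <- hcm_summary(records, halo_threshold_pct = gcfg$halo_threshold_pct)
  structure(list(sample_id = sample_id, condition = condition,
                 records = records,
                 hcm_mean_pct = summ[["hcm_mean_pct"]],
                 haloed_fraction_pct = summ[["haloed_fraction_pct"]],
                 n_nuclei = n),
            class = "SampleResult")
}

#' @export
print.SampleResult <- function(x, ...) {
  cat(sprintf(
    "<SampleResult '%s' [%s]: %d nuclei, HCM %.2f%%, haloed %.1f%%>\n",
    x$sample_id, x$condition, x$n_nuclei, x$hcm_mean_pct,
    x$haloed_fraction_pct))
  invisible(x)
}
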