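#' @title Synthetic H&E skin-section generator
#' @description Seeded generator of hematoxylin-eosin-like skin cross-section
#'   images with exact ground truth. The scene emulates the statistical
#'   structure the morphometry pipeline measures: a near-white slide
#'   background above the tissue, a pink eosinophilic tissue block, a
#'   nucleus-dense epidermal band over a sparse dermis, dark purple
#'   elliptical nuclei, and two damage phenotypes -- "haloed" nuclei
#'   (a bright empty perinuclear ring, the morphology scored by the
#'   high-contrast texture feature) and pyknotic nuclei (smaller, darker,
#'   condensed).
#' @name synth_histology
NULL

# Reference stain colors. Optical-density unit vectors for hematoxylin and
# eosin (Ruifrok-Johnston H&E matrix); rendering uses Beer-Lambert
# transmission 255 * 10^(-c * stain_od) so that color deconvolution with the
# same matrix round-trips.
.stain_h <- c(0.650, 0.704, 0.286)
.stain_e <- c(0.072, 0.990, 0.105)
.synth_background <- 250      # slide glass, near-white
.synth_halo_scale <- 0.95     # halo intensity relative to background
.synth_eosin_conc <- 0.25     # tissue (cytoplasm/collagen) eosin density
.synth_hema_conc <- 0.90      # nuclear chromatin hematoxylin density
.pyknotic_radius_scale <- 0.6
.pyknotic_brightness_scale <- 0.5

# run expr with a private RNG stream; global .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic slide
#'
#' Defaults model a small field of a 20x scan at 0.46 um/px: an epidermal
#' band roughly 55 um thick packed with nuclei of ~2.8 um median radius over
#' a sparsely populated dermis.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel size (default 0.46 um/px).
#' @param n_epidermal_nuclei,n_dermal_nuclei nucleus counts per compartment.
#' @param epidermis_top_px,epidermis_bottom_px row interval (0-based,
#'   half-open) of the epidermal band; tissue occupies all rows from
#'   `epidermis_top_px` downward, rows above are slide background.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd equivalent-radius
#'   distribution (normal, truncated below at 1 um).
#' @param halo_fraction probability that a nucleus is rendered with a bright
#'   perinuclear halo.
#' @param halo_width_um width of the halo annulus.
#' @param pyknotic_fraction probability that a nucleus is pyknotic (rendered
#'   at 0.6x radius and 0.5x brightness); assigned independently of the halo.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (8-bit intensity units); the image is clipped to `[0, 255]`.
#' @param rng_seed integer seed; identical specs produce bit-identical
#'   output.
#' @return a validated `SynthSpec` list.
#' @export
synth_spec <- function(width_px = 512L, height_px = 512L,
                       pixel_size_um = 0.46,
                       n_epidermal_nuclei = 80L, n_dermal_nuclei = 10L,
                       epidermis_top_px = round(height_px * 0.15),
                       epidermis_bottom_px = round(height_px * 0.45),
                       nucleus_radius_um_mean = 2.8,
                       nucleus_radius_um_sd = 0.4,
                       halo_fraction = 0, halo_width_um = 1.5,
                       pyknotic_fraction = 0, noise_sd = 0,
                       rng_seed = 1L) {
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               pixel_size_um = pixel_size_um,
               n_epidermal_nuclei = as.integer(n_epidermal_nuclei),
               n_dermal_nuclei = as.integer(n_dermal_nuclei),
               epidermis_top_px = as.integer(epidermis_top_px),
               epidermis_bottom_px = as.integer(epidermis_bottom_px),
               nucleus_radius_um_mean = nucleus_radius_um_mean,
               nucleus_radius_um_sd = nucleus_radius_um_sd,
               halo_fraction = halo_fraction,
               halo_width_um = halo_width_um,
               pyknotic_fraction = pyknotic_fraction,
               noise_sd = noise_sd,
               rng_seed = as.integer(rng_seed))
  validate_synth_spec(spec)
  class(spec) <- "SynthSpec"
  spec
}

validate_synth_spec <- function(s) {
  stopifnot(s$width_px >= 64L, s$height_px >= 64L, s$pixel_size_um > 0,
            s$n_epidermal_nuclei >= 0L, s$n_dermal_nuclei >= 0L,
            s$nucleus_radius_um_mean > 0, s$nucleus_radius_um_sd >= 0,
            s$halo_width_um > 0, s$noise_sd >= 0)
  if (!(s$epidermis_top_px >= 0L &&
        s$epidermis_top_px < s$epidermis_bottom_px &&
        s$epidermis_bottom_px <= s$height_px))
    stop("epidermis band must satisfy 0 <= top < bottom <= height")
  if (s$halo_fraction < 0 || s$halo_fraction > 1 ||
      s$pyknotic_fraction < 0 || s$pyknotic_fraction > 1)
    stop("phenotype fractions must lie in [0, 1]")
  invisible(s)
}

# Beer-Lambert rendering of a stain mixture to an RGB triplet (0..255)
stain_rgb <- function(h_conc = 0, e_conc = 0, scale = 1) {
  od <- h_conc * .stain_h + e_conc * .stain_e
  pmin(255, pmax(0, 255 * 10^(-od) * scale))
}

# rejection-sample non-overlapping nucleus centres inside a row band.
# Returns a data.frame or NULL on failure; `clear` is the per-nucleus
# clearance radius in px (semi-major axis + halo, if any).
place_nuclei <- function(n, row_lo, row_hi, width, clear, max_attempts) {
  if (n == 0L)
    return(data.frame(cx = numeric(), cy = numeric()))
  cx <- numeric(n); cy <- numeric(n)
  placed <- 0L
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    i <- placed + 1L
    x <- runif(1, clear[i], width - 1 - clear[i])
    y <- runif(1, row_lo + clear[i], row_hi - 1 - clear[i])
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (cx[seq_len(placed)] - x)^2 + (cy[seq_len(placed)] - y)^2
      min_gap <- (clear[seq_len(placed)] + clear[i] + 1)^2
      ok <- all(d2 > min_gap)
    }
    if (ok) {
      cx[i] <- x; cy[i] <- y
      placed <- placed + 1L
    }
  }
  if (placed < n)
    return(structure(list(placed = placed), class = "placement_failure"))
  data.frame(cx = cx, cy = cy)
}

#' Generate a synthetic slide with ground truth
#'
#' @param spec a [synth_spec()].
#' @return a list with elements `image` (a `SlideImage`) and `truth`, the
#'   ground truth: `nucleus_labels` (instance `LabelMask`), `epidermis_mask`
#'   and `tissue_mask` (binary `LabelMask`s), and `truth_table`, a data.frame
#'   with one row per nucleus (`label`, `centroid_x_px`, `centroid_y_px`,
#'   `radius_um`, `is_haloed`, `is_pyknotic`, `in_epidermis`).
#' @export
generate_slide <- function(spec) {
  validate_synth_spec(spec)
  with_local_seed(spec$rng_seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  h <- spec$height_px; w <- spec$width_px; ps <- spec$pixel_size_um
  n_epi <- spec$n_epidermal_nuclei; n_der <- spec$n_dermal_nuclei
  n <- n_epi + n_der

  # phenotypes and geometry drawn before placement so clearance radii are known
  is_haloed <- runif(n) < spec$halo_fraction
  is_pyknotic <- runif(n) < spec$pyknotic_fraction
  r_um <- pmax(1.0, rnorm(n, spec$nucleus_radius_um_mean,
                          spec$nucleus_radius_um_sd))
  r_um[is_pyknotic] <- r_um[is_pyknotic] * .pyknotic_radius_scale
  aspect <- runif(n, 1, 1.6)
  theta <- runif(n, 0, pi)
  a_px <- r_um * sqrt(aspect) / ps   # semi-major
  b_px <- r_um / sqrt(aspect) / ps   # semi-minor
  halo_px <- ifelse(is_haloed, spec$halo_width_um / ps, 0)
  clear <- a_px + halo_px

  in_epi <- rep(c(TRUE, FALSE), c(n_epi, n_der))
  pos <- data.frame(cx = numeric(n), cy = numeric(n))
  for (compartment in list(
    list(sel = in_epi, lo = spec$epidermis_top_px,
         hi = spec$epidermis_bottom_px, n = n_epi),
    list(sel = !in_epi, lo = spec$epidermis_bottom_px, hi = h, n = n_der))) {
    if (compartment$n == 0L) next
    res <- place_nuclei(compartment$n, compartment$lo, compartment$hi, w,
                        clear[compartment$sel],
                        max_attempts = 400L * compartment$n)
    if (inherits(res, "placement_failure"))
      stop(sprintf(paste0("nucleus placement infeasible: requested %d ",
                          "nuclei in rows [%d, %d) but only %d could be ",
                          "placed without overlap"),
                   compartment$n, compartment$lo, compartment$hi,
                   res$placed))
    pos[compartment$sel, ] <- res
  }

  # compartment masks
  tissue <- matrix(0L, h, w)
  tissue[(spec$epidermis_top_px + 1L):h, ] <- 1L
  epidermis <- matrix(0L, h, w)
  epidermis[(spec$epidermis_top_px + 1L):spec$epidermis_bottom_px, ] <- 1L

  # base rendering: background above the tissue, eosin-pink tissue below
  bg <- rep(.synth_background, 3)
  pink <- stain_rgb(e_conc = .synth_eosin_conc)
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    plane <- matrix(bg[k], h, w)
    plane[tissue == 1L] <- pink[k]
    img[, , k] <- plane
  }

  labels <- matrix(0L, h, w)
  halo_rgb <- rep(.synth_background * .synth_halo_scale, 3)
  nuc_plain <- stain_rgb(h_conc = .synth_hema_conc)
  nuc_pyk <- nuc_plain * .pyknotic_brightness_scale

  paint <- function(i) {
    a <- a_px[i]; b <- b_px[i]
    ao <- a + halo_px[i]; bo <- b + halo_px[i]
    cx <- pos$cx[i]; cy <- pos$cy[i]
    ext <- ceiling(ao) + 1L
    c0 <- max(0L, floor(cx) - ext); c1 <- min(w - 1L, ceiling(cx) + ext)
    r0 <- max(0L, floor(cy) - ext); r1 <- min(h - 1L, ceiling(cy) + ext)
    cols <- c0:c1; rows <- r0:r1
    u <- outer(rows - cy, cols - cx, function(yy, xx) xx)
    v <- outer(rows - cy, cols - cx, function(yy, xx) yy)
    ur <- u * cos(theta[i]) + v * sin(theta[i])
    vr <- -u * sin(theta[i]) + v * cos(theta[i])
    inner <- (ur / a)^2 + (vr / b)^2 <= 1
    color <- if (is_pyknotic[i]) nuc_pyk else nuc_plain
    ri <- rows + 1L; ci <- cols + 1L
    if (is_haloed[i]) {
      outer_e <- (ur / ao)^2 + (vr / bo)^2 <= 1
      ring <- outer_e & !inner
      for (k in 1:3) {
        plane <- img[ri, ci, k]
        plane[ring] <- halo_rgb[k]
        img[ri, ci, k] <<- plane
      }
    }
    for (k in 1:3) {
      plane <- img[ri, ci, k]
      plane[inner] <- color[k]
      img[ri, ci, k] <<- plane
    }
    lb <- labels[ri, ci]
    lb[inner] <- i
    labels[ri, ci] <<- lb
  }
  for (i in seq_len(n)) paint(i)

  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  cent <- mask_centroids(label_mask(labels, "nuclei-instances", ps))
  tt_row <- pmin(h - 1L, pmax(0L, floor(cent$y + 0.5)))
  truth_table <- data.frame(
    label = cent$label,
    centroid_x_px = cent$x, centroid_y_px = cent$y,
    radius_um = r_um[cent$label],
    is_haloed = is_haloed[cent$label],
    is_pyknotic = is_pyknotic[cent$label],
    in_epidermis = epidermis[cbind(tt_row + 1L,
                                   pmin(w - 1L, pmax(0L, floor(cent$x + 0.5))) + 1L)] == 1L)

  list(image = slide_image(img, ps, "<synthetic>"),
       truth = list(
         nucleus_labels = label_mask(labels, "nuclei-instances", ps),
         epidermis_mask = label_mask(epidermis, "epidermis-binary", ps),
         tissue_mask = label_mask(tissue, "tissue-binary", ps),
         truth_table = truth_table))
}

#' Generate a multi-condition synthetic cohort
#'
#' Emulates a treatment/control explant experiment: each condition gets its
#' own halo fraction (the damage level) and a number of replicate slides.
#' Replicate seeds are derived deterministically from the base seed and the
#' condition/replicate indices, so cohorts are reproducible and independent
#' of processing order.
#'
#' @param base_spec a [synth_spec()] supplying everything but the halo
#'   fraction and seed.
#' @param conditions a data.frame with columns `name`, `halo_fraction`,
#'   `n_replicates` (or a list of such triplets).
#' @return a list of samples; each sample is a list with `image`, `truth`,
#'   `condition`, `replicate`, `sample_id`.
#' @export
generate_cohort <- function(base_spec, conditions) {
  if (is.list(conditions) && !is.data.frame(conditions))
    conditions <- do.call(rbind, lapply(conditions, function(x)
      data.frame(name = x[[1]], halo_fraction = as.numeric(x[[2]]),
                 n_replicates = as.integer(x[[3]]))))
  if (nrow(conditions) == 0L) return(list())
  if (anyDuplicated(conditions$name))
    stop("duplicate condition names: ",
         paste(unique(conditions$name[duplicated(conditions$name)]),
               collapse = ", "))
  out <- list()
  for (ci in seq_len(nrow(conditions))) {
    for (ri in seq_len(conditions$n_replicates[ci])) {
      seed <- as.integer((as.numeric(base_spec$rng_seed) +
                          15485863 * ci + 32452843 * ri) %% 2147483646) + 1L
      spec <- base_spec
      spec$halo_fraction <- conditions$halo_fraction[ci]
      spec$rng_seed <- seed
      s <- generate_slide(spec)
      s$condition <- as.character(conditions$name[ci])
      s$replicate <- ri
      s$sample_id <- sprintf("%s_rep%d", s$condition, ri)
      out[[length(out) + 1L]] <- s
    }
  }
  out
}
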