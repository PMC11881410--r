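# Independent oracles used across tests. These deliberately use naive
# enumeration / closed forms, not the package's vectorized code paths.

# brute-force GLCM features: double loop over every pixel and offset,
# symmetric accumulation, per-offset normalization, averaged over offsets
glcm_oracle <- function(gray, window, G,
                        offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  q <- floor(gray * G / 256)
  q[q > G - 1] <- G - 1
  win <- window > 0
  h <- nrow(q); w <- ncol(q)
  per_offset <- list()
  for (off in offsets) {
    M <- matrix(0, G, G)
    np <- 0
    for (r in 1:h) for (c in 1:w) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (!win[r, c] || !win[r2, c2]) next
      i <- q[r, c] + 1; j <- q[r2, c2] + 1
      M[i, j] <- M[i, j] + 1
      M[j, i] <- M[j, i] + 1
      np <- np + 1
    }
    if (np == 0) next
    P <- M / sum(M)
    ii <- row(P) - 1; jj <- col(P) - 1
    pos <- P > 0
    per_offset[[length(per_offset) + 1]] <- c(
      contrast = sum((ii - jj)^2 * P),
      energy = sum(P^2),
      entropy_bits = -sum(P[pos] * log2(P[pos])),
      homogeneity = sum(P / (1 + abs(ii - jj))))
  }
  f <- colMeans(do.call(rbind, per_offset))
  c(contrast_pct = 100 * f[["contrast"]] / (G - 1)^2,
    energy = f[["energy"]], entropy_bits = f[["entropy_bits"]],
    homogeneity = f[["homogeneity"]])
}

# instance-matching at an IoU threshold; returns c(matched, n_pred, n_truth)
iou_match_counts <- function(pred, truth, iou = 0.5) {
  pl <- pred$labels; tl <- truth$labels
  n_pred <- max(pl); n_truth <- max(tl)
  both <- pl > 0 & tl > 0
  matched <- 0
  if (any(both)) {
    pairs <- table(pl[both], tl[both])
    pa <- tabulate(pl[pl > 0], n_pred)
    ta <- tabulate(tl[tl > 0], n_truth)
    for (i in rownames(pairs)) for (j in colnames(pairs)) {
      inter <- pairs[i, j]
      if (inter == 0) next
      u <- pa[as.integer(i)] + ta[as.integer(j)] - inter
      if (inter / u >= iou) matched <- matched + 1
    }
  }
  c(matched = matched, n_pred = n_pred, n_truth = n_truth)
}

# largest nearest-neighbour distance between two centroid sets (both ways)
centroid_set_distance <- function(a, b) {
  one_way <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i)
      min(sqrt((q$x - p$x[i])^2 + (q$y - p$y[i])^2)), 0))
  }
  max(one_way(a, b), one_way(b, a))
}

dice_coef <- function(a, b) {
  2 * sum(a$labels & b$labels) / (sum(a$labels) + sum(b$labels))
}

# rasterized disc mask (logical), 1-based centre
disc_mask <- function(n, cx, cy, r) {
  xs <- matrix(rep(1:n, each = n), n)
  ys <- matrix(rep(1:n, n), n)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# small synthetic scene shared by several tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(width_px = 384, height_px = 384,
         n_epidermal_nuclei = 40, n_dermal_nuclei = 8,
         epidermis_top_px = 60, epidermis_bottom_px = 180,
         rng_seed = 1L),
    list(...))
  do.call(synth_spec, args)
}
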