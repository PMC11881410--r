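#' @title Sample summaries and two-group statistics
#' @description The statistics toolbox used to compare treated and control
#'   samples: per-sample HCM summaries, two-group t-tests (Welch, Student,
#'   paired) with the strictly standardized mean difference (SSMD) effect
#'   size, Benjamini-Hochberg adjustment, principal components and Fisher
#'   linear discriminant analysis of descriptor tables.
#' @name group_stats
NULL

#' Sample-level high-contrast summaries
#'
#' @param records nucleus records (data.frame with `glcm_contrast_pct`).
#' @param halo_threshold_pct contrast percentage above which (strictly) a
#'   nucleus counts as haloed.
#' @return named vector `hcm_mean_pct` (mean per-nucleus contrast
#'   percentage over records with defined texture) and `haloed_fraction_pct`
#'   (percentage of defined records exceeding the threshold); both `NA`
#'   when no record has defined texture.
#' @export
hcm_summary <- function(records, halo_threshold_pct = 4) {
  v <- records$glcm_contrast_pct
  v <- v[!is.na(v)]
  if (length(v) == 0L)
    return(c(hcm_mean_pct = NA_real_, haloed_fraction_pct = NA_real_))
  c(hcm_mean_pct = mean(v),
    haloed_fraction_pct = 100 * mean(v > halo_threshold_pct))
}

#' Two-group comparison of one descriptor
#'
#' Welch (default), Student or paired two-sided t-test plus SSMD. SSMD is
#' `(mean_a - mean_b) / sqrt(var_a + var_b)` with sample variances; in
#' paired mode it is `mean(d) / sd(d)` on the paired differences. With zero
#' variance in both groups, equal means give `t = 0, p = 1`; unequal means
#' give an underflowed p reported as `1e-300`.
#'
#' @param descriptor name of the descriptor being compared (metadata).
#' @param a,b numeric value vectors for the two groups (`a` first, e.g.
#'   treated; `b` second, e.g. control).
#' @param mode `"welch"`, `"student"` or `"paired"`.
#' @return a `GroupComparison`: one-row data.frame with `descriptor`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `var_a`, `var_b`, `mean_difference`,
#'   `t_statistic`, `degrees_of_freedom`, `p_value`, `ssmd`.
#' @export
compare_groups <- function(descriptor, a, b,
                           mode = c("welch", "student", "paired")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (mode == "paired" && length(a) != length(b))
    stop("paired mode requires equal group lengths")
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 values per group")
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  ssmd <- if (mode == "paired") {
    d <- a - b
    if (stats::sd(d) == 0) ifelse(mean(d) == 0, 0, sign(mean(d)) * Inf)
    else mean(d) / stats::sd(d)
  } else {
    if (va + vb == 0) ifelse(ma == mb, 0, sign(ma - mb) * Inf)
    else (ma - mb) / sqrt(va + vb)
  }
  degenerate <- if (mode == "paired") stats::sd(a - b) == 0 else va + vb == 0
  if (degenerate) {
    same <- if (mode == "paired") mean(a - b) == 0 else ma == mb
    t_stat <- if (same) 0 else sign(ma - mb) * Inf
    df <- length(a) + length(b) - 2
    p <- if (same) 1 else 1e-300
  } else {
    tt <- stats::t.test(a, b, paired = (mode == "paired"),
                        var.equal = (mode == "student"))
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
    if (p < 1e-300) p <- 1e-300
  }
  structure(data.frame(
    descriptor = descriptor, n_a = length(a), n_b = length(b),
    mean_a = ma, mean_b = mb, var_a = va, var_b = vb,
    mean_difference = ma - mb, t_statistic = t_stat,
    degrees_of_freedom = df, p_value = p, ssmd = ssmd),
    class = c("GroupComparison", "data.frame"))
}

#' Compare every descriptor of two samples' nucleus tables
#'
#' @param records_a,records_b nucleus record data.frames (pooled
#'   nucleus-level values, or replicate-level summary tables).
#' @param mode test mode, see [compare_groups()].
#' @param descriptors which numeric columns to compare (default: all
#'   numeric descriptor columns present in both).
#' @param adjust apply Benjamini-Hochberg adjustment across descriptors.
#' @return data.frame of [compare_groups()] rows plus `p_adjusted`.
#' @export
compare_descriptors <- function(records_a, records_b,
                                mode = "welch",
                                descriptors = NULL, adjust = TRUE) {
  num <- c("area_um2", "perimeter_um", "roundness", "aspect_ratio",
           "intensity_min", "intensity_max", "intensity_mean",
           "intensity_variance", "glcm_contrast_pct", "glcm_energy",
           "glcm_entropy_bits", "glcm_homogeneity", "n_neighbors",
           "nn_distance_um", "epidermal_depth")
  if (is.null(descriptors))
    descriptors <- intersect(num, intersect(names(records_a),
                                            names(records_b)))
  out <- do.call(rbind, lapply(descriptors, function(d)
    compare_groups(d, records_a[[d]], records_b[[d]], mode = mode)))
  out$p_adjusted <- if (adjust) adjust_pvalues(out$p_value) else out$p_value
  out
}

#' Benjamini-Hochberg adjustment
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values (step-up FDR).
#' @export
adjust_pvalues <- function(p) {
  if (!all(p >= 0 & p <= 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Principal component scores of a descriptor table
#'
#' Columns are standardized to zero mean and unit variance (zero-variance
#' columns dropped with a warning) and decomposed by SVD. Component signs
#' are fixed so each loading vector's largest-magnitude entry is positive.
#'
#' @param table numeric matrix/data.frame (rows = samples or nuclei).
#' @return list `scores`, `loadings`, `explained` (variance fractions
#'   summing to 1), `dropped` (names of dropped columns).
#' @export
pca_scores <- function(table) {
  x <- as.matrix(table)
  stopifnot(nrow(x) >= 2L)
  sds <- apply(x, 2, stats::sd)
  drop <- which(sds == 0 | is.na(sds))
  if (length(drop)) {
    nm <- colnames(x)[drop]
    nm[is.na(nm) | nm == ""] <- paste0("#", drop[is.na(nm) | nm == ""])
    warning("dropping zero-variance column(s): ", paste(nm, collapse = ", "))
    x <- x[, -drop, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("need at least 2 usable columns")
  xs <- scale(x)
  sv <- svd(xs)
  k <- length(sv$d)
  loadings <- sv$v
  scores <- xs %*% loadings
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       explained = sv$d^2 / sum(sv$d^2),
       dropped = if (length(drop)) colnames(as.matrix(table))[drop]
                 else character())
}

#' Fisher linear discriminant axis for two classes
#'
#' `w` proportional to `Sw^-1 (mu1 - mu2)` with the pooled within-class
#' covariance regularized by `+1e-6 I`, normalized to unit length and
#' oriented so class 1 projects higher.
#'
#' @param table numeric matrix/data.frame of descriptors.
#' @param labels binary class labels (factor/logical/two unique values);
#'   class 1 is the first level.
#' @return list `w` (unit weight vector), `means` (projected class means,
#'   class 1 first).
#' @export
lda_axis <- function(table, labels) {
  x <- as.matrix(table)
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes")
  x1 <- x[f == levels(f)[1], , drop = FALSE]
  x2 <- x[f == levels(f)[2], , drop = FALSE]
  if (nrow(x1) < 2L || nrow(x2) < 2L)
    stop("each class needs at least 2 rows")
  s1 <- stats::cov(x1); s2 <- stats::cov(x2)
  sw <- ((nrow(x1) - 1) * s1 + (nrow(x2) - 1) * s2) /
    (nrow(x1) + nrow(x2) - 2) + 1e-6 * diag(ncol(x))
  w <- tryCatch(solve(sw, colMeans(x1) - colMeans(x2)),
                error = function(e)
                  stop("within-class covariance is singular even after ",
                       "regularization"))
  w <- w / sqrt(sum(w^2))
  m1 <- sum(colMeans(x1) * w); m2 <- sum(colMeans(x2) * w)
  if (m1 < m2) { w <- -w; m1 <- -m1; m2 <- -m2 }
  names(w) <- colnames(x)
  list(w = w, means = c(class1 = m1, class2 = m2))
}
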