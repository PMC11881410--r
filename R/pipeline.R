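#' @title End-to-end runs and batch processing
#' @description Orchestrates segment -> filter -> features -> summaries for
#'   one slide or a whole project directory, writing masks, the per-nucleus
#'   CSV, a sample summary and a run manifest. All stages are deterministic
#'   given the configuration, so reruns are byte-identical.
#' @name cli_pipeline
NULL

log_stage <- function(sample, stage, t0, detail = "") {
  message(sprintf("[%s] %-12s %6.2fs %s", sample, stage,
                  as.numeric(Sys.time()) - t0, detail))
}

# crop a SlideImage to the preview window (x, y, w, h; 0-based pixels)
crop_preview <- function(image, preview) {
  if (is.null(preview)) return(image)
  p <- preview
  h <- dim(image$pixels)[1]; w <- dim(image$pixels)[2]
  r0 <- max(0L, p$y); c0 <- max(0L, p$x)
  r1 <- min(h, p$y + p$h); c1 <- min(w, p$x + p$w)
  slide_image(image$pixels[(r0 + 1L):r1, (c0 + 1L):c1, , drop = FALSE],
              image$pixel_size_um,
              paste0(image$source_path, "#preview"))
}

#' Process one sample end to end
#'
#' Runs tissue detection, (tiled) nucleus segmentation, epidermis
#' segmentation, the epidermal/size filter and descriptor computation, and
#' writes `<sample>_nuclei.tiff`, `<sample>_epidermis.png`,
#' `<sample>_tissue.png`, `<sample>.csv` and `<sample>_summary.json` into
#' the configured output directory. With the `external` backend the nucleus
#' and epidermis masks are imported from `<sample>_nuclei.tiff` /
#' `<sample>_epidermis.png` next to the image instead of being computed.
#'
#' @param image a `SlideImage` or a path readable by [read_slide()].
#' @param cfg run configuration ([default_config()]).
#' @param sample_id,condition sample metadata.
#' @param write write output files (set `FALSE` for in-memory use).
#' @return the `SampleResult` (invisibly gains `files`, the written paths).
#' @export
run_sample <- function(image, cfg = default_config(),
                       sample_id = "sample", condition = "",
                       write = TRUE) {
  t0 <- as.numeric(Sys.time())
  image_path <- NULL
  if (is.character(image)) {
    image_path <- image
    image <- read_slide(image, cfg$pixel_size_um)
  }
  image <- crop_preview(image, cfg$preview)
  ps <- image$pixel_size_um
  log_stage(sample_id, "load", t0,
            sprintf("%d x %d px", dim(image$pixels)[1], dim(image$pixels)[2]))

  external <- identical(cfg$segmentation$backend, "external")
  tissue <- detect_tissue_roi(image)
  log_stage(sample_id, "tissue", t0, sprintf("%d px", sum(tissue$labels)))

  if (external) {
    if (is.null(image_path))
      stop("external backend needs a file-based sample to locate masks")
    base <- tools::file_path_sans_ext(image_path)
    nuclei <- load_mask(paste0(base, "_nuclei.tiff"),
                        "nuclei-instances", ps)
    epidermis <- load_mask(paste0(base, "_epidermis.png"),
                           "epidermis-binary", ps)
  } else {
    nuclei <- run_tiled(image, cfg, backend = cfg$segmentation$backend)
    epidermis <- segment_epidermis(image, nuclei, tissue, cfg)
  }
  log_stage(sample_id, "segment", t0,
            sprintf("%d instances", n_instances(nuclei)))

  nuclei <- filter_nuclei(nuclei, epidermis, cfg)
  log_stage(sample_id, "filter", t0,
            sprintf("%d kept", n_instances(nuclei)))

  res <- build_records(image, nuclei, epidermis, cfg,
                       sample_id = sample_id, condition = condition,
                       tissue = tissue)
  log_stage(sample_id, "features", t0, sprintf("%d records", res$n_nuclei))

  if (write) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(suffix) file.path(cfg$output_dir,
                                     paste0(sample_id, suffix))
    write_mask(nuclei, fp("_nuclei.tiff"))
    write_mask(epidermis, fp("_epidermis.png"))
    write_mask(tissue, fp("_tissue.png"))
    write_nucleus_csv(res, fp(".csv"))
    summary_rec <- list(sample_id = sample_id, condition = condition,
                        n_nuclei = res$n_nuclei,
                        hcm_mean_pct = res$hcm_mean_pct,
                        haloed_fraction_pct = res$haloed_fraction_pct)
    jsonlite::write_json(summary_rec, fp("_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$files <- c(fp("_nuclei.tiff"), fp("_epidermis.png"),
                   fp("_tissue.png"), fp(".csv"), fp("_summary.json"))
  }
  res
}

#' Batch-process a project directory
#'
#' The project directory holds slide images plus a `metadata.csv` with
#' columns `file`, `sample_id`, `condition`. Each listed image is processed
#' with [run_sample()]; failures are recorded in the manifest and the batch
#' continues. Images without a metadata row are skipped with a warning.
#'
#' @param project_dir directory with images and `metadata.csv`.
#' @param cfg run configuration; `output_dir` receives all outputs plus
#'   `manifest.json` and the per-condition `conditions.csv` aggregate.
#' @return the run manifest (list), invisibly written to JSON.
#' @export
run_batch <- function(project_dir, cfg = default_config()) {
  meta_path <- file.path(project_dir, "metadata.csv")
  if (!file.exists(meta_path)) stop("no metadata.csv in ", project_dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  stopifnot(all(c("file", "sample_id", "condition") %in% names(meta)))
  imgs <- list.files(project_dir, pattern = "\\.(tif|tiff|png)$",
                     ignore.case = TRUE)
  imgs <- imgs[!grepl("_(nuclei|epidermis|tissue)\\.", imgs)]
  unlisted <- setdiff(imgs, meta$file)
  if (length(unlisted))
    warning("image(s) without metadata row skipped: ",
            paste(unlisted, collapse = ", "))

  manifest <- list(
    config = cfg,
    rng_seed = cfg$rng_seed,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(tools::md5sum(
      file.path(project_dir, intersect(meta$file, imgs)))),
    samples = list())
  results <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    path <- file.path(project_dir, meta$file[i])
    t0 <- Sys.time()
    status <- tryCatch({
      res <- run_sample(path, cfg, sample_id = sid,
                        condition = meta$condition[i])
      results[[sid]] <- res
      list(status = "ok", n_nuclei = res$n_nuclei,
           hcm_mean_pct = res$hcm_mean_pct)
    }, error = function(e) {
      warning(sprintf("sample %s failed: %s", sid, conditionMessage(e)))
      list(status = "failed", error = conditionMessage(e))
    })
    status$seconds <- round(as.numeric(Sys.time()) - as.numeric(t0), 2)
    manifest$samples[[sid]] <- status
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(results)) {
    agg <- do.call(rbind, lapply(results, function(r)
      data.frame(sample_id = r$sample_id, condition = r$condition,
                 n_nuclei = r$n_nuclei, hcm_mean_pct = r$hcm_mean_pct,
                 haloed_fraction_pct = r$haloed_fraction_pct)))
    cond <- do.call(rbind, lapply(split(agg, agg$condition), function(g)
      data.frame(condition = g$condition[1], n_samples = nrow(g),
                 n_nuclei = sum(g$n_nuclei),
                 hcm_mean_pct = mean(g$hcm_mean_pct),
                 haloed_fraction_pct = mean(g$haloed_fraction_pct))))
    utils::write.csv(agg, file.path(cfg$output_dir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(cond, file.path(cfg$output_dir, "conditions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(manifest)
}

#' Write a synthetic sample to disk in the project layout
#'
#' Convenience wrapper for building fixture projects and CLI `synth` runs:
#' writes `image.tiff`, `nuclei.tiff` (16-bit labels), `epidermis.png`,
#' `tissue.png` and `truth.csv` for one generated slide.
#'
#' @param sample one element of [generate_cohort()] output (or
#'   [generate_slide()] output plus a `sample_id`).
#' @param out_dir output directory.
#' @param basename file prefix (default the sample id, or "image").
#' @return invisibly, the written paths.
#' @export
write_synth_sample <- function(sample, out_dir,
                               basename = sample$sample_id %||% "image") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(suffix) file.path(out_dir, paste0(basename, suffix))
  write_slide(sample$image, fp(".tiff"))
  write_mask(sample$truth$nucleus_labels, fp("_nuclei.tiff"))
  write_mask(sample$truth$epidermis_mask, fp("_epidermis.png"))
  write_mask(sample$truth$tissue_mask, fp("_tissue.png"))
  utils::write.csv(sample$truth$truth_table, fp("_truth.csv"),
                   row.names = FALSE)
  invisible(c(fp(".tiff"), fp("_nuclei.tiff"), fp("_epidermis.png"),
              fp("_tissue.png"), fp("_truth.csv")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
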