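# End-to-end driver: segment -> patch -> classify -> activity -> stats
# (optionally sensors -> forecast) over an on-disk campaign directory, with
# every stage's outputs, the resolved configuration and all seeds written
# to the run directory.

#' Pipeline configuration
#'
#' One object holding every tunable of the image pipeline. All values
#' round-trip through YAML ([writePipelineConfig()] /
#' [readPipelineConfig()]).
#'
#' @param input_dir campaign directory (images/, masks/, manifest.csv, ...).
#' @param output_dir run directory for all artifacts.
#' @param seed master seed (split, networks).
#' @param apply_gamma,gamma gamma-correction preprocessing toggle and value.
#' @param patch_size,p_min patch side length and eligibility threshold.
#' @param blue_threshold region-size threshold (pixels) for the
#'   distant-colony visibility filter; `NULL` derives it from the data.
#' @param split_fractions train/val/test image fractions.
#' @param cutoff image timestamp cutoff (default 7 April 2019).
#' @param seg,clf overrides for [segConfig()] / [clfConfig()] entries.
#' @param forecast `NULL` to skip forecasting, or a list of
#'   [ForecastConfig()] arguments.
#' @param sigma,peak_threshold,min_days smoothing and low-activity
#'   detection parameters.
#' @return config list.
#' @export
pipelineConfig <- function(input_dir, output_dir, seed = 1L,
                           apply_gamma = TRUE, gamma = 0.3,
                           patch_size = 128L, p_min = 0.1,
                           blue_threshold = NULL,
                           split_fractions = c(0.6, 0.2, 0.2),
                           cutoff = "2019-04-07 00:00:00",
                           seg = list(), clf = list(), forecast = NULL,
                           sigma = 10, peak_threshold = 0.1, min_days = 5) {
  if (p_min < 0 || p_min > 1) stop("p_min must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  list(input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
       apply_gamma = apply_gamma, gamma = gamma,
       patch_size = as.integer(patch_size), p_min = p_min,
       blue_threshold = blue_threshold, split_fractions = split_fractions,
       cutoff = cutoff, seg = seg, clf = clf, forecast = forecast,
       sigma = sigma, peak_threshold = peak_threshold, min_days = min_days)
}

#' @rdname pipelineConfig
#' @param config a pipeline configuration list.
#' @param path YAML file.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

.load_campaign_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("missing manifest: ", man_path)
  manifest <- readImageManifest(man_path)
  states_path <- file.path(dir, "states.csv")
  states <- if (file.exists(states_path))
    read.csv(states_path, stringsAsFactors = FALSE) else NULL
  scenes <- lapply(seq_len(nrow(manifest)), function(i) {
    px <- readImageArray(file.path(dir, manifest$path[i]))
    img <- ImageRecord(manifest$image_id[i], manifest$timestamp[i], px,
                       manifest$sensor[i], manifest$angle[i])
    mp <- file.path(dir, "masks", paste0(manifest$image_id[i], ".png"))
    mask <- if (file.exists(mp)) readMaskPNG(mp) else NULL
    st <- if (!is.null(states))
      states[states$image_id == manifest$image_id[i],
             c("coral", "cell_x", "cell_y", "extended"), drop = FALSE]
    else NULL
    list(image = img, mask = mask, states = st)
  })
  list(manifest = manifest, scenes = scenes)
}

#' Run the full image pipeline over a campaign directory
#'
#' Loads the campaign, splits images (per-image, seeded), trains the
#' segmenter and the per-coral classifiers on the train/validation splits,
#' then runs segmentation, patch extraction (predicted masks), patch
#' classification, per-image and hourly activity computation (with the
#' distant-colony visibility filter), the MAE-with-penalty evaluation
#' against the ground-truth path, and the correlation/smoothing/low-
#' activity statistics. All tables are written as CSV under the output
#' directory together with the resolved configuration and a stage log.
#' Reruns with identical configuration and seeds reproduce identical
#' outputs.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the key metrics and output paths.
#' @export
runPipeline <- function(config) {
  cfg <- config
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run_log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                               "\n", file = logf, append = TRUE)
  stage <- function(name, expr) {
    logline("stage", name, "start")
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logline("stage", name, "done")
    r
  }
  writePipelineConfig(cfg, file.path(out, "config_resolved.yaml"))

  camp <- stage("load", .load_campaign_dir(cfg$input_dir))
  scenes <- camp$scenes
  ids <- vapply(scenes, function(s) s$image@image_id, "")
  split <- seededSplit(ids, cfg$split_fractions, cfg$seed)
  logline("split:", length(split$train), "train,", length(split$val),
          "val,", length(split$test), "test")

  seg_cfg <- do.call(segConfig, modifyList(
    list(apply_gamma = cfg$apply_gamma, gamma = cfg$gamma, seed = cfg$seed),
    cfg$seg))
  seg <- stage("train-seg", trainSegmenter(
    scenes[ids %in% split$train], scenes[ids %in% split$val], seg_cfg))

  masks_hat <- stage("segment", lapply(scenes, function(s)
    applySegmenter(seg, s$image)))

  test_idx <- which(ids %in% split$test)
  seg_metrics <- data.frame(
    image_id = ids[test_idx],
    macro_jaccard = vapply(test_idx, function(i)
      macroJaccard(masks_hat[[i]], scenes[[i]]$mask), 0),
    jaccard_red = vapply(test_idx, function(i)
      jaccard(masks_hat[[i]], scenes[[i]]$mask, 1L), 0),
    jaccard_blue = vapply(test_idx, function(i)
      jaccard(masks_hat[[i]], scenes[[i]]$mask, 2L), 0))
  write.csv(seg_metrics, file.path(out, "segmentation_metrics.csv"),
            row.names = FALSE)

  clf_cfg <- do.call(clfConfig, modifyList(
    list(apply_gamma = cfg$apply_gamma, gamma = cfg$gamma, seed = cfg$seed),
    cfg$clf))
  images <- lapply(scenes, `[[`, "image")
  rs_blue <- regionSizeSeries(images, masks_hat, 2L)
  visible_ids <- ids[vapply(scenes, function(s) any(s$mask@labels == 2L), NA)]
  blue_thr <- cfg$blue_threshold
  if (is.null(blue_thr))
    blue_thr <- if (length(visible_ids))
      blueVisibilityThreshold(rs_blue, visible_ids) else 0
  kept_blue <- blueVisibilityFilter(rs_blue, blue_thr)
  logline("blue visibility filter: threshold", round(blue_thr, 1), "px;",
          nrow(rs_blue) - length(kept_blue), "image(s) filtered")

  results <- list(seg_model = seg, split = split, blue_threshold = blue_thr,
                  test_macro_jaccard = mean(seg_metrics$macro_jaccard))
  all_series <- list()
  for (coral in .CORALS) {
    ds <- stage(paste0("make-patches-", coral), buildPatchDatasets(
      scenes, split, coral, cfg$patch_size, cfg$p_min))
    if (!nrow(ds$train@info)) { logline("no ", coral, " patches; skipped"); next }
    clf <- stage(paste0("train-clf-", coral), trainClassifier(
      ds$train, ds$val, clf_cfg, coral = coral))

    per_image <- list(); truth_image <- list()
    use_ids <- if (coral == "C_b") kept_blue else ids
    for (i in seq_along(scenes)) {
      s <- scenes[[i]]
      if (s$image@image_id %in% use_ids) {
        ph <- extractPatches(s$image, masks_hat[[i]], coral, cfg$patch_size,
                             cfg$p_min)
        ph <- if (nrow(ph@info)) classifyPatches(clf, ph, cfg$p_min) else ph
        ia <- imageActivity(ph, "k_hat", cfg$p_min)
      } else {
        ia <- data.frame(image_id = s$image@image_id, coral = coral,
                         a = NA_real_, n_patches = 0L, weight_sum = 0)
      }
      ia$image_id <- s$image@image_id; ia$coral <- coral
      ia$timestamp <- s$image@timestamp
      per_image[[i]] <- ia
      pg <- extractPatches(s$image, s$mask, coral, cfg$patch_size, cfg$p_min)
      if (nrow(pg@info) && !is.null(s$states))
        pg <- labelPatchesFromStates(pg, s$states)
      it <- imageActivity(pg, "k", cfg$p_min)
      it$image_id <- s$image@image_id; it$coral <- coral
      truth_image[[i]] <- it
    }
    per_image <- do.call(rbind, per_image)
    truth_image <- do.call(rbind, truth_image)
    write.csv(per_image[, c("image_id", "coral", "a", "n_patches")],
              file.path(out, paste0("image_activity_", coral, ".csv")),
              row.names = FALSE)
    mae <- maeWithPenalty(per_image[per_image$image_id %in% split$test, ],
                          truth_image[truth_image$image_id %in% split$test, ])
    results[[paste0("mae_", coral)]] <- mae
    logline(coral, "test MAE (with penalty):", round(mae, 4))

    series <- stage(paste0("activity-", coral), hourlySeries(
      per_image, coral, scenes[[1]]$image@campaign, cutoff = cfg$cutoff))
    writeActivityCSV(series, file.path(out, paste0("activity_", coral, ".csv")))
    all_series[[coral]] <- series

    sm <- gaussianSmooth(series, cfg$sigma)
    low <- detectLowActivity(sm$series, cfg$peak_threshold, cfg$min_days)
    write.csv(low, file.path(out, paste0("low_activity_", coral, ".csv")),
              row.names = FALSE)
  }

  if (length(all_series) == 2L) {
    ct <- tryCatch(correlateSeries(all_series$C_r, all_series$C_b),
                   error = function(e) NULL)
    if (!is.null(ct))
      write.csv(ct, file.path(out, "correlation_corals.csv"),
                row.names = FALSE)
  }

  raw_path <- file.path(cfg$input_dir, "sensors_raw.csv")
  if (!is.null(cfg$forecast) && file.exists(raw_path) &&
      "C_r" %in% names(all_series)) {
    fc_cfg <- do.call(ForecastConfig,
                      modifyList(list(seed = cfg$seed), cfg$forecast))
    raw <- readRawSensorCSV(raw_path)
    sens <- hourlySensorSeries(raw)
    fc <- stage("forecast", rollingForecast(sens, all_series$C_r, fc_cfg))
    writeActivityCSV(fc@predicted, file.path(out, "predicted_activity_C_r.csv"))
    write.csv(fc@weekly_log, file.path(out, "forecast_weekly_log.csv"),
              row.names = FALSE)
    results$forecast_mae <- fc@mae
  }

  logline("pipeline complete")
  invisible(results)
}
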