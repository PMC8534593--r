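# End-to-end seeded pipelines. A single config drives every stage; outputs
# land in a subdirectory named by a hash of the config so reruns never mix
# stale intermediates, and a rerun from the same config and seed is
# byte-identical.

#' Pipeline run configuration
#'
#' One global seed deterministically derives every stage seed. Defaults are
#' desk-scale so a full run finishes in minutes on one CPU.
#'
#' @param out_dir Output directory root.
#' @param n_per_class Phantoms generated per class.
#' @param image_size Phantom side length.
#' @param split_ratio Train fraction (default 0.7; 0.8 is the common
#'   alternative).
#' @param feature_scheme Histogram feature scheme (see [extractFeatures()]).
#' @param classifiers Character subset of `c("dt", "knn", "svm", "nb")`.
#' @param cnn_iterations,cnn_batch,cnn_lr CNN classifier training knobs.
#' @param seg_iterations,seg_batch,seg_lr Segmenter training knobs.
#' @param seg_threshold Probability threshold for the predicted mask.
#' @param morph_radius,morph_min_size Morphological refinement parameters.
#' @param auc_cutoff Per-image AUC cutoff for the summary fraction.
#' @param contrast Phantom contrast multiplier (see [generateDataset()]).
#' @param seed Global seed.
#' @return Config list of class `"RunConfig"`.
#' @export
runConfig <- function(out_dir = tempfile("busecho_run_"),
                      n_per_class = 10L, image_size = 256L,
                      split_ratio = 0.7, feature_scheme = "means",
                      classifiers = c("dt", "knn", "svm", "nb"),
                      cnn_iterations = 120L, cnn_batch = 8L, cnn_lr = 1e-3,
                      seg_iterations = 150L, seg_batch = 2L, seg_lr = 2e-3,
                      seg_threshold = 0.5, morph_radius = 5L,
                      morph_min_size = 20L, auc_cutoff = 0.6,
                      contrast = 1, seed = 1L) {
  structure(list(out_dir = out_dir, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 split_ratio = split_ratio, feature_scheme = feature_scheme,
                 classifiers = classifiers,
                 cnn_iterations = as.integer(cnn_iterations),
                 cnn_batch = as.integer(cnn_batch), cnn_lr = cnn_lr,
                 seg_iterations = as.integer(seg_iterations),
                 seg_batch = as.integer(seg_batch), seg_lr = seg_lr,
                 seg_threshold = seg_threshold,
                 morph_radius = as.integer(morph_radius),
                 morph_min_size = as.integer(morph_min_size),
                 auc_cutoff = auc_cutoff, contrast = contrast,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

# stable short hash of the config (excluding out_dir) for content addressing
configHash <- function(cfg) {
  key <- cfg[setdiff(names(cfg), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(key), vapply(key, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";"), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

stageSeed <- function(cfg, stage) {
  offsets <- c(generate = 101L, split = 202L, features = 303L, cls = 404L,
               cnn = 505L, seg = 606L)
  (cfg$seed * 1009L + offsets[[stage]]) %% 2147483647L
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

pipelineDir <- function(cfg, flavor) {
  dir_ <- file.path(cfg$out_dir, paste0(flavor, "_", configHash(cfg)))
  if (!dir.exists(dir_)) dir.create(dir_, recursive = TRUE)
  dir_
}

macroOvrAuc <- function(scores, truth, levels) {
  aucs <- vapply(seq_along(levels), function(i) {
    pos <- truth == levels[i]
    if (!any(pos) || all(pos)) return(NA_real_)
    rocCurve(scores[, i], pos)$auc
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Run the classification pipeline
#'
#' Generate phantoms, split, extract the four histogram features, train the
#' four classical classifiers and the CNN classifier, and evaluate all five
#' on the test split. Writes `features.csv`, one `confusion_<model>.csv`
#' per model and a Table-2-style `metrics.csv` (model, auc, error,
#' accuracy; one-vs-rest macro AUC) into the content-addressed run
#' directory.
#'
#' @param cfg A [runConfig()].
#' @return List with `dir`, `manifest`, `features`, `confusions` and the
#'   `metrics` data.frame.
#' @export
runClassificationPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir_ <- pipelineDir(cfg, "cls")
  data_dir <- file.path(dir_, "data")
  manifest <- runStage("generate",
    generateDataset(cfg$n_per_class, stageSeed(cfg, "generate"), data_dir,
                    image_size = c(cfg$image_size, cfg$image_size),
                    contrast = cfg$contrast))
  manifest <- runStage("split",
    splitDataset(manifest, cfg$split_ratio, stageSeed(cfg, "split")))
  writeManifest(manifest, file.path(dir_, "split.csv"))
  feats <- runStage("features",
    featureTable(manifest, data_dir, scheme = cfg$feature_scheme,
                 seed = stageSeed(cfg, "features")))
  write.csv(feats, file.path(dir_, "features.csv"), row.names = FALSE)
  train <- manifest$split == "train"
  fx <- as.matrix(feats[, c("f1", "f2", "f3", "f4")])
  levels_ <- as.character(sort(unique(manifest$class)))
  confusions <- list()
  metrics <- data.frame()
  for (kind in cfg$classifiers) {
    fc <- runStage("cls", trainClassifier(
      classifierSpec(kind, seed = stageSeed(cfg, "cls")),
      fx[train, , drop = FALSE], manifest$class[train]))
    cm <- evaluateClassifier(fc, fx[!train, , drop = FALSE],
                             manifest$class[!train])
    confusions[[kind]] <- cm
    write.csv(cm, file.path(dir_, paste0("confusion_", kind, ".csv")))
    auc <- macroOvrAuc(predictScores(fc, fx[!train, , drop = FALSE]),
                       as.character(manifest$class[!train]), levels_)
    acc <- accuracyFromConfusion(cm)
    metrics <- rbind(metrics, data.frame(
      model = kind, auc = round(auc, 4),
      error_pct = asPercent(1 - acc), accuracy_pct = asPercent(acc)))
  }
  net <- runStage("cnn", {
    ncfg <- netConfig("classify", image_size = cfg$image_size,
                      iterations = cfg$cnn_iterations,
                      batch_size = cfg$cnn_batch, lr = cfg$cnn_lr,
                      seed = stageSeed(cfg, "cnn"))
    trainClassifierNet(buildClassifierNet(ncfg),
                       manifest[train, , drop = FALSE], dir = data_dir)
  })
  probs <- predictClasses(net, manifest[!train, , drop = FALSE], dir = data_dir)
  pred <- levels_[max.col(probs, ties.method = "first")]
  cm <- confusionCounts(manifest$class[!train], pred, levels_)
  confusions[["cnn"]] <- cm
  write.csv(cm, file.path(dir_, "confusion_cnn.csv"))
  acc <- accuracyFromConfusion(cm)
  metrics <- rbind(metrics, data.frame(
    model = "cnn",
    auc = round(macroOvrAuc(probs, as.character(manifest$class[!train]),
                            levels_), 4),
    error_pct = asPercent(1 - acc), accuracy_pct = asPercent(acc)))
  write.csv(metrics, file.path(dir_, "metrics.csv"), row.names = FALSE)
  list(dir = dir_, manifest = manifest, features = feats,
       confusions = confusions, metrics = metrics, net = net)
}

#' Run the segmentation pipeline
#'
#' Generate lesion-bearing phantoms, train the pixel-labelling CNN on the
#' training split, predict probability maps for the test split, compute the
#' per-image AUC list and its above-cutoff fraction, refine the thresholded
#' masks morphologically and compare the lesion reports against the
#' generator's truth. Writes `aucs.csv`, `summary.csv`, per-image lesion
#' reports (`reports.json`) and contour overlay PNGs.
#'
#' @param cfg A [runConfig()].
#' @return List with `dir`, `aucs`, `auc_above_cutoff`, `median_auc`,
#'   `reports`, `centroid_err` (px, NA when truth or detection is absent)
#'   and the fitted `net`.
#' @export
runSegmentationPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir_ <- pipelineDir(cfg, "seg")
  data_dir <- file.path(dir_, "data")
  manifest <- runStage("generate",
    generateDataset(cfg$n_per_class, stageSeed(cfg, "generate"), data_dir,
                    image_size = c(cfg$image_size, cfg$image_size),
                    contrast = cfg$contrast))
  manifest <- manifest[manifest$class != 0L, , drop = FALSE]  # lesion-bearing
  missing <- !file.exists(file.path(data_dir, manifest$mask_file))
  if (any(missing))
    stop("missing mask for image: ",
         paste(manifest$file[missing], collapse = ", "))
  manifest <- splitDataset(manifest, cfg$split_ratio, stageSeed(cfg, "split"))
  writeManifest(manifest, file.path(dir_, "split.csv"))
  train <- manifest$split == "train"
  net <- runStage("seg", {
    ncfg <- netConfig("segment", image_size = cfg$image_size,
                      iterations = cfg$seg_iterations,
                      batch_size = cfg$seg_batch, lr = cfg$seg_lr,
                      seed = stageSeed(cfg, "seg"))
    trainSegmenterNet(buildSegmenterNet(ncfg),
                      manifest[train, , drop = FALSE], dir = data_dir)
  })
  test_rows <- which(!train)
  aucs <- rep(NA_real_, length(test_rows))
  cents <- rep(NA_real_, length(test_rows))
  reports <- vector("list", length(test_rows))
  for (k in seq_along(test_rows)) {
    i <- test_rows[k]
    img <- loadImage(file.path(data_dir, manifest$file[i]))
    gt <- loadImage(file.path(data_dir, manifest$mask_file[i]))
    pm <- predictMask(net, img, threshold = cfg$seg_threshold)
    tum <- decodeMask(gt)$tumor
    if (any(tum) && !all(tum)) aucs[k] <- perImageAuc(pm$prob, gt)
    refined <- morphologicalRefine(pm$mask, radius = cfg$morph_radius,
                                   min_size = cfg$morph_min_size)
    rep_ <- lesionReport(refined)
    reports[[k]] <- rep_
    if (rep_@present && !is.na(manifest$lesion_row[i]))
      cents[k] <- sqrt((rep_@centroid[1] - manifest$lesion_row[i])^2 +
                       (rep_@centroid[2] - manifest$lesion_col[i])^2)
    overlay <- img
    edge <- refined == 255L &
      !(EBImage::erode(EBImage::Image(t(refined == 255L) * 1),
                       EBImage::makeBrush(3, "box")) |> EBImage::imageData() |> t() > 0.5)
    overlay[edge] <- 255L
    saveImage(overlay, file.path(dir_, paste0("overlay_", manifest$file[i])))
  }
  auc_df <- data.frame(file = manifest$file[test_rows], auc = aucs,
                       centroid_err_px = cents)
  write.csv(auc_df, file.path(dir_, "aucs.csv"), row.names = FALSE)
  summary_df <- data.frame(
    median_auc = median(aucs, na.rm = TRUE),
    auc_above_cutoff = mean(aucs > cfg$auc_cutoff, na.rm = TRUE),
    centroid_within_3px = mean(cents <= 3, na.rm = TRUE))
  write.csv(summary_df, file.path(dir_, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(reports, lesionReportAsList),
                       file.path(dir_, "reports.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  list(dir = dir_, aucs = aucs, median_auc = summary_df$median_auc,
       auc_above_cutoff = summary_df$auc_above_cutoff,
       centroid_err = cents, reports = reports, net = net)
}
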