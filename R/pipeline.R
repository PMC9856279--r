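# End-to-end pipeline: synthetic data (optional) -> preprocessing ->
# CNN training -> calibration -> hybrid head -> evaluation -> RPE scoring,
# with every artifact stamped by the config hash and seed.

#' Default pipeline configuration
#'
#' Defaults mirror the reference training recipe (epochs 19, batch 8,
#' seed 0, k 512, sym_one scaling) at the full 512 canvas; tests and the
#' worked examples use smaller canvases and counts.
#'
#' @return named list of pipeline settings.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = tempfile("slicenet_run_"),
    counts = c(IPSC = 40L, MSC = 40L, RGC = 40L, RPE = 40L),
    canvas_side = 512L,
    scale_bar_frac = 0,
    crop_margin = 0,
    scale_mode = "sym_one",
    train_frac = 2 / 3,
    val_frac = 0.20,
    divide_expand = FALSE,
    model = "multi",
    branch_filters = c(32L, 64L, 128L),
    merge_filters = 128L,
    dense_width = 128L,
    epochs = 19L,
    batch_size = 8L,
    learning_rate = 1e-3,
    k = 512L,
    projector = "pca",
    kernel = "radial",
    seed = 0L,
    ref_class = "IPSC",
    target_class = "RPE",
    verbose = FALSE)
}

read_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  bad <- setdiff(names(config), names(base))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  if (!is.null(cfg$counts)) cfg$counts <- unlist(cfg$counts)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stopf("train_frac must lie in (0, 1), got %g", cfg$train_frac)
  if (!cfg$model %in% c("multi", "single")) stopf("model must be 'multi' or 'single'")
  cfg
}

bundles_of <- function(imgs, side, scale_mode, crop_margin = 0) {
  lapply(imgs, prep_bundle, side = side, scale_mode = scale_mode,
         crop_margin = crop_margin)
}

labels_of <- function(imgs) vapply(imgs, function(x) x$label, "")
ids_of <- function(imgs) vapply(imgs, function(x) x$source_id, "")

#' Run the full pipeline from a config
#'
#' Stages: generate (or load) the dataset, split, preprocess into slice
#' bundles, train the CNN, calibrate it into a feature extractor, fit the
#' hybrid PCA/SVM head on training features, evaluate on the held-out test
#' set, find the iPSC/RPE separating axis and score the test RPE images.
#' All randomness derives from `config$seed`; rerunning an identical config
#' reproduces the report exactly. Artifacts (manifest, split membership,
#' training history, evaluation CSVs, scores) are written under
#' `config$out_dir` together with a log recording the config hash, seed and
#' per-stage sample counts.
#'
#' @param config a named list (see [default_pipeline_config()]) or a YAML
#'   file path; unknown keys are rejected before any compute.
#' @return invisibly, a list with the fit, extractor, head, separating
#'   axis, evaluation report, scores and the artifact directory.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- object_md5(cfg[setdiff(names(cfg), "out_dir")])
  logf <- file.path(cfg$out_dir, "pipeline_log.txt")
  log_line <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logf, append = TRUE)
    if (cfg$verbose) message(sprintf(fmt, ...))
  }
  cat(sprintf("slicenet pipeline\nconfig_hash: %s\nseed: %d\n\n",
              cfg_hash, cfg$seed), file = logf)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed (config %s): %s", name, cfg_hash,
            conditionMessage(e)))
  }

  ds <- stage("gen-data", {
    d <- generate_dataset(cfg$counts, seed = cfg$seed,
                          canvas_side = cfg$canvas_side,
                          scale_bar_frac = cfg$scale_bar_frac)
    utils::write.csv(d$manifest, file.path(cfg$out_dir, "manifest.csv"),
                     row.names = FALSE)
    log_line("gen-data: %d images (%s)", length(d$images),
             paste(sprintf("%s=%d", names(cfg$counts), cfg$counts), collapse = ", "))
    d
  })

  split <- stage("split", {
    s <- split_dataset(ds$images, train_frac = cfg$train_frac,
                       val_frac = cfg$val_frac, seed = cfg$seed)
    memb <- rbind(
      data.frame(id = ids_of(s$train), split = "train"),
      data.frame(id = ids_of(s$val), split = "val"),
      data.frame(id = ids_of(s$test), split = "test"))
    utils::write.csv(memb, file.path(cfg$out_dir, "split.csv"), row.names = FALSE)
    log_line("split: %d source -> train %d (augmented), val %d, test %d",
             s$counts["source"], s$counts["train"], s$counts["val"],
             s$counts["test"])
    s
  })

  train_imgs <- split$train
  if (isTRUE(cfg$divide_expand)) {
    train_imgs <- stage("divide-expand", {
      out <- divide_expand(train_imgs)
      log_line("divide-expand: %d -> %d samples", length(split$train), length(out))
      out
    })
  }

  prep <- stage("prep", {
    side <- cfg$canvas_side
    p <- list(
      train = bundles_of(train_imgs, side, cfg$scale_mode, cfg$crop_margin),
      val = bundles_of(split$val, side, cfg$scale_mode, cfg$crop_margin),
      test = bundles_of(split$test, side, cfg$scale_mode, cfg$crop_margin))
    log_line("prep: %d/%d/%d bundles (scale %s, crop %.2f)",
             length(p$train), length(p$val), length(p$test),
             cfg$scale_mode, cfg$crop_margin)
    p
  })

  mcfg <- mst_config(canvas_side = cfg$canvas_side,
                     branch_filters = cfg$branch_filters,
                     merge_filters = cfg$merge_filters,
                     dense_width = cfg$dense_width,
                     epochs = cfg$epochs, batch_size = cfg$batch_size,
                     learning_rate = cfg$learning_rate,
                     scale_mode = cfg$scale_mode, seed = cfg$seed)
  fit <- stage("train", {
    net <- if (cfg$model == "multi") build_multi_slice(mcfg)
           else build_single_tensor(mcfg)
    f <- mst_train(net, prep$train, labels_of(train_imgs),
                   val_bundles = prep$val, val_labels = labels_of(split$val),
                   verbose = cfg$verbose)
    utils::write.csv(f$history, file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    log_line("train: %d epochs, final acc %.3f", nrow(f$history),
             f$history$accuracy[nrow(f$history)])
    f
  })

  extractor <- stage("calibrate", calibrate(fit))

  head_fit <- stage("fit-head", {
    feats <- predict(extractor, prep$train)
    h <- withCallingHandlers(
      fit_head(feats, labels_of(train_imgs), k = cfg$k,
               projector = cfg$projector, kernel = cfg$kernel),
      warning = function(w) { log_line("fit-head: %s", conditionMessage(w))
                              invokeRestart("muffleWarning") })
    log_line("fit-head: %s(k=%d) + %s SVM on %d features",
             cfg$projector, h$k, cfg$kernel, ncol(feats))
    list(head = h, train_feats = feats)
  })

  report <- stage("evaluate", {
    test_feats <- predict(extractor, prep$test)
    preds <- classify(head_fit$head, test_feats)
    r <- evaluate(preds, labels_of(split$test))
    write_eval_report(r, file.path(cfg$out_dir, "evaluation"))
    log_line("evaluate: overall accuracy %.1f%% on %d test images",
             r$accuracy, r$n)
    list(report = r, test_feats = test_feats)
  })

  scores <- stage("score-rpe", {
    proj_train <- project(head_fit$head, head_fit$train_feats)
    axis <- find_separating_axis(proj_train, labels_of(train_imgs),
                                 ref_class = cfg$ref_class,
                                 target_class = cfg$target_class)
    is_t <- labels_of(split$test) == cfg$target_class
    sc <- if (any(is_t)) {
      pt <- project(head_fit$head, report$test_feats[is_t, , drop = FALSE])
      score_samples(axis, pt, sample_ids = ids_of(split$test)[is_t])
    } else data.frame(sample_id = character(0), coordinate = numeric(0),
                      rank = integer(0))
    utils::write.csv(sc, file.path(cfg$out_dir, "rpe_scores.csv"),
                     row.names = FALSE)
    log_line("score-rpe: axis %d (sided %.2f), %d samples scored",
             axis$axis_index, axis$sided_fraction, nrow(sc))
    list(axis = axis, scores = sc)
  })

  log_line("done")
  res <- list(config = cfg, config_hash = cfg_hash, dataset = ds,
              split = split, fit = fit, extractor = extractor,
              head = head_fit$head, report = report$report,
              axis = scores$axis, scores = scores$scores,
              out_dir = cfg$out_dir)
  saveRDS(res[setdiff(names(res), c("dataset", "split"))],
          file.path(cfg$out_dir, "pipeline_result.rds"))
  invisible(res)
}
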