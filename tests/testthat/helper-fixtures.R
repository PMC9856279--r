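# Shared fixtures. Heavy objects (trained pipelines) are computed once per
# test session and cached, so several test files can probe the same fit.

.fixtures <- new.env(parent = emptyenv())

fx <- function(key, make) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- make()
  .fixtures[[key]]
}

labels_of <- function(l) vapply(l, function(x) x$label, "")

# concatenate two H x W x C arrays along rows / columns
abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}
abind_cols <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

# a small but real architecture: canvas 64 keeps every structural element of
# the reference network (front average pool, three conv/pool stages, merge,
# dropout, average pool, dense softmax) with all spatial sides scaled by 1/8
tiny_cfg <- function(seed = 1, dropout = 0, filters = c(4L, 6L, 8L)) {
  mst_config(canvas_side = 64, branch_filters = filters, merge_filters = 8L,
             dense_width = 16L, dropout_rate = dropout, epochs = 2L,
             batch_size = 4L, seed = seed)
}

tiny_bundle <- function(class = "RPE", seed = 7, degree = 0.5,
                        scale_mode = "sym_one") {
  img <- generate_image(phenotype_spec(class, 64, rpe_degree = degree,
                                       seed = seed))
  prep_bundle(img, side = 64, scale_mode = scale_mode)
}

# a minimally trained tiny fit (enough for heatmaps / calibration contracts)
tiny_fit <- function() fx("tiny_fit", function() {
  imgs <- unlist(lapply(cell_classes(), function(cl) lapply(1:4, function(i)
    generate_image(phenotype_spec(cl, 64, rpe_degree = 0.8, seed = 50 + i)))),
    recursive = FALSE)
  bundles <- lapply(imgs, prep_bundle, side = 64, scale_mode = "sym_one")
  net <- build_multi_slice(tiny_cfg(seed = 3, dropout = 0.5))
  mst_train(net, bundles, labels_of(imgs), epochs = 2)
})

# the package's scaled-down study conditions: 32 images/class at canvas 64,
# 10 epochs, batch 8, sym_one scaling, PCA(k)+RBF-SVM head; held-out
# accuracy is measured both on the pipeline's own test split and on a
# fresh 100-image synthetic set generated under a different master seed
study_config <- function(seed) {
  list(counts = c(IPSC = 32L, MSC = 32L, RGC = 32L, RPE = 32L),
       canvas_side = 64L, train_frac = 0.75, epochs = 10L, seed = seed,
       out_dir = file.path(tempdir(), sprintf("slicenet_fx_%d", seed)))
}

trained_pipeline <- function(seed) fx(sprintf("pipe_%d", seed), function() {
  pipe <- suppressWarnings(run_pipeline(study_config(seed)))
  fresh <- generate_dataset(c(IPSC = 25L, MSC = 25L, RGC = 25L, RPE = 25L),
                            seed = 7700 + seed, canvas_side = 64)
  fb <- lapply(fresh$images, prep_bundle, side = 64, scale_mode = "sym_one")
  truth <- labels_of(fresh$images)
  pred <- classify(pipe$head, predict(pipe$extractor, fb))
  pipe$fresh_accuracy <- 100 * mean(pred == truth)
  pipe
})

# the scale-bar confound study: bar presence is coupled to acquisition
# provenance via twin structureless classes — every "MSC-batch" image is
# blank except for a burned-in corner bar, its "RGC-batch" twin is blank
# without one — so the bar is the only cue separating them and the trained
# network provably relies on it. Fresh held-out stamped images probe where
# the attention lands.
bar_confound_fit <- function(seed) fx(sprintf("barfit_%d", seed), function() {
  ds <- generate_dataset(c(IPSC = 8L, RPE = 8L), seed = 300 + seed,
                         canvas_side = 64)
  msc <- lapply(1:16, function(i)
    stamp_scale_bar(generate_image(phenotype_spec("MSC", 64, n_structures = 0L,
                                                  seed = 7000 + seed * 50 + i)),
                    "bottom_right", c(24L, 6L), inset = 2L))
  rgc <- lapply(1:16, function(i)
    generate_image(phenotype_spec("RGC", 64, n_structures = 0L,
                                  seed = 7500 + seed * 50 + i)))
  imgs <- c(ds$images, msc, rgc)
  sp <- split_dataset(imgs, train_frac = 0.75, val_frac = 0, seed = seed)
  cfg <- mst_config(canvas_side = 64, epochs = 8L, batch_size = 8L, seed = seed)
  tb <- lapply(sp$train, prep_bundle, side = 64, scale_mode = "sym_one")
  fit <- mst_train(build_multi_slice(cfg), tb, labels_of(sp$train))
  test_imgs <- lapply(1:4, function(i)
    stamp_scale_bar(generate_image(phenotype_spec("MSC", 64, n_structures = 0L,
                                                  seed = 8000 + seed * 10 + i)),
                    "bottom_right", c(24L, 6L), inset = 2L))
  list(fit = fit, test_imgs = test_imgs)
})

# an RPE-only degree series pushed through a trained pipeline
degree_series_scores <- function(pipe, seed) {
  degs <- seq(0.05, 0.95, length.out = 20)
  ids <- sprintf("rpe_%02d", seq_along(degs))
  bundles <- lapply(seq_along(degs), function(i)
    prep_bundle(generate_image(phenotype_spec("RPE", 64, rpe_degree = degs[i],
                                              seed = 9000 + seed * 100 + i)),
                side = 64, scale_mode = "sym_one"))
  feats <- predict(pipe$extractor, bundles)
  proj <- project(pipe$head, feats)
  sc <- score_samples(pipe$axis, proj, sample_ids = ids)
  data.frame(degree = degs, score = sc$coordinate[match(ids, sc$sample_id)])
}

# lightweight placeholder images for split/augmentation arithmetic at the
# published dataset sizes (pixel content is irrelevant to the counting)
dummy_images <- function(n, label = "IPSC") {
  px <- array(128, c(64, 64, 3))
  lapply(seq_len(n), function(i)
    labeled_image(px, label = label, source_id = sprintf("%s_%d", label, i)))
}
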