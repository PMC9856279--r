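# The multi-slice tensor network: shape ledger, backprop correctness
# against finite differences, determinism, calibration and prediction
# contracts.

test_that("configured shapes satisfy the architecture's invariants", {
  cfg <- mst_config()                       # reference 512 configuration
  sh <- slicenet:::mst_shapes(cfg, "multi")
  expect_identical(sh$branch_input, c(256L, 256L, 3L))
  expect_identical(sh$branch_output, c(32L, 32L, 128L))
  expect_identical(sh$concat, c(32L, 32L, 640L))       # 5 x 128 channels
  expect_identical(sh$post_pool, c(16L, 16L, 128L))
  expect_identical(sh$flatten, 32768L)                  # 16 x 16 x 128

  expect_error(mst_config(canvas_side = 100), "multiple of 32")
  expect_error(mst_config(kernel = 5), "3x3")
})

test_that("backprop gradients match finite differences", {
  cfg <- tiny_cfg(seed = 1)
  net <- build_multi_slice(cfg)
  b <- tiny_bundle("RPE", seed = 7)
  fw <- slicenet:::net_forward(net, b, train = TRUE, keep = "train")
  y <- c(0, 0, 0, 1)
  g <- slicenet:::net_backward(net, fw, y)
  loss_at <- function(n) -log(slicenet:::net_forward(n, b)$probs[4])

  set.seed(99)
  for (nm in c("br1_c1_W", "br3_c2_W", "br5_c3_W", "br2_c1_b",
               "merge_W", "merge_b", "fc_W", "fc_b", "out_W", "out_b")) {
    p <- net$params[[nm]]
    for (trial in 1:3) {
      i <- sample(length(p), 1)
      eps <- 1e-5
      n2 <- net
      n2$params[[nm]][i] <- p[i] + eps; lp <- loss_at(n2)
      n2$params[[nm]][i] <- p[i] - eps; lm <- loss_at(n2)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])),
                1e-5)
    }
  }
})

test_that("softmax output is a proper probability vector", {
  net <- build_multi_slice(tiny_cfg(seed = 2))
  b <- tiny_bundle("MSC", seed = 3)
  pr <- predict(net, b, type = "prob")
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))

  # zeroed final layer -> exactly uniform probabilities
  net$params$out_W[] <- 0
  net$params$out_b[] <- 0
  expect_equal(as.vector(predict(net, b, type = "prob")),
               rep(0.25, 4), tolerance = 1e-12)
})

test_that("single-tensor baseline shares the head but drops four branches", {
  cfg <- tiny_cfg(seed = 4)
  multi <- build_multi_slice(cfg)
  single <- build_single_tensor(cfg)
  expect_lt(n_params(single), n_params(multi))
  expect_identical(single$shapes$n_branches, 1L)
  # same flatten length: the merge/pool/flatten head is identical
  expect_identical(single$shapes$flatten, multi$shapes$flatten)
  b <- tiny_bundle("IPSC", seed = 5)
  expect_equal(sum(predict(single, b, type = "prob")), 1, tolerance = 1e-6)
})

test_that("tied branch weights shrink the model and still run", {
  cfg_tied <- mst_config(canvas_side = 64, branch_filters = c(4L, 6L, 8L),
                         merge_filters = 8L, dense_width = 16L,
                         tie_branch_weights = TRUE, seed = 1)
  tied <- build_multi_slice(cfg_tied)
  untied <- build_multi_slice(tiny_cfg(seed = 1))
  expect_lt(n_params(tied), n_params(untied))
  b <- tiny_bundle("RGC", seed = 6)
  expect_equal(sum(predict(tied, b, type = "prob")), 1, tolerance = 1e-6)
})

test_that("training is deterministic and records one history row per epoch", {
  imgs <- lapply(1:8, function(i) generate_image(
    phenotype_spec(cell_classes()[(i - 1) %% 4 + 1], 64, rpe_degree = 0.6,
                   seed = i)))
  bundles <- lapply(imgs, prep_bundle, side = 64, scale_mode = "sym_one")
  labs <- labels_of(imgs)

  f1 <- mst_train(build_multi_slice(tiny_cfg(seed = 5, dropout = 0.5)),
                  bundles, labs, epochs = 1)
  expect_identical(nrow(f1$history), 1L)
  f2 <- mst_train(build_multi_slice(tiny_cfg(seed = 5, dropout = 0.5)),
                  bundles, labs, epochs = 1)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$net$params, f2$net$params)

  # dropout is inactive at inference: repeated passes agree exactly
  p1 <- predict(f1, bundles[[1]], type = "prob")
  p2 <- predict(f1, bundles[[1]], type = "prob")
  expect_identical(p1, p2)

  expect_error(mst_train(build_multi_slice(tiny_cfg()), list(), character(0)),
               "empty")
  expect_error(mst_train(build_multi_slice(tiny_cfg()), bundles,
                         rep("ASTRO", 8)), "unknown label")
})

test_that("divergent training aborts with a diagnostic", {
  imgs <- lapply(1:4, function(i) generate_image(
    phenotype_spec("IPSC", 64, seed = i)))
  bundles <- lapply(imgs, prep_bundle, side = 64, scale_mode = "sym_one")
  expect_error(
    mst_train(build_multi_slice(tiny_cfg(seed = 1)), bundles,
              rep("IPSC", 4), epochs = 2, learning_rate = 1e200),
    "diverged")
})

test_that("calibration truncates at the flatten layer", {
  fit <- tiny_fit()
  ex <- calibrate(fit)
  b <- tiny_bundle("RPE", seed = 11, degree = 0.7)

  feats <- predict(ex, b)
  expect_length(feats, fit$net$shapes$flatten)
  # definitional equality with the full model's flatten activation
  expect_identical(feats, as.vector(predict(fit, b, type = "feature")))
  # the extractor serializes strictly smaller than the full fit
  expect_lt(slicenet:::serialized_size(ex), slicenet:::serialized_size(fit))

  # zero input -> finite features
  zb <- make_slices(array(0, c(64, 64, 3)), "sym_one")
  expect_true(all(is.finite(predict(ex, zb))))

  expect_error(calibrate(fit$net), "mst_fit")
})

test_that("bundle/config mismatches are rejected", {
  net <- build_multi_slice(tiny_cfg())
  b01 <- tiny_bundle("IPSC", seed = 2, scale_mode = "zero_one")
  expect_error(slicenet:::net_forward(net, b01), "scale_mode")
  big <- make_slices(array(0.5, c(128, 128, 3)), "sym_one")
  expect_error(slicenet:::net_forward(net, big), "side")
})

test_that("flip augmentation does not hurt held-out accuracy beyond noise", {
  accs <- sapply(0:2, function(sd) {
    ds <- generate_dataset(c(IPSC = 16, MSC = 16, RGC = 16, RPE = 16),
                           seed = 100 + sd, canvas_side = 64)
    sp <- split_dataset(ds, train_frac = 0.75, val_frac = 0, seed = sd)
    cfg <- mst_config(canvas_side = 64, branch_filters = c(8L, 12L, 16L),
                      merge_filters = 16L, dense_width = 32L,
                      epochs = 3L, batch_size = 8L, seed = sd)
    test_b <- lapply(sp$test, prep_bundle, side = 64, scale_mode = "sym_one")
    acc_of <- function(train_imgs) {
      tb <- lapply(train_imgs, prep_bundle, side = 64, scale_mode = "sym_one")
      fit <- mst_train(build_multi_slice(cfg), tb, labels_of(train_imgs))
      mean(predict(fit, test_b) == labels_of(sp$test))
    }
    # sp$train is the augmented pool; strip to originals for the baseline
    originals <- sp$train[grepl("::orig$", vapply(sp$train, `[[`, "", "source_id"))]
    c(aug = acc_of(sp$train), plain = acc_of(originals))
  })
  expect_gte(mean(accs["aug", ]), mean(accs["plain", ]) - 0.05)
})
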