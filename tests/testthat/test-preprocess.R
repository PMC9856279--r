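# Loading, cropping, resizing, scaling, slicing, augmentation and splitting.

test_that("images round-trip losslessly and channels are normalized", {
  dir <- withr::local_tempdir()

  # grayscale TIFF replicates across channels
  g <- matrix(seq(0, 1, length.out = 100 * 100), 100, 100)
  tiff::writeTIFF(g, file.path(dir, "gray.tiff"), bits.per.sample = 8L)
  im <- load_image(file.path(dir, "gray.tiff"))
  expect_equal(dim(im$pixels), c(100, 100, 3))
  expect_identical(im$pixels[, , 1], im$pixels[, , 2])
  expect_identical(im$pixels[, , 1], im$pixels[, , 3])

  # RGBA PNG: alpha dropped
  rgba <- array(runif(64 * 64 * 4), c(64, 64, 4))
  png::writePNG(rgba, file.path(dir, "rgba.png"))
  im2 <- load_image(file.path(dir, "rgba.png"))
  expect_equal(dim(im2$pixels), c(64, 64, 3))

  # save -> load -> identical pixels (lossless round trip), label from dir
  src <- generate_image(phenotype_spec("MSC", 64, seed = 1))
  dir.create(file.path(dir, "MSC"))
  p <- file.path(dir, "MSC", "img.png")
  save_image(src, p)
  back <- load_image(p)
  expect_identical(back$pixels, src$pixels)
  expect_identical(back$label, "MSC")

  expect_error(load_image(file.path(dir, "missing.png")), "missing.png")
})

test_that("fixed-margin crop removes corner scale bars", {
  img <- generate_image(phenotype_spec("IPSC", 512, seed = 2))
  st <- stamp_scale_bar(img, "bottom_right", c(80L, 12L), inset = 6L)

  cr <- crop_scale_bar(st, 0.05)
  expect_equal(dim(cr$pixels), c(462, 462, 3))   # 512 - 2*floor(512*0.05)
  expect_false(cr$has_scale_bar)
  # every bar pixel lies in the margin: the crop of the stamped image is
  # pixel-identical to the crop of the pristine one
  expect_identical(cr$pixels, crop_scale_bar(img, 0.05)$pixels)

  # margin 0 is the identity on pixels
  id <- crop_scale_bar(st, 0)
  expect_identical(id$pixels, st$pixels)

  expect_error(crop_scale_bar(img, 0.3), "margin_frac")
})

test_that("canonicalize resizes bilinearly and preserves trivial cases", {
  img <- generate_image(phenotype_spec("RGC", 128, seed = 4))
  out <- canonicalize(img, 512)
  expect_equal(dim(out$pixels), c(512, 512, 3))

  # same-size input is numerically untouched
  img512 <- generate_image(phenotype_spec("RGC", 512, seed = 4))
  expect_identical(canonicalize(img512, 512)$pixels, img512$pixels)

  # constant image stays constant under bilinear interpolation
  const <- labeled_image(array(140, c(128, 96, 3)), "IPSC")
  cc <- canonicalize(const, 64)
  expect_equal(max(abs(cc$pixels - 140)), 0, tolerance = 1e-9)
})

test_that("pixel scaling maps boundaries and midpoint exactly", {
  t <- array(c(0, 127.5, 255), c(1, 3, 1))[rep(1, 64), , rep(1, 3)]
  z <- scale_pixels(t, "zero_one")
  s <- scale_pixels(t, "sym_one")
  expect_equal(unique(as.vector(z[, 1, ])), 0)
  expect_equal(unique(as.vector(z[, 3, ])), 1)
  expect_equal(unique(as.vector(z[, 2, ])), 0.5)
  expect_equal(unique(as.vector(s[, 1, ])), -1)
  expect_equal(unique(as.vector(s[, 3, ])), 1)
  expect_equal(unique(as.vector(s[, 2, ])), 0)
  expect_error(scale_pixels(t - 10, "zero_one"), "outside")
})

test_that("slicing partitions the macro tensor in fixed quadrant order", {
  img <- generate_image(phenotype_spec("MSC", 64, seed = 6))
  t <- scale_pixels(canonicalize(img, 64)$pixels, "sym_one")
  b <- make_slices(t, "sym_one")

  # reassembly reproduces the macro exactly
  top <- abind_cols(b$quadrants$TL, b$quadrants$TR)
  bottom <- abind_cols(b$quadrants$BL, b$quadrants$BR)
  re <- abind_rows(top, bottom)
  expect_identical(re, b$macro)

  # a single nonzero pixel at (10, 50) lands only in the top-right quadrant
  one <- array(0, c(64, 64, 3))
  one[10, 50, ] <- 1
  b1 <- make_slices(one, "sym_one")
  expect_true(all(b1$quadrants$TR[10, 18, ] == 1))
  expect_identical(sum(b1$quadrants$TL != 0) + sum(b1$quadrants$BL != 0) +
                     sum(b1$quadrants$BR != 0), 0L)

  expect_error(make_slices(array(0, c(64, 32, 3))), "side x side")
  expect_error(make_slices(array(5, c(64, 64, 3)), "sym_one"), "scale_pixels")
})

test_that("flip augmentation quadruples the set and is an involution", {
  imgs <- lapply(1:3, function(i)
    generate_image(phenotype_spec("RPE", 64, rpe_degree = 0.4, seed = i)))
  aug <- augment_flips(imgs)
  expect_length(aug, 12L)
  expect_identical(labels_of(aug), rep("RPE", 12))

  # hv-flip applied twice is the identity
  hv <- aug[[4]]                              # variants ordered orig,h,v,hv
  expect_match(hv$source_id, "::hv$")
  hv2 <- augment_flips(list(hv))[[4]]
  expect_identical(hv2$pixels, imgs[[1]]$pixels)

  # class proportions conserved exactly
  mix <- c(imgs, lapply(1:2, function(i)
    generate_image(phenotype_spec("IPSC", 64, seed = i))))
  am <- augment_flips(mix)
  expect_equal(as.vector(table(labels_of(am))),
               4L * as.vector(table(labels_of(mix))))
})

test_that("divide-expand adds the four upscaled quadrants per image", {
  imgs <- lapply(1:2, function(i)
    generate_image(phenotype_spec("RPE", 256, rpe_degree = 0.5, seed = i + 30)))
  ex <- divide_expand(imgs)
  expect_length(ex, 10L)

  # constant image yields five constant samples
  const <- labeled_image(array(150, c(64, 64, 3)), "IPSC")
  ec <- divide_expand(list(const))
  for (e in ec) expect_equal(max(abs(e$pixels - 150)), 0, tolerance = 1e-9)

  # a quadrant sample's pigment fraction matches that quadrant's share of
  # the parent, within resize tolerance
  parent <- imgs[[1]]
  q1 <- ex[[2]]                               # parent's top-left quadrant
  expect_match(q1$source_id, "::q1$")
  parent_q1_frac <- mean(luminance(parent$pixels[1:128, 1:128, ]) < 90)
  expect_lt(abs(pigment_fraction(q1) - parent_q1_frac), 0.02)
})

test_that("train/val/test splitting is disjoint, seeded and augment-aware", {
  imgs <- c(dummy_images(30, "IPSC"), dummy_images(30, "RPE"))
  s1 <- split_dataset(imgs, train_frac = 0.5, val_frac = 0.2, seed = 0)
  s2 <- split_dataset(imgs, train_frac = 0.5, val_frac = 0.2, seed = 0)
  expect_identical(vapply(s1$train, `[[`, "", "source_id"),
                   vapply(s2$train, `[[`, "", "source_id"))
  expect_identical(vapply(s1$test, `[[`, "", "source_id"),
                   vapply(s2$test, `[[`, "", "source_id"))

  # test sources never appear among training sources (pre-augmentation ids)
  src_of <- function(l) unique(sub("::.*$", "", vapply(l, `[[`, "", "source_id")))
  expect_length(intersect(src_of(s1$test), src_of(c(s1$train, s1$val))), 0L)
  expect_identical(s1$counts[["train_source"]] + s1$counts[["test"]], 60L)

  # test subset is not augmented; train pool is the 4x augmentation
  expect_identical(s1$counts[["augmented"]], 4L * s1$counts[["train_source"]])
  expect_identical(s1$counts[["val"]],
                   as.integer(floor(0.2 * s1$counts[["augmented"]])))

  expect_error(split_dataset(imgs, train_frac = 0), "train_frac")
  expect_error(split_dataset(imgs, train_frac = 0.5, val_frac = 1), "val_frac")
})

test_that("the preprocessing chain composes into a valid slice bundle", {
  img <- stamp_scale_bar(generate_image(phenotype_spec("IPSC", 96, seed = 8)),
                         "top_right", c(20L, 4L), inset = 2L)
  b <- prep_bundle(img, side = 64, scale_mode = "sym_one", crop_margin = 0.05)
  expect_s3_class(b, "slice_bundle")
  expect_identical(dim(b$macro), c(64L, 64L, 3L))
  expect_length(b$quadrants, 4L)
  expect_true(all(vapply(b$quadrants, function(q)
    all(dim(q) == c(32, 32, 3)), TRUE)))
  rng <- range(b$macro)
  expect_gte(rng[1], -1); expect_lte(rng[2], 1)
  top <- abind_cols(b$quadrants$TL, b$quadrants$TR)
  bottom <- abind_cols(b$quadrants$BL, b$quadrants$BR)
  expect_identical(abind_rows(top, bottom), b$macro)
})
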