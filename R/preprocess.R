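#' Load a microscopy image from disk
#'
#' Reads JPEG, TIFF or PNG into the package's canonical representation: an
#' H x W x 3 array on the 0-255 scale. Grayscale images are replicated
#' across the three channels; an alpha channel is dropped; 16-bit TIFFs are
#' linearly rescaled to the 8-bit range.
#'
#' @param path image file path.
#' @param label optional class label; when NULL, taken from the name of the
#'   enclosing directory if it matches one of [cell_classes()].
#' @return a [labeled_image()].
#' @export
load_image <- function(path, label = NULL) {
  if (!file.exists(path)) stopf("no such image file: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stopf("unsupported image format '.%s' for %s", ext, path)),
    error = function(e) stopf("failed to read %s: %s", path, conditionMessage(e)))
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nc <- dim(raw)[3]
  px <- if (nc == 1L) array(raw[, , 1], c(dim(raw)[1:2], 3L))
        else if (nc >= 3L) raw[, , 1:3, drop = FALSE]
        else stopf("unsupported channel count %d in %s", nc, path)
  px <- round(px * 255)
  if (is.null(label)) {
    dirlab <- basename(dirname(path))
    label <- if (dirlab %in% cell_classes()) dirlab else NA_character_
  }
  labeled_image(px, label = label,
                source_id = tools::file_path_sans_ext(basename(path)))
}

#' Save a labeled image as PNG or TIFF (lossless)
#'
#' @param img a [labeled_image()].
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "labeled_image"))
  a <- img$pixels / 255
  a[a < 0] <- 0; a[a > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(a, path),
    tif = , tiff = tiff::writeTIFF(a, path, bits.per.sample = 8L),
    stopf("unsupported output format '.%s'", ext))
  invisible(path)
}

#' Remove burned-in scale bars by a fixed-margin centered crop
#'
#' Scale bars sit at image corners; a centered crop discarding
#' `margin_frac` of the height and width from each edge removes them
#' without any detection step.
#'
#' @param img a [labeled_image()].
#' @param margin_frac fraction cropped from each edge, in \[0, 0.25).
#' @return cropped [labeled_image()] with `has_scale_bar = FALSE`.
#' @export
crop_scale_bar <- function(img, margin_frac = 0.05) {
  stopifnot(inherits(img, "labeled_image"))
  if (margin_frac < 0 || margin_frac >= 0.25)
    stopf("margin_frac must lie in [0, 0.25), got %g", margin_frac)
  if (margin_frac == 0) {
    out <- img
    out$has_scale_bar <- FALSE
    out$scale_bar_rects <- list()
    return(out)
  }
  d <- dim(img$pixels); H <- d[1]; W <- d[2]
  mh <- floor(H * margin_frac); mw <- floor(W * margin_frac)
  rows <- (mh + 1L):(H - mh); cols <- (mw + 1L):(W - mw)
  out <- img
  out$pixels <- img$pixels[rows, cols, , drop = FALSE]
  if (!is.null(img$pigment_mask))
    out$pigment_mask <- img$pigment_mask[rows, cols, drop = FALSE]
  out$has_scale_bar <- FALSE
  out$scale_bar_rects <- list()
  out
}

# bilinear resize of an H x W x C array (any numeric scale) to side x side,
# via EBImage; exact no-op when the size already matches
resize_bilinear <- function(arr, side) {
  d <- dim(arr)
  if (d[1] == side && d[2] == side) return(arr)
  eb <- EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = side, h = side, filter = "bilinear")
  aperm(EBImage::imageData(out), c(2, 1, 3))
}

#' Resize an image to the canonical square input size
#'
#' Bilinear resize to `side` x `side`; pixel values remain on the 0-255
#' scale as floats. The ground-truth pigment mask, when present, is resized
#' alongside (nearest threshold at 0.5) so oracle properties survive
#' preprocessing.
#'
#' @param img a [labeled_image()].
#' @param side target side in pixels, default 512.
#' @return a [labeled_image()] with float pixels of shape side x side x 3.
#' @export
canonicalize <- function(img, side = 512L) {
  stopifnot(inherits(img, "labeled_image"))
  out <- img
  out$pixels <- resize_bilinear(img$pixels, side)
  if (!is.null(img$pigment_mask)) {
    m <- array(img$pigment_mask + 0, c(dim(img$pigment_mask), 3L))
    out$pigment_mask <- resize_bilinear(m, side)[, , 1] > 0.5
  }
  out
}

#' Scale pixel values for network input
#'
#' `zero_one` maps 0-255 to \[0, 1\] (t/255); `sym_one` maps to \[-1, 1\]
#' (t/127.5 - 1), centering the input range on zero.
#'
#' @param t numeric array with values in \[0, 255\].
#' @param mode "zero_one" or "sym_one".
#' @return scaled array of the same shape.
#' @export
scale_pixels <- function(t, mode = c("sym_one", "zero_one")) {
  mode <- match.arg(mode)
  rng <- range(t)
  if (rng[1] < -1e-9 || rng[2] > 255 + 1e-9)
    stopf("pixel values outside [0, 255]: range [%g, %g]", rng[1], rng[2])
  if (mode == "zero_one") t / 255 else t / 127.5 - 1
}

#' Slice a scaled tensor into the five-branch input bundle
#'
#' The macro tensor is the full image; the four quadrants are its top-left,
#' top-right, bottom-left, bottom-right blocks in that fixed order
#' (row-major, origin top-left). Reassembling the quadrants reproduces the
#' macro exactly.
#'
#' @param t side x side x 3 float tensor, already pixel-scaled.
#' @param mode the scale mode that produced `t` ("sym_one" or "zero_one").
#' @return object of class `slice_bundle` with fields `macro`, `quadrants`
#'   (list of 4), `scale_mode`, `side`.
#' @export
make_slices <- function(t, mode = c("sym_one", "zero_one")) {
  mode <- match.arg(mode)
  d <- dim(t)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L || d[1] %% 2L != 0L)
    stopf("expected an even side x side x 3 tensor, got [%s]",
          paste(d, collapse = ", "))
  lo <- if (mode == "sym_one") -1 else 0
  rng <- range(t)
  if (rng[1] < lo - 1e-9 || rng[2] > 1 + 1e-9)
    stopf("tensor values outside [%g, 1]; apply scale_pixels() first", lo)
  s <- d[1]; h <- s %/% 2L
  structure(list(
    macro = t,
    quadrants = list(
      TL = t[1:h, 1:h, , drop = FALSE],
      TR = t[1:h, (h + 1L):s, , drop = FALSE],
      BL = t[(h + 1L):s, 1:h, , drop = FALSE],
      BR = t[(h + 1L):s, (h + 1L):s, , drop = FALSE]),
    scale_mode = mode, side = s), class = "slice_bundle")
}

#' Preprocess one image into a network-ready slice bundle
#'
#' Composes [crop_scale_bar()] (optional), [canonicalize()],
#' [scale_pixels()] and [make_slices()].
#'
#' @param img a [labeled_image()].
#' @param side canonical side, default 512.
#' @param scale_mode "sym_one" (default) or "zero_one".
#' @param crop_margin per-edge crop fraction; 0 disables cropping.
#' @return a `slice_bundle`.
#' @export
prep_bundle <- function(img, side = 512L, scale_mode = "sym_one",
                        crop_margin = 0) {
  if (crop_margin > 0) img <- crop_scale_bar(img, crop_margin)
  img <- canonicalize(img, side)
  make_slices(scale_pixels(img$pixels, scale_mode), scale_mode)
}

flip_pixels <- function(px, horizontal, vertical) {
  d <- dim(px)
  ri <- if (vertical) d[1]:1 else 1:d[1]
  ci <- if (horizontal) d[2]:1 else 1:d[2]
  px[ri, ci, , drop = FALSE]
}

#' Expand a list of images by flip augmentation
#'
#' Each image contributes four samples: the original, its horizontal flip,
#' its vertical flip, and both flips combined. Labels are preserved and
#' provenance ids are suffixed with the variant.
#'
#' @param imgs list of [labeled_image()].
#' @return list of length `4 * length(imgs)`.
#' @export
augment_flips <- function(imgs) {
  if (length(imgs) == 0L) stopf("augment_flips() needs a nonempty list")
  variants <- list(orig = c(FALSE, FALSE), h = c(TRUE, FALSE),
                   v = c(FALSE, TRUE), hv = c(TRUE, TRUE))
  out <- vector("list", 4L * length(imgs))
  k <- 0L
  for (im in imgs) {
    for (v in names(variants)) {
      k <- k + 1L
      fl <- variants[[v]]
      nx <- im
      if (v != "orig") {
        nx$pixels <- flip_pixels(im$pixels, fl[1], fl[2])
        if (!is.null(im$pigment_mask)) {
          m <- im$pigment_mask
          if (fl[2]) m <- m[nrow(m):1, , drop = FALSE]
          if (fl[1]) m <- m[, ncol(m):1, drop = FALSE]
          nx$pigment_mask <- m
        }
      }
      nx$source_id <- paste0(im$source_id, "::", v)
      out[[k]] <- nx
    }
  }
  out
}

#' Expand a list of images with their upscaled quadrants
#'
#' For magnification robustness, each image contributes itself plus its four
#' quadrants, each bilinearly upsampled back to the parent's size, as
#' independent samples carrying the parent's label (5x expansion).
#'
#' @param imgs list of [labeled_image()].
#' @return list of length `5 * length(imgs)`.
#' @export
divide_expand <- function(imgs) {
  if (length(imgs) == 0L) stopf("divide_expand() needs a nonempty list")
  out <- vector("list", 5L * length(imgs))
  k <- 0L
  for (im in imgs) {
    k <- k + 1L
    out[[k]] <- im
    d <- dim(im$pixels); H <- d[1]; W <- d[2]
    hh <- H %/% 2L; hw <- W %/% 2L
    qs <- list(q1 = list(1:hh, 1:hw), q2 = list(1:hh, (hw + 1L):W),
               q3 = list((hh + 1L):H, 1:hw), q4 = list((hh + 1L):H, (hw + 1L):W))
    for (qn in names(qs)) {
      k <- k + 1L
      q <- qs[[qn]]
      nx <- im
      nx$pixels <- resize_bilinear(im$pixels[q[[1]], q[[2]], , drop = FALSE], H)
      if (!is.null(im$pigment_mask)) {
        m <- array(im$pigment_mask[q[[1]], q[[2]]] + 0, c(hh, hw, 3L))
        nx$pigment_mask <- resize_bilinear(m, H)[, , 1] > 0.5
      }
      nx$source_id <- paste0(im$source_id, "::", qn)
      out[[k]] <- nx
    }
  }
  out
}

#' Split a dataset into train / validation / test
#'
#' Test images are drawn before augmentation and never augmented. The
#' training images are flip-augmented 4x, then `floor(val_frac * n_augmented)`
#' samples are held out as the validation subset. All shuffling derives from
#' `seed`, so the split is reproducible. Note that flip variants of one
#' source image may land in both train and validation; the source-level
#' train/test partition is strictly disjoint.
#'
#' @param imgs list of [labeled_image()] (or an `image_dataset`).
#' @param train_frac fraction of source images used for training, in (0, 1).
#' @param val_frac fraction of the augmented training pool held out for
#'   validation, in \[0, 1); default 0.20.
#' @param seed RNG seed, default 0.
#' @return object of class `dataset_split`: lists `train`, `val`, `test`,
#'   plus `counts` and the parameters.
#' @export
split_dataset <- function(imgs, train_frac = 2 / 3, val_frac = 0.20, seed = 0L) {
  if (inherits(imgs, "image_dataset")) imgs <- imgs$images
  n <- length(imgs)
  if (n < 2L) stopf("need at least 2 images to split")
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must lie in (0, 1)")
  if (val_frac < 0 || val_frac >= 1) stopf("val_frac must lie in [0, 1)")
  with_seed(as.integer(seed), {
    ord <- sample.int(n)
    n_train <- max(1L, as.integer(round(train_frac * n)))
    train_src <- imgs[ord[seq_len(n_train)]]
    test <- imgs[ord[(n_train + 1L):n]]
    aug <- augment_flips(train_src)
    aug <- aug[sample.int(length(aug))]
    n_val <- floor(val_frac * length(aug))
    val <- if (n_val > 0) aug[seq_len(n_val)] else list()
    train <- aug[setdiff(seq_along(aug), seq_len(n_val))]
    structure(list(train = train, val = val, test = test,
                   counts = c(source = n, train_source = n_train,
                              augmented = length(aug),
                              train = length(train), val = length(val),
                              test = length(test)),
                   train_frac = train_frac, val_frac = val_frac,
                   seed = as.integer(seed)),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>\n")
  print(x$counts)
  invisible(x)
}
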