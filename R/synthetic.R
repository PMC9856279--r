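#' Labeled microscopy-like image container
#'
#' Plain-array container for one image: `pixels` is an H x W x 3 numeric
#' array on the 0-255 scale, `label` one of [cell_classes()], plus
#' provenance metadata. Synthetic RPE images additionally carry their
#' ground-truth pigment mask and generator degree so downstream ranking and
#' heatmap properties can be checked against a known truth.
#'
#' @param pixels H x W x 3 numeric array, values in \[0, 255\].
#' @param label class label, one of [cell_classes()] (or NA).
#' @param source_id free-text provenance identifier.
#' @param has_scale_bar logical, TRUE when a scale-bar artifact is burned in.
#' @param rpe_degree generator differentiation degree (NA for non-RPE).
#' @param magnification_tag free text, e.g. "10x".
#' @param pigment_mask optional H x W logical matrix of ground-truth pigment.
#' @param scale_bar_rects list of burned-in bar rectangles (row/col ranges).
#' @return object of class `labeled_image`.
#' @export
labeled_image <- function(pixels, label = NA_character_, source_id = "img",
                          has_scale_bar = FALSE, rpe_degree = NA_real_,
                          magnification_tag = NA_character_,
                          pigment_mask = NULL, scale_bar_rects = list()) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stopf("pixels must be an H x W x 3 array, got dims [%s]",
          paste(d, collapse = ", "))
  if (d[1] < 64L || d[2] < 64L)
    stopf("image must be at least 64 x 64, got %d x %d", d[1], d[2])
  if (!is.na(label) && !label %in% cell_classes())
    stopf("unknown cell class '%s'", label)
  structure(list(pixels = pixels, label = label, source_id = source_id,
                 has_scale_bar = isTRUE(has_scale_bar),
                 rpe_degree = rpe_degree,
                 magnification_tag = magnification_tag,
                 pigment_mask = pigment_mask,
                 scale_bar_rects = scale_bar_rects),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<labeled_image> %d x %d  label=%s  id=%s%s%s\n",
              d[1], d[2], x$label, x$source_id,
              if (x$has_scale_bar) "  [scale bar]" else "",
              if (!is.na(x$rpe_degree)) sprintf("  degree=%.2f", x$rpe_degree) else ""))
  invisible(x)
}

#' Phenotype specification for the synthetic generator
#'
#' Describes one synthetic image: which cell class to emulate, the canvas
#' size, the RPE pigment coverage target, texture noise level and structure
#' count. Identical (spec, seed) pairs always yield byte-identical images.
#'
#' Default structure counts emulate what a 10-20x field of view typically
#' shows: a couple of iPSC colonies, a few tens of fibroblast streaks, a few
#' neurite-bearing somas. Counts for line-like structures scale linearly
#' with the canvas side so density looks similar at any size.
#'
#' @param cell_class one of [cell_classes()].
#' @param canvas_side canvas size in pixels (>= 64), default 512.
#' @param rpe_degree target areal fraction of pigment in \[0, 1\]
#'   (consulted only for RPE; default 0.5).
#' @param texture_noise_sd Gaussian pixel-noise standard deviation on the
#'   0-255 scale, default 8.
#' @param n_structures number of colonies/streaks/somas; default scales
#'   with canvas size (ignored for RPE, whose patch count is driven by
#'   `rpe_degree`).
#' @param seed integer RNG seed for this image.
#' @return object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(cell_class, canvas_side = 512L, rpe_degree = 0.5,
                           texture_noise_sd = 8, n_structures = NULL,
                           seed = 0L) {
  if (!is.character(cell_class) || length(cell_class) != 1L ||
      !cell_class %in% cell_classes())
    stopf("unknown cell class '%s'", paste(cell_class, collapse = ","))
  canvas_side <- as.integer(canvas_side)
  if (canvas_side < 64L) stopf("canvas_side must be >= 64, got %d", canvas_side)
  if (cell_class == "RPE" && (rpe_degree < 0 || rpe_degree > 1))
    stopf("rpe_degree must lie in [0, 1], got %g", rpe_degree)
  if (is.null(n_structures)) {
    n_structures <- switch(cell_class,
      IPSC = 2L,
      MSC  = max(8L, as.integer(round(30 * canvas_side / 512))),
      RGC  = max(2L, as.integer(round(5 * canvas_side / 512))),
      RPE  = NA_integer_)
  }
  structure(list(cell_class = cell_class, canvas_side = canvas_side,
                 rpe_degree = rpe_degree, texture_noise_sd = texture_noise_sd,
                 n_structures = n_structures, seed = as.integer(seed)),
            class = "phenotype_spec")
}

# logical mask of a rotated ellipse on an s x s grid (row = y, col = x)
ellipse_mask <- function(s, cy, cx, a, b, theta = 0) {
  yy <- matrix(seq_len(s), s, s)            # row index
  xx <- matrix(seq_len(s), s, s, byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# set of in-bounds (row, col) pixel indices tracing a polyline with the
# given half-width; returns linear indices into an s x s matrix
polyline_pixels <- function(s, pts, width = 1L) {
  if (nrow(pts) < 2L) return(integer(0))
  segs <- lapply(seq_len(nrow(pts) - 1L), function(i) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    len <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 2)))
    cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  })
  pt <- do.call(rbind, segs)
  # thicken by stamping a small neighbourhood around each sample point
  off <- expand.grid(dr = -(width - 1L):(width - 1L),
                     dc = -(width - 1L):(width - 1L))
  off <- off[abs(off$dr) + abs(off$dc) <= width - 1L, , drop = FALSE]
  r <- rep(round(pt[, 1]), each = nrow(off)) + off$dr
  c <- rep(round(pt[, 2]), each = nrow(off)) + off$dc
  ok <- r >= 1 & r <= s & c >= 1 & c <= s
  unique((c[ok] - 1L) * s + r[ok])
}

# recursive branching tree (neurite) starting at (cy, cx); returns a list of
# polyline point matrices
branch_tree <- function(s, cy, cx, angle, depth, step) {
  n_seg <- sample(3:5, 1)
  pts <- matrix(c(cy, cx), 1, 2)
  out <- list()
  for (i in seq_len(n_seg)) {
    angle <- angle + stats::rnorm(1, 0, 0.35)
    cy <- cy + sin(angle) * step
    cx <- cx + cos(angle) * step
    pts <- rbind(pts, c(cy, cx))
    if (depth > 0L && stats::runif(1) < 0.6) {
      out <- c(out, branch_tree(s, cy, cx, angle + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1),
                                depth - 1L, step * 0.8))
    }
  }
  c(list(pts), out)
}

#' Generate one synthetic cell image
#'
#' Renders the class-distinguishing phenotype on a light-gray textured
#' background: iPSC — bright compact colonies with a sharp dark boundary
#' ring; MSC — thin elongated fibroblast-like streaks; RGC — dark somas with
#' branching neurite polylines; RPE — dark-brown pigment patches whose areal
#' fraction tracks `rpe_degree`. Pixel luminance is kept strictly above the
#' pigment threshold outside pigment patches and strictly below it inside,
#' so pigment coverage is exactly countable.
#'
#' @param spec a [phenotype_spec()].
#' @return a [labeled_image()].
#' @export
generate_image <- function(spec) {
  if (!inherits(spec, "phenotype_spec")) stopf("spec must be a phenotype_spec")
  s <- spec$canvas_side
  with_seed(spec$seed, {
    bg <- 205
    R <- matrix(bg, s, s); G <- matrix(bg, s, s); B <- matrix(bg, s, s)
    pig <- matrix(FALSE, s, s)

    if (spec$cell_class == "IPSC") {
      for (k in seq_len(spec$n_structures)) {
        cy <- stats::runif(1, 0.25, 0.75) * s
        cx <- stats::runif(1, 0.25, 0.75) * s
        a <- stats::runif(1, 0.14, 0.26) * s
        b <- a * stats::runif(1, 0.75, 1)
        th <- stats::runif(1, 0, pi)
        inner <- ellipse_mask(s, cy, cx, a * 0.93, b * 0.93, th)
        outer <- ellipse_mask(s, cy, cx, a * 1.05, b * 1.05, th)
        ring <- outer & !inner
        # bright compact interior, dark high-gradient boundary
        R[inner] <- 232; G[inner] <- 230; B[inner] <- 226
        R[ring] <- 118; G[ring] <- 115; B[ring] <- 112
      }
    } else if (spec$cell_class == "MSC") {
      for (k in seq_len(spec$n_structures)) {
        y0 <- stats::runif(1, 1, s); x0 <- stats::runif(1, 1, s)
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.25, 0.55) * s
        nseg <- 6L
        pts <- matrix(0, nseg + 1L, 2L); pts[1, ] <- c(y0, x0)
        for (i in seq_len(nseg)) {
          ang <- ang + stats::rnorm(1, 0, 0.08)   # gentle curvature
          pts[i + 1L, ] <- pts[i, ] + c(sin(ang), cos(ang)) * len / nseg
        }
        idx <- polyline_pixels(s, pts, width = sample(1:2, 1))
        v <- stats::runif(1, 128, 145)
        R[idx] <- v; G[idx] <- v - 3; B[idx] <- v - 6
      }
    } else if (spec$cell_class == "RGC") {
      for (k in seq_len(spec$n_structures)) {
        cy <- stats::runif(1, 0.15, 0.85) * s
        cx <- stats::runif(1, 0.15, 0.85) * s
        soma <- ellipse_mask(s, cy, cx, 0.020 * s, 0.020 * s, 0)
        R[soma] <- 120; G[soma] <- 116; B[soma] <- 112
        n_neur <- sample(3:5, 1)
        for (j in seq_len(n_neur)) {
          trees <- branch_tree(s, cy, cx, stats::runif(1, 0, 2 * pi),
                               depth = 2L, step = 0.055 * s)
          for (pts in trees) {
            idx <- polyline_pixels(s, pts, width = 1L)
            R[idx] <- 126; G[idx] <- 122; B[idx] <- 118
          }
        }
      }
    } else { # RPE
      target <- spec$rpe_degree
      it <- 0L
      while (mean(pig) < target && it < 2000L) {
        it <- it + 1L
        cy <- stats::runif(1, 1, s); cx <- stats::runif(1, 1, s)
        a <- stats::runif(1, 0.035, 0.09) * s
        b <- a * stats::runif(1, 0.6, 1)
        m <- ellipse_mask(s, cy, cx, a, b, stats::runif(1, 0, pi))
        pig <- pig | m
        jit <- stats::rnorm(1, 0, 6)
        R[m] <- 74 + jit; G[m] <- 54 + jit; B[m] <- 38 + jit
      }
    }

    n <- s * s
    sd <- spec$texture_noise_sd
    R <- R + stats::rnorm(n, 0, sd)
    G <- G + stats::rnorm(n, 0, sd)
    B <- B + stats::rnorm(n, 0, sd)
    # clamp so pigment pixels stay strictly below the luminance threshold
    # and everything else strictly above it (noise cannot blur the count)
    clamp <- function(ch) {
      ch[pig] <- pmin(pmax(ch[pig], 0), 85)
      ch[!pig] <- pmin(pmax(ch[!pig], 95), 255)
      ch
    }
    px <- array(0, c(s, s, 3))
    px[, , 1] <- clamp(R); px[, , 2] <- clamp(G); px[, , 3] <- clamp(B)
    px <- round(px)  # uint8 domain

    labeled_image(px, label = spec$cell_class,
                  source_id = sprintf("%s_s%d", spec$cell_class, spec$seed),
                  rpe_degree = if (spec$cell_class == "RPE") spec$rpe_degree else NA_real_,
                  magnification_tag = "synthetic",
                  pigment_mask = if (spec$cell_class == "RPE") pig else NULL)
  })
}

#' Burn a scale-bar artifact into an image
#'
#' Stamps a solid near-white rectangle with text-like tick marks into the
#' chosen corner, emulating the burned-in scale bars that confound CNN
#' attention. Only pixels inside the bar rectangle are modified.
#'
#' @param img a [labeled_image()].
#' @param corner one of "bottom_right", "bottom_left", "top_right", "top_left".
#' @param bar_px integer c(width, height) of the bar in pixels.
#' @param inset distance from the image edges in pixels, default 6.
#' @return a modified copy with `has_scale_bar = TRUE`.
#' @export
stamp_scale_bar <- function(img, corner = "bottom_right", bar_px = c(80L, 12L),
                            inset = 6L) {
  stopifnot(inherits(img, "labeled_image"))
  corner <- match.arg(corner, c("bottom_right", "bottom_left",
                                "top_right", "top_left"))
  d <- dim(img$pixels); H <- d[1]; W <- d[2]
  bw <- as.integer(bar_px[1]); bh <- as.integer(bar_px[2])
  if (bw + inset > W || bh + inset > H)
    stopf("scale bar %dx%d (+inset %d) does not fit in a %dx%d image",
          bw, bh, inset, W, H)
  rows <- if (grepl("^bottom", corner)) (H - inset - bh + 1L):(H - inset)
          else (inset + 1L):(inset + bh)
  cols <- if (grepl("right$", corner)) (W - inset - bw + 1L):(W - inset)
          else (inset + 1L):(inset + bw)
  px <- img$pixels
  px[rows, cols, ] <- 245
  # text-like tick marks: short darker strokes inside the bar
  tick_cols <- cols[round(seq(2, bw - 1, length.out = 5))]
  tick_rows <- rows[seq_len(max(1L, floor(bh / 2)))]
  px[tick_rows, tick_cols, ] <- 180
  out <- img
  out$pixels <- px
  out$has_scale_bar <- TRUE
  out$scale_bar_rects <- c(img$scale_bar_rects,
                           list(list(rows = range(rows), cols = range(cols))))
  out
}

#' Generate a labeled synthetic dataset
#'
#' @param per_class_counts named integer vector, e.g.
#'   `c(IPSC = 100, MSC = 100, RGC = 100, RPE = 100)`. Missing classes count 0.
#' @param rpe_degree_sampler function(n) returning n degrees in \[0, 1\];
#'   default uniform on \[0, 1\].
#' @param seed master seed; per-image seeds are derived from it.
#' @param canvas_side canvas size passed to every [phenotype_spec()].
#' @param scale_bar_frac fraction of images stamped with a corner scale bar.
#' @param texture_noise_sd passed through to [phenotype_spec()].
#' @return object of class `image_dataset`: list with `images` (shuffled list
#'   of [labeled_image()]) and `manifest` (data.frame: id, label, rpe_degree,
#'   has_scale_bar, seed).
#' @export
generate_dataset <- function(per_class_counts,
                             rpe_degree_sampler = function(n) stats::runif(n),
                             seed = 0L, canvas_side = 512L,
                             scale_bar_frac = 0,
                             texture_noise_sd = 8) {
  cls <- cell_classes()
  if (length(per_class_counts) && is.null(names(per_class_counts)))
    stopf("per_class_counts must be named by cell class, e.g. c(IPSC = 10)")
  counts <- stats::setNames(integer(4), cls)
  counts[names(per_class_counts)] <- as.integer(per_class_counts)
  if (any(counts < 0)) stopf("per-class counts must be >= 0")
  if (!all(names(per_class_counts) %in% cls))
    stopf("unknown class in counts: %s",
          paste(setdiff(names(per_class_counts), cls), collapse = ", "))
  total <- sum(counts)
  with_seed(as.integer(seed), {
    img_seeds <- sample.int(.Machine$integer.max - 1L, total)
    labels <- rep(cls, counts)
    degrees <- rep(NA_real_, total)
    if (counts["RPE"] > 0) {
      dg <- rpe_degree_sampler(counts["RPE"])
      if (any(dg < 0 | dg > 1)) stopf("sampled rpe degrees outside [0, 1]")
      degrees[labels == "RPE"] <- dg
    }
    bars <- stats::runif(total) < scale_bar_frac
    ord <- sample.int(total)
    imgs <- vector("list", total)
    for (i in seq_len(total)) {
      sp <- phenotype_spec(labels[i], canvas_side = canvas_side,
                           rpe_degree = if (is.na(degrees[i])) 0.5 else degrees[i],
                           texture_noise_sd = texture_noise_sd,
                           seed = img_seeds[i])
      im <- generate_image(sp)
      im$source_id <- sprintf("%s_%04d", labels[i], i)
      if (bars[i]) {
        bw <- max(20L, as.integer(round(canvas_side * 80 / 512)))
        bh <- max(4L, as.integer(round(canvas_side * 12 / 512)))
        im <- stamp_scale_bar(im, "bottom_right", c(bw, bh),
                              inset = max(2L, as.integer(round(canvas_side * 6 / 512))))
      }
      imgs[[i]] <- im
    }
    imgs <- imgs[ord]
    manifest <- data.frame(
      id = vapply(imgs, function(x) x$source_id, ""),
      label = vapply(imgs, function(x) x$label, ""),
      rpe_degree = vapply(imgs, function(x) x$rpe_degree, 0),
      has_scale_bar = vapply(imgs, function(x) x$has_scale_bar, TRUE),
      seed = img_seeds[ord],
      stringsAsFactors = FALSE)
    structure(list(images = imgs, manifest = manifest, seed = as.integer(seed)),
              class = "image_dataset")
  })
}

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images (seed %d)\n",
              length(x$images), x$seed))
  print(table(x$manifest$label))
  invisible(x)
}

#' Write a dataset to disk as PNGs plus a CSV manifest
#'
#' @param ds an `image_dataset` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest with a `path` column.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "image_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    im <- ds$images[[i]]
    sub <- file.path(dir, im$label)
    dir.create(sub, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(im$source_id, ".png"))
    save_image(im, paths[i])
  }
  man <- ds$manifest
  man$path <- paths
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
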