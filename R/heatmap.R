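# Class-activation heatmaps: gradient-weighted attention maps computed at
# the merge convolution layer, used to check what the network attends to
# (and to reproduce the scale-bar confound).

#' Compute a class-activation heatmap
#'
#' Class-conditional activation mapping at the merge convolution. The
#' gradient of the target-class logit with respect to the merge-layer
#' activation maps is combined with the activations in one of two ways:
#'
#' * `"layercam"` (default): per-position ReLU-rectified gradients multiply
#'   the activations before the channel sum. This respects the
#'   position-sensitive flatten + dense head of this architecture, so
#'   class evidence tied to a specific image region (e.g. a burned-in
#'   scale bar) stays localized.
#' * `"gradcam"`: gradients are spatially averaged into one weight per
#'   channel before the weighted channel sum (the classic formulation,
#'   designed for global-average-pooling heads; at this network's coarse
#'   merge resolution it tends to spread position-specific evidence).
#'
#' The map is ReLU-rectified, normalized to \[0, 1\] and bilinearly
#' upsampled to the input's spatial size. Dropout is inactive, so the map
#' is deterministic.
#'
#' @param fit a trained `mst_fit`.
#' @param bundle a `slice_bundle` preprocessed to match the fit's config.
#' @param target_class class whose evidence is mapped; default the
#'   predicted class.
#' @param method "layercam" (default) or "gradcam".
#' @param alpha overlay blending weight in \[0, 1\], default 0.45.
#' @return object of class `mst_heatmap`: `weights` (canvas x canvas in
#'   \[0, 1\]), `overlay` (canvas x canvas x 3, 0-255), `target_class`,
#'   `probs`.
#' @export
compute_heatmap <- function(fit, bundle, target_class = NULL,
                            method = c("layercam", "gradcam"), alpha = 0.45) {
  if (!inherits(fit, "mst_fit"))
    stopf("compute_heatmap() needs a trained mst_fit")
  method <- match.arg(method)
  net <- fit$net
  fw <- net_forward(net, bundle, keep = "heat")
  classes <- fit$classes
  if (is.null(target_class)) target_class <- classes[which.max(fw$probs)]
  ci <- match(target_class, classes)
  if (is.na(ci)) stopf("unknown target class '%s'", target_class)

  # backprop the target logit to the merge activation maps
  p <- net$params
  sh <- net$shapes
  dh <- p$out_W[, ci]
  dz1 <- dh * (fw$z1 > 0)
  dv <- drop(p$fc_W %*% dz1)
  dim(dv) <- sh$post_pool
  G <- avgpool_bwd(dv, sh$merge_output[1], sh$merge_output[2])

  A <- fw$merge_act
  heat <- matrix(0, sh$merge_output[1], sh$merge_output[2])
  if (method == "layercam") {
    Gp <- G
    Gp[Gp < 0] <- 0                              # per-position rectified grads
    for (f in seq_len(dim(A)[3])) heat <- heat + Gp[, , f] * A[, , f]
  } else {
    w <- apply(G, 3L, mean)                      # one weight per channel
    for (f in seq_along(w)) heat <- heat + w[f] * A[, , f]
  }
  heat[heat < 0] <- 0
  if (max(heat) > 0) heat <- heat / max(heat)

  side <- net$cfg$canvas_side
  up <- resize_bilinear(array(heat, c(dim(heat), 3L)), side)[, , 1]
  up[up < 0] <- 0; up[up > 1] <- 1

  # recover a displayable 0-255 image from the scaled macro tensor
  img <- if (bundle$scale_mode == "sym_one") (bundle$macro + 1) * 127.5
         else bundle$macro * 255
  ramp <- grDevices::colorRamp(c("navy", "dodgerblue", "cyan", "yellow", "red"))
  hcol <- ramp(as.vector(up))
  heat_rgb <- array(hcol, c(side, side, 3L))
  overlay <- (1 - alpha) * img + alpha * heat_rgb

  structure(list(weights = up, heat_rgb = heat_rgb, input = img,
                 overlay = overlay, target_class = target_class,
                 probs = stats::setNames(fw$probs, classes)),
            class = "mst_heatmap")
}

#' @export
print.mst_heatmap <- function(x, ...) {
  cat(sprintf("<mst_heatmap> %d x %d, target %s (p = %.3f)\n",
              nrow(x$weights), ncol(x$weights), x$target_class,
              x$probs[x$target_class]))
  invisible(x)
}

#' Plot a heatmap triptych (input | heat | overlay)
#' @param x an `mst_heatmap`.
#' @param ... unused.
#' @export
plot.mst_heatmap <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  show <- function(a, main) {
    graphics::plot.new()
    graphics::plot.window(c(0, 1), c(0, 1), asp = 1)
    graphics::rasterImage(grDevices::as.raster(a / 255), 0, 0, 1, 1)
    graphics::title(main)
  }
  show(x$input, "input")
  show(x$heat_rgb, "heat")
  show(x$overlay, "overlay")
  invisible(x)
}

#' Write a heatmap triptych PNG (input | heat | overlay)
#'
#' @param hm an `mst_heatmap`.
#' @param path output PNG path.
#' @export
write_heatmap_png <- function(hm, path) {
  stopifnot(inherits(hm, "mst_heatmap"))
  s <- nrow(hm$weights)
  strip <- array(0, c(s, 3L * s + 16L, 3L))
  strip[, , ] <- 255
  strip[, 1:s, ] <- hm$input
  strip[, (s + 9L):(2L * s + 8L), ] <- hm$heat_rgb
  strip[, (2L * s + 17L):(3L * s + 16L), ] <- hm$overlay
  png::writePNG(pmin(pmax(strip / 255, 0), 1), path)
  invisible(path)
}

#' Fraction of heat mass inside a rectangle
#'
#' Utility for attention analyses, e.g. how much of the heat concentrates
#' on a burned-in scale bar relative to the bar's area fraction.
#'
#' @param hm an `mst_heatmap`.
#' @param rect list with `rows` and `cols` (min, max) in input coordinates.
#' @return named vector: heat_fraction, area_fraction, ratio.
#' @export
heat_mass_in_rect <- function(hm, rect) {
  w <- hm$weights
  total <- sum(w)
  ri <- rect$rows[1]:rect$rows[2]
  ci <- rect$cols[1]:rect$cols[2]
  inside <- sum(w[ri, ci])
  hf <- if (total > 0) inside / total else 0
  af <- length(ri) * length(ci) / length(w)
  c(heat_fraction = hf, area_fraction = af, ratio = hf / af)
}
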