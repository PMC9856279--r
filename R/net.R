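# The multi-slice tensor network: five convolutional branches (one pooled
# whole-image "macro" branch plus four quadrant branches) concatenated on
# channels, a merge convolution, dropout, average pooling, flatten and a
# dense softmax head. All forward/backward arithmetic lives here.

he_init <- function(nin, nout, fan_in) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan_in)), nin, nout)
}

branch_prefix <- function(net, i) {
  if (net$cfg$tie_branch_weights) "brS" else paste0("br", i)
}

init_params <- function(cfg, variant) {
  f <- cfg$branch_filters
  cins <- c(3L, f[1], f[2])
  shapes <- mst_shapes(cfg, variant)
  nb <- shapes$n_branches
  params <- list()
  prefixes <- if (cfg$tie_branch_weights) "brS" else paste0("br", seq_len(nb))
  for (pr in prefixes) {
    for (l in 1:3) {
      params[[paste0(pr, "_c", l, "_W")]] <-
        he_init(9L * cins[l], f[l], 9L * cins[l])
      params[[paste0(pr, "_c", l, "_b")]] <- numeric(f[l])
    }
  }
  ccat <- shapes$concat[3]
  params$merge_W <- he_init(9L * ccat, cfg$merge_filters, 9L * ccat)
  params$merge_b <- numeric(cfg$merge_filters)
  params$fc_W <- he_init(shapes$flatten, cfg$dense_width, shapes$flatten)
  params$fc_b <- numeric(cfg$dense_width)
  params$out_W <- matrix(stats::rnorm(cfg$dense_width * cfg$n_classes, 0,
                                      sqrt(1 / cfg$dense_width)),
                         cfg$dense_width, cfg$n_classes)
  params$out_b <- numeric(cfg$n_classes)
  params
}

new_mst_net <- function(cfg, variant) {
  shapes <- mst_shapes(cfg, variant)
  # build-time shape ledger: fail with a report if the config cannot
  # produce consistent shapes
  if (shapes$concat[3] != shapes$n_branches * cfg$branch_filters[3])
    stopf("shape ledger violation: concat channels %d != %d x %d",
          shapes$concat[3], shapes$n_branches, cfg$branch_filters[3])
  if (shapes$flatten != prod(shapes$post_pool))
    stopf("shape ledger violation: flatten %d != prod(%s)",
          shapes$flatten, paste(shapes$post_pool, collapse = "x"))
  params <- with_seed(cfg$seed, init_params(cfg, variant))
  structure(list(cfg = cfg, variant = variant, params = params,
                 shapes = shapes, trained = FALSE),
            class = "mst_net")
}

#' Build the multi-slice tensor network
#'
#' Five inputs: the macro tensor passes through a front 2x2 average pool so
#' all five branch stacks see (canvas/2)-sided inputs; each branch is three
#' same-padded 3x3 convolutions (ReLU) each followed by a 2x2 max pool; the
#' five branch outputs are concatenated on channels, merged by a 3x3
#' convolution, dropped out, average-pooled 2x2, flattened and passed
#' through a dense ReLU layer into a softmax over the four classes.
#'
#' @param cfg an [mst_config()].
#' @return an untrained `mst_net`.
#' @export
build_multi_slice <- function(cfg) {
  stopifnot(inherits(cfg, "mst_config"))
  new_mst_net(cfg, "multi")
}

#' Build the single-tensor baseline network
#'
#' The macro branch alone: identical branch stack and head, with the merge
#' convolution applied to the lone branch output.
#'
#' @param cfg an [mst_config()].
#' @return an untrained `mst_net`.
#' @export
build_single_tensor <- function(cfg) {
  stopifnot(inherits(cfg, "mst_config"))
  new_mst_net(cfg, "single")
}

#' Total number of trainable parameters
#' @param net an `mst_net`, `mst_fit` or `mst_extractor`.
#' @return integer parameter count.
#' @export
n_params <- function(net) {
  if (inherits(net, "mst_fit")) net <- net$net
  sum(vapply(net$params, length, 0L))
}

check_bundle <- function(net, bundle) {
  if (!inherits(bundle, "slice_bundle")) stopf("input must be a slice_bundle")
  if (bundle$side != net$cfg$canvas_side)
    stopf("bundle side %d does not match the network canvas %d",
          bundle$side, net$cfg$canvas_side)
  if (bundle$scale_mode != net$cfg$scale_mode)
    stopf("bundle scale_mode '%s' does not match the config's '%s'",
          bundle$scale_mode, net$cfg$scale_mode)
}

# forward through one branch; returns output array plus caches for backprop
branch_fwd <- function(params, pr, x, keep) {
  cache <- if (keep) list(x = x) else NULL
  a <- x
  for (l in 1:3) {
    Wm <- params[[paste0(pr, "_c", l, "_W")]]
    b <- params[[paste0(pr, "_c", l, "_b")]]
    cf <- conv_fwd(a, Wm, b)
    act <- relu(cf$pre)
    d <- dim(a)
    arr <- act
    dim(arr) <- c(d[1], d[2], length(b))
    mp <- maxpool_fwd(arr)
    if (keep) {
      cache[[paste0("col", l)]] <- cf$col
      cache[[paste0("mask", l)]] <- cf$pre > 0
      cache[[paste0("sel", l)]] <- mp$sel
      cache[[paste0("dim", l)]] <- d[1:2]
    }
    a <- mp$out
  }
  list(out = a, cache = cache)
}

branch_bwd <- function(params, pr, dout, cache, grads) {
  d3 <- dim(dout)
  da <- dout
  for (l in 3:1) {
    Wm <- params[[paste0(pr, "_c", l, "_W")]]
    dims <- cache[[paste0("dim", l)]]
    H <- dims[1]; W <- dims[2]
    darr <- maxpool_bwd(da, cache[[paste0("sel", l)]], H, W)
    dpre <- darr
    dim(dpre) <- c(H * W, length(params[[paste0(pr, "_c", l, "_b")]]))
    dpre[!cache[[paste0("mask", l)]]] <- 0
    g <- conv_bwd(dpre, cache[[paste0("col", l)]], Wm, H, W,
                  ncol(cache[[paste0("col", l)]]) %/% 9L, need_dx = l > 1L)
    wn <- paste0(pr, "_c", l, "_W"); bn <- paste0(pr, "_c", l, "_b")
    grads[[wn]] <- (grads[[wn]] %||% 0) + g$dW
    grads[[bn]] <- (grads[[bn]] %||% 0) + g$db
    if (l > 1L) da <- g$dx
  }
  grads
}

# full forward pass for one bundle.
# keep = "none" (inference), "train" (caches for backprop), "heat"
# (activations needed for class-activation maps)
net_forward <- function(net, bundle, train = FALSE, keep = "none",
                        dropout_mask = NULL) {
  check_bundle(net, bundle)
  p <- net$params
  cfg <- net$cfg
  sh <- net$shapes
  keep_cache <- keep == "train"

  macro_in <- avgpool_fwd(bundle$macro)   # front average pool
  inputs <- if (net$variant == "multi")
    c(list(macro_in), bundle$quadrants) else list(macro_in)
  nb <- length(inputs)
  stopifnot(nb == sh$n_branches)

  hm <- sh$concat[1]
  concat <- array(0, sh$concat)
  bcaches <- vector("list", nb)
  f3 <- cfg$branch_filters[3]
  for (i in seq_len(nb)) {
    bf <- branch_fwd(p, branch_prefix(net, i), inputs[[i]], keep_cache)
    stopifnot(all(dim(bf$out) == sh$branch_output))
    concat[, , ((i - 1L) * f3 + 1L):(i * f3)] <- bf$out
    bcaches[[i]] <- bf$cache
  }

  mf <- conv_fwd(concat, p$merge_W, p$merge_b)
  merge_act <- relu(mf$pre)                      # (hm*hm) x merge_filters

  if (train && cfg$dropout_rate > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- (stats::runif(length(merge_act)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
    merge_drop <- merge_act * dropout_mask
  } else {
    dropout_mask <- NULL
    merge_drop <- merge_act
  }

  marr <- merge_drop
  dim(marr) <- sh$merge_output
  pooled <- avgpool_fwd(marr)                    # (s/32, s/32, mf)
  v <- as.vector(pooled)                         # flatten
  stopifnot(length(v) == sh$flatten)

  z1 <- drop(v %*% p$fc_W) + p$fc_b
  h <- relu(z1)
  logits <- drop(h %*% p$out_W) + p$out_b
  probs <- softmax(logits)

  out <- list(probs = probs, logits = logits, flatten = v)
  if (keep_cache) {
    out$cache <- list(bcaches = bcaches, concat_col = mf$col,
                      merge_mask = mf$pre > 0, dropout_mask = dropout_mask,
                      v = v, z1 = z1, h = h)
  }
  if (keep == "heat") {
    A <- merge_act
    dim(A) <- sh$merge_output
    out$merge_act <- A
    out$z1 <- z1
  }
  out
}

# backward pass for one sample; returns the per-sample gradient list
net_backward <- function(net, fw, y_onehot) {
  p <- net$params
  sh <- net$shapes
  cfg <- net$cfg
  cache <- fw$cache
  grads <- list()

  dlogits <- fw$probs - y_onehot                 # softmax + cross-entropy
  grads$out_W <- outer(cache$h, dlogits)
  grads$out_b <- dlogits
  dh <- drop(p$out_W %*% dlogits)
  dz1 <- dh * (cache$z1 > 0)
  grads$fc_W <- outer(cache$v, dz1)
  grads$fc_b <- dz1
  dv <- drop(p$fc_W %*% dz1)

  dpooled <- dv
  dim(dpooled) <- sh$post_pool
  dmerge <- avgpool_bwd(dpooled, sh$merge_output[1], sh$merge_output[2])
  dim(dmerge) <- c(sh$merge_output[1] * sh$merge_output[2], cfg$merge_filters)
  if (!is.null(cache$dropout_mask)) dmerge <- dmerge * cache$dropout_mask
  dmerge[!cache$merge_mask] <- 0

  hm <- sh$concat[1]
  g <- conv_bwd(dmerge, cache$concat_col, p$merge_W, hm, hm, sh$concat[3])
  grads$merge_W <- g$dW
  grads$merge_b <- g$db

  f3 <- cfg$branch_filters[3]
  for (i in seq_len(sh$n_branches)) {
    dbr <- g$dx[, , ((i - 1L) * f3 + 1L):(i * f3), drop = FALSE]
    grads <- branch_bwd(p, branch_prefix(net, i), dbr, cache$bcaches[[i]], grads)
  }
  grads
}

label_index <- function(labels, classes) {
  idx <- match(as.character(labels), classes)
  if (anyNA(idx))
    stopf("unknown label(s): %s",
          paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

eval_set <- function(net, bundles, yidx) {
  n <- length(bundles)
  loss <- 0; correct <- 0L
  for (i in seq_len(n)) {
    fw <- net_forward(net, bundles[[i]])
    loss <- loss - log(max(fw$probs[yidx[i]], 1e-12))
    if (which.max(fw$probs) == yidx[i]) correct <- correct + 1L
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the multi-slice (or single-tensor) network
#'
#' Minibatch Adam on categorical cross-entropy. The sample order is
#' reshuffled each epoch, deterministically from the config seed, so two
#' runs with identical inputs and seed produce identical weights and
#' history.
#'
#' @param net an `mst_net` from [build_multi_slice()] or
#'   [build_single_tensor()].
#' @param bundles list of `slice_bundle` training inputs.
#' @param labels training labels (character/factor over [cell_classes()]).
#' @param val_bundles,val_labels optional validation set, evaluated after
#'   each epoch.
#' @param epochs,batch_size,learning_rate override the config values.
#' @param verbose print one line per epoch.
#' @return an `mst_fit`: the trained network plus a per-epoch `history`
#'   data.frame (loss, accuracy, val_loss, val_accuracy).
#' @export
mst_train <- function(net, bundles, labels, val_bundles = NULL,
                      val_labels = NULL, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, verbose = FALSE) {
  stopifnot(inherits(net, "mst_net"))
  if (length(bundles) == 0L) stopf("empty training set")
  if (length(bundles) != length(labels))
    stopf("bundles and labels lengths differ")
  cfg <- net$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  classes <- cell_classes()[seq_len(cfg$n_classes)]
  yidx <- label_index(labels, classes)
  vidx <- if (!is.null(val_bundles)) label_index(val_labels, classes)
  n <- length(bundles)

  params <- net$params
  st <- adam_init(params)
  hist <- vector("list", epochs)

  with_seed(cfg$seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0L
      for (b0 in seq.int(1L, n, by = batch_size)) {
        bidx <- ord[b0:min(b0 + batch_size - 1L, n)]
        acc_grads <- NULL
        net$params <- params
        for (i in bidx) {
          fw <- net_forward(net, bundles[[i]], train = TRUE, keep = "train")
          if (any(!is.finite(fw$logits)))
            stopf("training diverged: non-finite logits at epoch %d (lr %g); try a lower learning rate", ep, lr)
          li <- -log(max(fw$probs[yidx[i]], 1e-12))
          ep_loss <- ep_loss + li
          if (which.max(fw$probs) == yidx[i]) ep_correct <- ep_correct + 1L
          y <- numeric(cfg$n_classes); y[yidx[i]] <- 1
          g <- net_backward(net, fw, y)
          acc_grads <- if (is.null(acc_grads)) g
            else { for (nm in names(g)) acc_grads[[nm]] <- acc_grads[[nm]] + g[[nm]]; acc_grads }
        }
        nb <- length(bidx)
        for (nm in names(acc_grads)) acc_grads[[nm]] <- acc_grads[[nm]] / nb
        params <- adam_step(params, acc_grads, st, lr)
      }
      if (!is.finite(ep_loss))
        stopf("training diverged: non-finite loss at epoch %d (lr %g); try a lower learning rate", ep, lr)
      net$params <- params
      row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
                        val_loss = NA_real_, val_accuracy = NA_real_)
      if (!is.null(val_bundles) && length(val_bundles) > 0) {
        ev <- eval_set(net, val_bundles, vidx)
        row$val_loss <- ev["loss"]; row$val_accuracy <- ev["acc"]
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %d/%d  loss %.4f  acc %.3f%s", ep, epochs,
                        row$loss, row$accuracy,
                        if (!is.na(row$val_accuracy))
                          sprintf("  val_acc %.3f", row$val_accuracy) else ""))
    }
  })
  net$params <- params
  net$trained <- TRUE
  structure(list(net = net, cfg = cfg,
                 history = do.call(rbind, hist),
                 classes = classes),
            class = "mst_fit")
}

#' @export
print.mst_net <- function(x, ...) {
  cat(sprintf("<mst_net> %s-tensor, canvas %d, %s params%s\n", x$variant,
              x$cfg$canvas_side, format(n_params(x), big.mark = ","),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' @export
print.mst_fit <- function(x, ...) {
  h <- x$history
  last <- h[nrow(h), ]
  cat(sprintf("<mst_fit> %s-tensor, %d epochs, final loss %.4f, accuracy %.3f%s\n",
              x$net$variant, nrow(h), last$loss, last$accuracy,
              if (!is.na(last$val_accuracy))
                sprintf(", val accuracy %.3f", last$val_accuracy) else ""))
  invisible(x)
}

#' @export
summary.mst_fit <- function(object, ...) {
  cat(sprintf("Multi-slice tensor CNN fit (%s variant)\n", object$net$variant))
  print(object$cfg)
  cat(sprintf("  %s trainable parameters\n",
              format(n_params(object), big.mark = ",")))
  cat("Training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Plot training curves
#' @param x an `mst_fit`.
#' @param ... unused.
#' @export
plot.mst_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", main = "Model accuracy")
  if (!all(is.na(h$val_accuracy)))
    graphics::lines(h$epoch, h$val_accuracy, type = "b", col = 2)
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "Model loss")
  if (!all(is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, type = "b", col = 2)
  invisible(x)
}

predict_worker <- function(net, newdata, type, classes) {
  single <- inherits(newdata, "slice_bundle")
  bundles <- if (single) list(newdata) else newdata
  res <- lapply(bundles, function(b) net_forward(net, b))
  if (type == "prob") {
    out <- do.call(rbind, lapply(res, `[[`, "probs"))
    colnames(out) <- classes
  } else if (type == "feature") {
    out <- do.call(rbind, lapply(res, `[[`, "flatten"))
  } else {
    out <- classes[vapply(res, function(r) which.max(r$probs), 0L)]
  }
  if (single && type == "class") out[[1]] else out
}

#' Predict from a trained multi-slice fit
#'
#' Dropout is inactive at inference, so repeated predictions on the same
#' input are identical.
#'
#' @param object an `mst_fit`.
#' @param newdata one `slice_bundle` or a list of them.
#' @param type "class" (default), "prob" (softmax matrix, columns in the
#'   fixed class order), or "feature" (flatten-layer activations).
#' @param ... unused.
#' @export
predict.mst_fit <- function(object, newdata,
                            type = c("class", "prob", "feature"), ...) {
  type <- match.arg(type)
  predict_worker(object$net, newdata, type, object$classes)
}

#' @rdname predict.mst_fit
#' @export
predict.mst_net <- function(object, newdata,
                            type = c("class", "prob", "feature"), ...) {
  type <- match.arg(type)
  predict_worker(object, newdata, type,
                 cell_classes()[seq_len(object$cfg$n_classes)])
}

#' Calibrate a trained network into a fixed feature extractor
#'
#' Discards the dense and softmax layers, leaving the network truncated at
#' the flatten layer: the extractor maps a `slice_bundle` to the
#' flatten-layer activation vector ((canvas/32)^2 x merge filters
#' dimensions; 32,768 at the default configuration). The serialized
#' extractor is strictly smaller than the full fit.
#'
#' @param fit a trained `mst_fit`.
#' @return an `mst_extractor`.
#' @export
calibrate <- function(fit) {
  if (!inherits(fit, "mst_fit")) stopf("calibrate() needs a trained mst_fit")
  net <- fit$net
  net$params$fc_W <- NULL; net$params$fc_b <- NULL
  net$params$out_W <- NULL; net$params$out_b <- NULL
  structure(list(net = net, cfg = fit$cfg, truncated_at = "flatten",
                 n_features = net$shapes$flatten),
            class = "mst_extractor")
}

#' @export
print.mst_extractor <- function(x, ...) {
  cat(sprintf("<mst_extractor> %s-tensor truncated at flatten; %d features\n",
              x$net$variant, x$n_features))
  invisible(x)
}

#' Extract flatten-layer features
#'
#' @param object an `mst_extractor` from [calibrate()].
#' @param newdata one `slice_bundle` or a list of them.
#' @param ... unused.
#' @return numeric matrix (samples x features) or a vector for one bundle.
#' @export
predict.mst_extractor <- function(object, newdata, ...) {
  net <- object$net
  single <- inherits(newdata, "slice_bundle")
  bundles <- if (single) list(newdata) else newdata
  # head weights are gone; run the shared forward path up to the flatten
  feats <- t(vapply(bundles, function(b) forward_flatten(net, b),
                    numeric(object$n_features)))
  if (single) drop(feats) else feats
}

#' Measure intermediate tensor shapes on a real forward pass
#'
#' Runs one input through the network and records the actual dimensions of
#' every intermediate tensor (branch inputs and outputs, channel
#' concatenation, merge output, post-pool tensor, flatten vector). This is
#' the runtime counterpart of the build-time shape ledger.
#'
#' @param net an `mst_net` or `mst_fit`.
#' @param bundle a `slice_bundle` matching the config.
#' @return named list of integer dimension vectors.
#' @export
shape_trace <- function(net, bundle) {
  if (inherits(net, "mst_fit")) net <- net$net
  check_bundle(net, bundle)
  p <- net$params
  sh <- net$shapes
  macro_in <- avgpool_fwd(bundle$macro)
  inputs <- if (net$variant == "multi")
    c(list(macro_in), bundle$quadrants) else list(macro_in)
  f3 <- net$cfg$branch_filters[3]
  outs <- lapply(seq_along(inputs), function(i)
    branch_fwd(p, branch_prefix(net, i), inputs[[i]], keep = FALSE)$out)
  concat <- array(0, c(dim(outs[[1]])[1:2], length(outs) * f3))
  for (i in seq_along(outs))
    concat[, , ((i - 1L) * f3 + 1L):(i * f3)] <- outs[[i]]
  mf <- conv_fwd(concat, p$merge_W, p$merge_b)
  m <- relu(mf$pre)
  dim(m) <- c(dim(concat)[1:2], ncol(mf$pre))
  pooled <- avgpool_fwd(m)
  list(branch_input = dim(inputs[[1]]),
       branch_output = dim(outs[[1]]),
       concat = dim(concat),
       merge_output = dim(m),
       post_pool = dim(pooled),
       flatten = length(as.vector(pooled)))
}

# forward up to (and including) the flatten layer only
forward_flatten <- function(net, bundle) {
  check_bundle(net, bundle)
  p <- net$params
  sh <- net$shapes
  macro_in <- avgpool_fwd(bundle$macro)
  inputs <- if (net$variant == "multi")
    c(list(macro_in), bundle$quadrants) else list(macro_in)
  f3 <- net$cfg$branch_filters[3]
  concat <- array(0, sh$concat)
  for (i in seq_along(inputs)) {
    bf <- branch_fwd(p, branch_prefix(net, i), inputs[[i]], keep = FALSE)
    concat[, , ((i - 1L) * f3 + 1L):(i * f3)] <- bf$out
  }
  mf <- conv_fwd(concat, p$merge_W, p$merge_b)
  m <- relu(mf$pre)
  dim(m) <- sh$merge_output
  as.vector(avgpool_fwd(m))
}
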