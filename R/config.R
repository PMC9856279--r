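#' Model configuration for the multi-slice tensor CNN
#'
#' Collects every architecture and training hyperparameter. The defaults
#' reproduce the reference architecture: 512 canvas, branch filters
#' 32/64/128 with 3x3 kernels and 2x2 max pooling, a 2x2 average pool in
#' front of the macro branch, a 128-filter merge convolution over the
#' channel-concatenated branch outputs, 50% dropout, a 2x2 average pool,
#' a 128-unit dense layer and a 4-way softmax; 19 epochs at batch size 8,
#' Adam at learning rate 1e-3, inputs scaled to \[-1, 1\], seed 0.
#'
#' Derived shape invariants (asserted at build time and on every forward
#' pass): concatenated channels = 5 x last branch filter count (640 at
#' default), flatten length = (canvas/32)^2 x merge filters (32,768 at
#' default).
#'
#' @param canvas_side input image side; must be a multiple of 32, >= 64.
#' @param branch_filters integer vector of 3 conv filter counts per branch.
#' @param kernel convolution kernel side; the architecture uses 3.
#' @param merge_filters filters in the merge convolution.
#' @param dense_width width of the hidden dense layer.
#' @param n_classes number of output classes.
#' @param dropout_rate dropout probability after the merge convolution.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param scale_mode pixel scaling the network expects ("sym_one"/"zero_one").
#' @param seed seed for weight initialization, shuffling and dropout.
#' @param tie_branch_weights if TRUE the five branches share one weight set
#'   (the alternative reading of "shared by all cut images"); default FALSE
#'   (identical topology, independent weights).
#' @return object of class `mst_config`.
#' @export
mst_config <- function(canvas_side = 512L,
                       branch_filters = c(32L, 64L, 128L),
                       kernel = 3L,
                       merge_filters = 128L,
                       dense_width = 128L,
                       n_classes = 4L,
                       dropout_rate = 0.5,
                       epochs = 19L,
                       batch_size = 8L,
                       learning_rate = 1e-3,
                       scale_mode = c("sym_one", "zero_one"),
                       seed = 0L,
                       tie_branch_weights = FALSE) {
  scale_mode <- match.arg(scale_mode)
  canvas_side <- as.integer(canvas_side)
  branch_filters <- as.integer(branch_filters)
  if (canvas_side < 64L || canvas_side %% 32L != 0L)
    stopf("canvas_side must be a multiple of 32 and >= 64 (three 2x2 max pools, one front and one rear average pool); got %d", canvas_side)
  if (length(branch_filters) != 3L || any(branch_filters < 1L))
    stopf("branch_filters must be 3 positive filter counts")
  if (kernel != 3L)
    stopf("only 3x3 kernels are supported (the architecture's kernel size)")
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  cfg <- structure(list(
    canvas_side = canvas_side, branch_input_side = canvas_side %/% 2L,
    branch_filters = branch_filters, kernel = 3L,
    merge_filters = as.integer(merge_filters),
    dense_width = as.integer(dense_width),
    n_classes = as.integer(n_classes),
    dropout_rate = dropout_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    scale_mode = scale_mode, seed = as.integer(seed),
    tie_branch_weights = isTRUE(tie_branch_weights)),
    class = "mst_config")
  cfg
}

# expected intermediate shapes, the build-time "shape ledger"
mst_shapes <- function(cfg, variant = c("multi", "single")) {
  variant <- match.arg(variant)
  s <- cfg$canvas_side; q <- s %/% 2L
  f <- cfg$branch_filters
  nb <- if (variant == "multi") 5L else 1L
  list(
    branch_input = c(q, q, 3L),
    branch_output = c(s %/% 16L, s %/% 16L, f[3]),
    concat = c(s %/% 16L, s %/% 16L, nb * f[3]),
    merge_output = c(s %/% 16L, s %/% 16L, cfg$merge_filters),
    post_pool = c(s %/% 32L, s %/% 32L, cfg$merge_filters),
    flatten = (s %/% 32L) * (s %/% 32L) * cfg$merge_filters,
    n_branches = nb)
}

#' @export
print.mst_config <- function(x, ...) {
  cat("<mst_config>\n")
  cat(sprintf("  canvas %dx%dx3, branch input %dx%dx3\n",
              x$canvas_side, x$canvas_side, x$branch_input_side, x$branch_input_side))
  cat(sprintf("  branch filters %s (3x3 conv + 2x2 max pool), merge %d, dense %d, classes %d\n",
              paste(x$branch_filters, collapse = "/"), x$merge_filters,
              x$dense_width, x$n_classes))
  cat(sprintf("  dropout %.2f, epochs %d, batch %d, lr %g, scale %s, seed %d%s\n",
              x$dropout_rate, x$epochs, x$batch_size, x$learning_rate,
              x$scale_mode, x$seed,
              if (x$tie_branch_weights) ", tied branches" else ""))
  invisible(x)
}
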