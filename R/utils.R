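#' Fixed class order for iPSC-derived cell types
#'
#' All label vectors, one-hot encodings, confusion matrices and softmax
#' outputs in the package use this order: iPSC colonies, iPSC-derived
#' mesenchymal stem cells, retinal ganglion cells, retinal pigment
#' epithelium.
#'
#' @return Character vector of the four class names.
#' @export
cell_classes <- function() c("IPSC", "MSC", "RGC", "RPE")

# Luminance threshold (0-255) below which a pixel counts as RPE pigment.
# Fixed so that pigment coverage is a crisp, countable image property.
PIGMENT_LUM_THRESHOLD <- 90

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rec. 601 luma of an RGB pixel array
#'
#' @param pixels H x W x 3 numeric array on the 0-255 scale.
#' @return H x W matrix of luminance values (0-255).
#' @export
luminance <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Fraction of pigment pixels in an image
#'
#' Counts pixels whose luminance falls below the fixed pigment threshold
#' (90/255), the package's operational definition of dark-brown RPE
#' pigmentation.
#'
#' @param x a `labeled_image` or an H x W x 3 array on the 0-255 scale.
#' @param threshold luminance cutoff, default 90.
#' @return scalar fraction in \[0, 1\].
#' @export
pigment_fraction <- function(x, threshold = PIGMENT_LUM_THRESHOLD) {
  px <- if (inherits(x, "labeled_image")) x$pixels else x
  mean(luminance(px) < threshold)
}

# Round half away from zero (base round() is half-even); used for the
# percentages printed in evaluation reports.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so generators and training are pure functions of their
# seed without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# md5 of an R object via its canonical serialization (version 3, no
# ASCII), used to fingerprint configs in pipeline artifact logs.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3)
  close(con)
  unname(tools::md5sum(f))
}

# serialized size in bytes (used to check that a calibrated extractor is
# strictly smaller than the full fit it came from)
serialized_size <- function(x) length(serialize(x, NULL, version = 3))
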