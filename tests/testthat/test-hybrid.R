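# Hybrid head: max-abs scaling, PCA against a brute-force eigendecomposition
# oracle, SVM classification contracts, the LDA variant, and the
# confusion-matrix report.

make_clusters <- function(n_per = 20, p = 50, sep = 10, seed = 1) {
  with_seed_local(seed, {
    centers <- matrix(rnorm(4 * p), 4, p)
    centers <- centers / sqrt(rowSums(centers^2)) * sep
    X <- do.call(rbind, lapply(1:4, function(k)
      sweep(matrix(rnorm(n_per * p, 0, 1), n_per, p), 2, centers[k, ], "+")))
    list(x = X, y = rep(cell_classes(), each = n_per))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

test_that("PCA projection agrees with a brute-force eigendecomposition", {
  with_seed_local(42, {
    X <- matrix(rnorm(50 * 64), 50, 64)
    head <- fit_head(X, rep(cell_classes(), length.out = 50), k = 10)

    # independent oracle: eigenvectors of the covariance of the max-abs
    # scaled matrix, computed without any code shared with project()
    sf <- apply(abs(X), 2, max); sf[sf == 0] <- 1
    Xs <- sweep(X, 2, sf, "/")
    mu <- colMeans(Xs)
    C <- stats::cov(Xs)
    ev <- eigen(C, symmetric = TRUE)
    Z_oracle <- sweep(Xs, 2, mu) %*% ev$vectors[, 1:10]

    Z <- project(head, X)
    for (j in 1:10) {
      sgn <- sign(sum(Z[, j] * Z_oracle[, j]))
      expect_lt(max(abs(Z[, j] - sgn * Z_oracle[, j])), 1e-8)
    }
    # component rows orthonormal
    expect_lt(max(abs(crossprod(head$components) - diag(10))), 1e-10)
    # axes ordered by decreasing explained variance
    expect_true(all(diff(head$sdev) <= 1e-12))
  })
})

test_that("low intrinsic dimension is recovered in the leading axes", {
  with_seed_local(7, {
    n <- 60; p <- 32768
    latent <- matrix(rnorm(n * 3), n, 3)
    embed <- matrix(rnorm(3 * p), 3, p)
    X <- latent %*% embed + matrix(rnorm(n * p, 0, 1e-3), n, p)
    head <- suppressWarnings(
      fit_head(X, rep(cell_classes(), length.out = n), k = 20))
    varfrac <- sum(head$sdev[1:3]^2) / sum(head$sdev^2)
    expect_gte(varfrac, 0.99)

    # round trip: reconstruction from 3 coordinates is at the noise floor
    # (measured in raw feature units, where the noise sd is uniformly 1e-3)
    Z <- project(head, X)
    sf <- head$scale_factors
    recon <- sweep(Z[, 1:3] %*% t(head$components[, 1:3]), 2, head$center, "+")
    Xs <- sweep(X, 2, sf, "/")
    expect_lt(max(abs(sweep(recon - Xs, 2, sf, "*"))), 1e-2)
  })
})

test_that("well-separated clusters are classified perfectly", {
  cl <- make_clusters(n_per = 25, seed = 3)
  train <- c(outer(1:15, (0:3) * 25, `+`))
  test <- setdiff(seq_len(100), train)
  head <- suppressWarnings(fit_head(cl$x[train, ], cl$y[train], k = 20))

  expect_identical(classify(head, cl$x[train, ]), cl$y[train])  # 100% train
  expect_identical(classify(head, cl$x[test, ]), cl$y[test])    # 0 errors
  # duplicate of a training point keeps its training label
  expect_identical(classify(head, cl$x[1, ]), cl$y[1])
})

test_that("rank bound caps k with a warning", {
  cl <- make_clusters(n_per = 8, p = 40, seed = 5)
  expect_warning(h <- fit_head(cl$x, cl$y, k = 512), "rank")
  expect_identical(h$k, 32L)            # min(512, 32 samples, 40 features)
})

test_that("projection is centered, contractive and domain-checked", {
  cl <- make_clusters(n_per = 10, p = 30, seed = 6)
  head <- suppressWarnings(fit_head(cl$x, cl$y, k = 16))

  # the training mean-feature projects to (approximately) the origin
  sf <- head$scale_factors
  mean_raw <- colMeans(sweep(cl$x, 2, sf, "/")) * sf
  z0 <- project(head, mean_raw)
  expect_lt(sqrt(sum(z0^2)) / sqrt(sum(head$center^2)), 1e-6)

  # orthonormal projection never lengthens a vector
  f <- cl$x[5, ]
  z <- project(head, f)
  resid <- f / sf - head$center
  expect_lte(sqrt(sum(z^2)), sqrt(sum(resid^2)) + 1e-12)

  # already-scaled input is rejected by the domain check
  scaled <- sweep(cl$x, 2, sf, "/")
  expect_error(project(head, scaled[1, ]), "already scaled")
  expect_error(project(head, cl$x[1, 1:10]), "length")
})

test_that("the LDA variant caps the projection at n_classes - 1", {
  cl <- make_clusters(n_per = 15, p = 20, seed = 8)
  h <- fit_head(cl$x, cl$y, k = 512, projector = "lda")
  expect_lte(h$k, 3L)
  expect_identical(classify(h, cl$x), cl$y)
})

test_that("degenerate inputs are rejected with informative errors", {
  cl <- make_clusters(n_per = 5, p = 10, seed = 9)
  expect_error(fit_head(cl$x, cl$y, k = 0), "positive")
  expect_error(fit_head(cl$x[1:5, ], cl$y[1:5]), "2 classes")
  expect_error(fit_head(cl$x[c(1:5, 6), ], cl$y[c(1:5, 6)]), ">= 2 samples")
})

test_that("a fitted head survives serialization bit-identically", {
  cl <- make_clusters(n_per = 10, p = 25, seed = 10)
  head <- suppressWarnings(fit_head(cl$x, cl$y, k = 8))
  f <- tempfile(fileext = ".rds")
  saveRDS(head, f)
  head2 <- readRDS(f)
  expect_identical(classify(head2, cl$x), classify(head, cl$x))
  expect_identical(project(head2, cl$x), project(head, cl$x))
})

test_that("evaluation metrics follow the standard definitions", {
  # all-correct toy input: diagonal matrix, every metric 100
  y <- rep(cell_classes(), each = 3)
  r <- evaluate(y, y)
  expect_identical(unname(diag(r$confusion)), rep(3L, 4))
  expect_identical(r$accuracy, 100)
  expect_identical(unname(r$f_score), rep(100, 4))

  # row sums equal per-class truth counts; accuracy = trace/total
  pred <- c("IPSC", "MSC", "MSC", "RGC", "RPE", "RPE", "IPSC", "RGC")
  truth <- c("IPSC", "IPSC", "MSC", "RGC", "RGC", "RPE", "RPE", "RGC")
  r2 <- evaluate(pred, truth)
  expect_equal(unname(rowSums(r2$confusion)),
               as.vector(table(factor(truth, cell_classes()))))
  expect_equal(r2$full$accuracy, sum(diag(r2$confusion)) / 8)

  # invariant under simultaneous permutation of (pred, truth) pairs
  perm <- c(5, 3, 8, 1, 7, 2, 4, 6)
  r3 <- evaluate(pred[perm], truth[perm])
  expect_identical(r2$confusion, r3$confusion)

  expect_error(evaluate(pred, truth[1:3]), "equal length")
  expect_error(evaluate(c(pred, "GLIA"), c(truth, "RPE")), "unknown label")
})
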