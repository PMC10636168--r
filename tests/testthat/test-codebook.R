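make_blobs <- function(n, centers, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n * ncol(centers), mean = rep(centers[i, ], each = n), sd = sd),
             n, ncol(centers))
    }))
  })
}

test_that("V=1 codebook centroids are the class means", {
  X <- rbind(make_blobs(20, rbind(c(0, 0), c(4, 4)), seed = 2),
             make_blobs(20, rbind(c(-3, 1)), seed = 3))
  y <- rep(c("bleached", "unbleached"), c(40, 20))
  cb <- build_codebook(X, y, V = 1, seed = 5)
  # map centroids back to raw feature space through the stored scaler
  raw <- sweep(sweep(cb$centroids, 2, cb$scaler$scale, "*"), 2, cb$scaler$center, "+")
  expect_equal(raw[1, ], colMeans(X[1:40, ]), tolerance = 1e-10)
  expect_equal(raw[2, ], colMeans(X[41:60, ]), tolerance = 1e-10)
  expect_equal(cb$centroid_class, c("bleached", "unbleached"))
})

test_that("well-separated blobs are recovered and match stats::kmeans", {
  centers_b <- rbind(c(0, 0), c(10, 0))
  centers_u <- rbind(c(0, 8), c(10, 8))
  X <- rbind(make_blobs(25, centers_b, seed = 4), make_blobs(25, centers_u, seed = 5))
  y <- rep(c("bleached", "unbleached"), each = 50)
  cb <- build_codebook(X, y, V = 2, seed = 9)
  Xs <- coralbof:::apply_scaler(X, cb$scaler)
  # independent oracle: base R Lloyd's on the same standardized class data
  for (cls in c(1, 2)) {
    rows <- if (cls == 1) 1:50 else 51:100
    km <- withr::with_seed(1,
      stats::kmeans(Xs[rows, ], centers = 2, nstart = 10, algorithm = "Lloyd"))
    ours <- cb$centroids[(cls - 1) * 2 + 1:2, , drop = FALSE]
    theirs <- km$centers
    reorder <- apply(coralbof:::dist2(ours, theirs), 1, which.min)
    expect_equal(sort(reorder), 1:2)
    expect_equal(unname(ours), unname(theirs[reorder, , drop = FALSE]),
                 tolerance = 1e-6)
  }
})

test_that("the Lloyd objective trace is non-increasing and centroids are assignment means", {
  X <- make_blobs(40, rbind(c(0, 0, 0), c(2, 2, 2), c(-2, 1, 0)), sd = 0.8, seed = 7)
  y <- rep(c("bleached", "unbleached"), 60)
  cb <- build_codebook(X, y, V = 3, seed = 11)
  for (tr in cb$trace) {
    expect_true(all(diff(tr) <= 1e-9 * max(tr)))
  }
  # stored assignments reproduce the centroids
  Xs <- coralbof:::apply_scaler(X, cb$scaler)
  a <- cb$assignments$bleached
  Xb <- Xs[y == "bleached", ]
  for (j in unique(a)) {
    expect_equal(unname(cb$centroids[j, ]), unname(colMeans(Xb[a == j, , drop = FALSE])),
                 tolerance = 1e-8)
  }
})

test_that("codebook fits are deterministic in the seed", {
  X <- make_blobs(30, rbind(c(0, 0), c(3, 1)), seed = 8)
  y <- rep(c("bleached", "unbleached"), 30)
  cb1 <- build_codebook(X, y, V = 2, seed = 21)
  cb2 <- build_codebook(X, y, V = 2, seed = 21)
  expect_identical(cb1$centroids, cb2$centroids)
  expect_identical(cb1$objective, cb2$objective)
})

test_that("invalid vocabulary requests are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rep(c("bleached", "unbleached"), 5)
  expect_error(build_codebook(X, y, V = 0), "V must be >= 1")
  expect_error(build_codebook(X, y, V = 6), "exceeds")
  expect_error(build_codebook(X, rep("bleached", 10), V = 2), "both classes")
})

test_that("threshold encoding reproduces the hand-worked two-centroid examples", {
  cb <- codebook(rbind(c(0, 0), c(10, 10)))
  # feature at the first centroid: d2 = (0, 200), eta = 100
  e_all <- encode_image(matrix(c(0, 0), 1), cb, mode = "all_below_threshold")
  e_near <- encode_image(matrix(c(0, 0), 1), cb, mode = "nearest_only")
  expect_equal(e_all$F, c(1L, 0L))
  expect_equal(e_near$F, c(1L, 0L))
  # equidistant feature: d2 = (50, 50), eta = 50, both below; tie -> lowest index
  e_all <- encode_image(matrix(c(5, 5), 1), cb, mode = "all_below_threshold")
  e_near <- encode_image(matrix(c(5, 5), 1), cb, mode = "nearest_only")
  expect_equal(e_all$F, c(1L, 1L))
  expect_equal(e_near$F, c(1L, 0L))
  # N identical features on a centroid
  X <- matrix(rep(c(0, 0), each = 7), 7)
  for (m in c("all_below_threshold", "nearest_only")) {
    expect_equal(encode_image(X, cb, mode = m)$F, c(7L, 0L))
  }
})

test_that("encoding matches the naive double-loop oracle on random instances", {
  for (seed in 1:40) {
    dims <- withr::with_seed(seed, c(sample(1:50, 1), sample(1:8, 1), sample(2:6, 1)))
    X <- withr::with_seed(seed + 1000, matrix(stats::rnorm(dims[1] * dims[2]), dims[1]))
    C <- withr::with_seed(seed + 2000, matrix(stats::rnorm(dims[3] * dims[2]), dims[3]))
    cb <- codebook(C)
    for (m in c("all_below_threshold", "nearest_only")) {
      got <- encode_image(X, cb, mode = m)
      expect_identical(got$F, as.integer(naive_encode(X, C, m)))
      if (m == "nearest_only") expect_equal(sum(got$F), nrow(X))
      if (m == "all_below_threshold") {
        expect_gte(sum(got$F), nrow(X))
        expect_lte(sum(got$F), nrow(X) * nrow(C))
      }
    }
  }
})

test_that("encoding is invariant to feature order and to joint rescaling", {
  X <- withr::with_seed(3, matrix(stats::rnorm(60), 15, 4))
  C <- withr::with_seed(4, matrix(stats::rnorm(16), 4, 4))
  for (m in c("all_below_threshold", "nearest_only")) {
    base <- encode_image(X, codebook(C), mode = m)$F
    perm <- withr::with_seed(5, X[sample(15), ])
    expect_identical(encode_image(perm, codebook(C), mode = m)$F, base)
    # doubling features and centroids scales every d2 and eta by 4: F unchanged
    expect_identical(encode_image(2 * X, codebook(2 * C), mode = m)$F, base)
  }
})

test_that("encoding rejects empty and mismatched inputs", {
  cb <- codebook(matrix(0, 2, 3))
  expect_error(encode_image(matrix(0, 0, 3), cb), "no patch features")
  expect_error(encode_image(matrix(0, 2, 4), cb), "does not match")
})

test_that("encode_dataset maps the pipeline over a manifest deterministically", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 2, canvas = 64, seed = 12)
  be <- deep_backend("stub", dim = 16, input_size = 12)
  ct <- color_texture_params(8, 2)
  feats <- lapply(seq_len(4), function(i) {
    img <- load_and_canonicalize(man$entries$path[i], canvas = 64)
    image_features(img, 32, be, ct)
  })
  labels <- man$entries$label
  cb <- build_codebook(do.call(rbind, feats),
                       rep(labels, vapply(feats, nrow, integer(1))), V = 2, seed = 6)
  enc <- encode_dataset(man, cb, patch_size = 32, backend = be, ct = ct, canvas = 64)
  expect_length(enc, 4)
  for (e in enc) expect_length(e$F, 4)
  expect_equal(vapply(enc, `[[`, character(1), "image_id"),
               sub("\\.png$", "", basename(man$entries$path)))
  # per-image independence + determinism: re-encoding reproduces bit-identically
  enc2 <- encode_dataset(man, cb, patch_size = 32, backend = be, ct = ct, canvas = 64)
  expect_identical(lapply(enc, `[[`, "F"), lapply(enc2, `[[`, "F"))
  for (i in seq_len(4)) {
    expect_identical(enc[[i]]$F, encode_image(feats[[i]], cb)$F)
  }
})
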