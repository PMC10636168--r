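#' Build the class-wise visual vocabulary by k-means
#'
#' Fits a per-dimension standardizer on the training-fold raw features,
#' then runs Lloyd's k-means (k-means++ seeding) separately on the
#' bleached-class and unbleached-class patch features, yielding `V`
#' centroids per class stacked bleached-first — the `2V`-word visual
#' vocabulary. The clustering objective is the summed within-cluster
#' squared Euclidean distance.
#'
#' @param features Numeric matrix of raw patch features (rows = patches).
#' @param labels Class label per row (`bleached` / `unbleached`).
#' @param V Clusters per class (>= 1, and at most the per-class feature
#'   count).
#' @param seed Integer seed; the fit is fully reproducible from it.
#' @param max_iter Lloyd iteration cap (default 300).
#' @return A `coral_codebook`: `centroids` (`2V x d`, standardized space),
#'   `centroid_class`, `V`, `m = 2V`, `d`, the fitted `scaler`, final
#'   `objective`, per-class objective `trace`s (one value per Lloyd
#'   iteration, non-increasing), and the final training `assignments`.
#' @export
build_codebook <- function(features, labels, V, seed = 1L, max_iter = 300L) {
  features <- as.matrix(features)
  V <- as.integer(V)
  if (is.na(V) || V < 1) stop("vocabulary size V must be >= 1")
  y <- as_class_factor(labels)
  if (length(y) != nrow(features)) stop("labels must match feature rows")
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present to build a class-wise codebook")
  for (cls in CLASS_LEVELS) {
    if (sum(y == cls) < V) {
      stop("V=", V, " exceeds the number of ", cls, " features (", sum(y == cls), ")")
    }
  }
  scaler <- fit_scaler(features)
  Xs <- apply_scaler(features, scaler)
  fits <- withr::with_seed(as.integer(seed), {
    lapply(CLASS_LEVELS, function(cls) {
      lloyd_kmeans(Xs[y == cls, , drop = FALSE], V, max_iter = max_iter)
    })
  })
  names(fits) <- CLASS_LEVELS
  structure(
    list(centroids = rbind(fits$bleached$centers, fits$unbleached$centers),
         centroid_class = rep(CLASS_LEVELS, each = V),
         V = V, m = 2L * V, d = ncol(features),
         scaler = scaler,
         objective = fits$bleached$objective + fits$unbleached$objective,
         trace = list(bleached = fits$bleached$trace,
                      unbleached = fits$unbleached$trace),
         assignments = list(bleached = fits$bleached$cluster,
                            unbleached = fits$unbleached$cluster),
         seed = as.integer(seed)),
    class = "coral_codebook"
  )
}

#' Assemble a codebook from explicit centroids
#'
#' Lower-level constructor used when the vocabulary comes from elsewhere
#' (persisted runs, tests, worked examples) rather than [build_codebook()].
#'
#' @param centroids Numeric `m x d` centroid matrix.
#' @param centroid_class Optional class tag per centroid.
#' @param scaler Optional `list(center, scale)` applied to features before
#'   encoding (`NULL` = identity).
#' @return A `coral_codebook`.
#' @export
codebook <- function(centroids, centroid_class = NULL, scaler = NULL) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 1) stop("codebook must contain at least one centroid")
  structure(
    list(centroids = centroids,
         centroid_class = centroid_class %||% rep(NA_character_, nrow(centroids)),
         V = NA_integer_, m = nrow(centroids), d = ncol(centroids),
         scaler = scaler, objective = NA_real_,
         trace = NULL, assignments = NULL, seed = NA_integer_),
    class = "coral_codebook"
  )
}

#' @export
print.coral_codebook <- function(x, ...) {
  cat(sprintf("<coral_codebook> m=%d centroids (V=%s per class), d=%d, objective=%s\n",
              x$m, x$V, x$d, format(x$objective)))
  invisible(x)
}

# k-means++ seeding: first center uniform, then D^2-weighted draws.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1)
  centers[1, ] <- X[first, ]
  if (k == 1) return(centers)
  d2 <- dist2(X, centers[1, , drop = FALSE])[, 1]
  for (j in 2:k) {
    pick <- if (sum(d2) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = d2)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, dist2(X, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

# Lloyd's algorithm with assignment-stability convergence, an objective
# trace recorded once per iteration (at the assignment step, after any
# empty-cluster repair, so the trace is provably non-increasing), and
# farthest-point re-seeding of empty clusters. Re-seeding cannot raise
# the objective: an empty centroid serves no point, and the re-seeded
# point's own cost drops to zero.
lloyd_kmeans <- function(X, k, max_iter = 300L, tol = 1e-6) {
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of feature vectors")
  centers <- kmeanspp_init(X, k)
  xnorm <- matrix(rowSums(X * X), n, k)
  prev_assign <- integer(0)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    D <- xnorm + matrix(rowSums(centers * centers), n, k, byrow = TRUE) -
      2 * tcrossprod(X, centers)
    D[D < 0] <- 0
    a <- max.col(-D, ties.method = "first")
    point_d <- D[cbind(seq_len(n), a)]
    empty <- setdiff(seq_len(k), unique(a))
    for (j in empty) {
      far <- which.max(point_d)
      centers[j, ] <- X[far, ]
      a[far] <- j
      point_d[far] <- 0
    }
    obj <- sum(point_d)
    trace <- c(trace, obj)
    if (length(prev_assign) && identical(a, prev_assign)) break
    sums <- rowsum(X, group = a, reorder = FALSE)
    cnt <- as.integer(table(factor(a, levels = seq_len(k))))
    ord <- as.integer(rownames(sums))
    centers[ord, ] <- sums / cnt[ord]
    prev_assign <- a
    if (length(trace) > 1 && (trace[length(trace) - 1] - obj) <= tol * max(trace[1], 1)) break
  }
  list(centers = centers, cluster = prev_assign,
       objective = trace[length(trace)], trace = trace, iterations = length(trace))
}

#' Encode an image's patch features against a codebook
#'
#' For each patch feature the squared Euclidean distances to all `m`
#' centroids are computed, and the feature's match threshold is its mean
#' squared distance over the codebook,
#' `eta_i = sum_j d2_ij / m`. Two assignment rules are available:
#'
#' * `nearest_only` (default): the feature votes for its single nearest
#'   centroid, provided that centroid is within `eta_i` — a condition
#'   that always holds (min <= mean), so this mode is exactly classical
#'   hard-assignment bag-of-features and `sum(F)` equals the patch
#'   count. This is the default because in high-dimensional feature
#'   spaces the mean-distance threshold saturates (see the methods
#'   vignette).
#' * `all_below_threshold`: the feature votes for every centroid with
#'   `d2_ij <= eta_i` — the reading under which the threshold actively
#'   selects matches (each feature contributes between 1 and `m` votes,
#'   since its minimum distance never exceeds its mean).
#'
#' Ties on the nearest centroid go to the lowest centroid index.
#'
#' @param features Numeric matrix of raw patch features for one image
#'   (rows = patches); the codebook's scaler is applied internally.
#' @param cb A `coral_codebook`.
#' @param mode Assignment rule (see above).
#' @return A `coral_encoded`: integer count vector `F` of length `m`,
#'   `n_patches`, and the `mode` used.
#' @export
encode_image <- function(features, cb,
                         mode = c("nearest_only", "all_below_threshold")) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("image yielded no patch features to encode")
  if (ncol(features) != cb$d) {
    stop("feature dimension (", ncol(features), ") does not match codebook (", cb$d, ")")
  }
  Xs <- apply_scaler(features, cb$scaler)
  D <- dist2(Xs, cb$centroids)
  eta <- rowMeans(D)
  if (mode == "all_below_threshold") {
    F_counts <- colSums(D <= eta)
  } else {
    nn <- max.col(-D, ties.method = "first")
    keep <- D[cbind(seq_len(nrow(D)), nn)] <= eta
    F_counts <- tabulate(nn[keep], nbins = cb$m)
  }
  structure(list(F = as.integer(F_counts), n_patches = nrow(features), mode = mode),
            class = "coral_encoded")
}

#' @export
print.coral_encoded <- function(x, ...) {
  cat(sprintf("<coral_encoded> %d words, %d patches, mode=%s\n",
              length(x$F), x$n_patches, x$mode))
  invisible(x)
}

# Stack encoded images into the classifier input matrix; the L1-normalized
# view is what the SVM consumes (counts are also safe here because the
# patch count is constant on a fixed canvas).
encoded_matrix <- function(encoded, normalize = TRUE) {
  E <- t(vapply(encoded, function(e) as.numeric(e$F), numeric(length(encoded[[1]]$F))))
  if (normalize) E <- E / rowSums(E)
  E
}

#' Encode every image of a manifest
#'
#' Maps canonicalization, patching, hybrid feature extraction and
#' [encode_image()] over all manifest entries, order preserved. Any
#' failure aborts naming the offending image.
#'
#' @param manifest A `coral_manifest`.
#' @param cb A `coral_codebook` fitted on training data.
#' @param patch_size Patch side `M`.
#' @param backend A [deep_backend()].
#' @param ct A [color_texture_params()].
#' @param canvas Analysis canvas side (default 512).
#' @param mode Assignment rule, see [encode_image()].
#' @return List of `coral_encoded`, one per manifest row, each carrying
#'   its `image_id`.
#' @export
encode_dataset <- function(manifest, cb, patch_size, backend,
                           ct = color_texture_params(), canvas = 512L,
                           mode = c("nearest_only", "all_below_threshold")) {
  mode <- match.arg(mode)
  lapply(seq_len(nrow(manifest$entries)), function(i) {
    p <- manifest$entries$path[i]
    tryCatch({
      img <- load_and_canonicalize(p, canvas = canvas,
                                   label = manifest$entries$label[i])
      chi <- image_features(img, patch_size, backend, ct)
      e <- encode_image(chi, cb, mode)
      e$image_id <- img$image_id
      e
    }, error = function(err) {
      stop("encoding failed for image '", p, "': ", conditionMessage(err),
           call. = FALSE)
    })
  })
}
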