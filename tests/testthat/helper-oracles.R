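# Independent brute-force oracles and small fixture builders.

# Naive sliding-window enumeration: every 0-based origin (r, c) that is a
# multiple of M/2 with the window fully inside the image, row-major.
naive_patch_origins <- function(L_r, L_c, M) {
  s <- M / 2
  out <- list()
  for (r in seq(0, L_r, by = s)) {
    for (c in seq(0, L_c, by = s)) {
      if (r + M <= L_r && c + M <= L_c) out[[length(out) + 1]] <- c(r, c)
    }
  }
  out
}

# Naive (feature x centroid) double-loop implementation of the thresholded
# histogram encoding, written against the formulas directly.
naive_encode <- function(X, centroids, mode) {
  n <- nrow(X)
  m <- nrow(centroids)
  F_counts <- integer(m)
  for (i in seq_len(n)) {
    d2 <- numeric(m)
    for (j in seq_len(m)) d2[j] <- sum((X[i, ] - centroids[j, ])^2)
    eta <- sum(d2) / m
    if (mode == "all_below_threshold") {
      for (j in seq_len(m)) if (d2[j] <= eta) F_counts[j] <- F_counts[j] + 1L
    } else {
      j_star <- which(d2 == min(d2))[1]
      if (d2[j_star] <= eta) F_counts[j_star] <- F_counts[j_star] + 1L
    }
  }
  F_counts
}

# Naive per-pixel bilinear resize with the same half-pixel convention.
naive_resize <- function(px, out_h, out_w) {
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- array(0, dim = c(out_h, out_w, dim(px)[3]))
  for (ch in seq_len(dim(px)[3])) {
    for (y in seq_len(out_h)) {
      fy <- min(max((y - 0.5) * h / out_h - 0.5, 0), h - 1)
      y0 <- floor(fy); wy <- fy - y0
      y1 <- min(y0 + 1, h - 1)
      for (x in seq_len(out_w)) {
        fx <- min(max((x - 0.5) * w / out_w - 0.5, 0), w - 1)
        x0 <- floor(fx); wx <- fx - x0
        x1 <- min(x0 + 1, w - 1)
        out[y, x, ch] <-
          (1 - wy) * (1 - wx) * px[y0 + 1, x0 + 1, ch] +
          (1 - wy) * wx * px[y0 + 1, x1 + 1, ch] +
          wy * (1 - wx) * px[y1 + 1, x0 + 1, ch] +
          wy * wx * px[y1 + 1, x1 + 1, ch]
      }
    }
  }
  out
}

rand_pixels <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(sample.int(256, h * w * 3, replace = TRUE) - 1L,
                               dim = c(h, w, 3)))
}

rand_image <- function(h, w, seed = 1, id = "rand") {
  new_coral_image(rand_pixels(h, w, seed), id)
}

# Small two-class dataset shared by evaluation-level tests.
small_dataset <- function(dir, n = 5, canvas = 96, separation = 1, seed = 42) {
  generate_dataset(
    synthetic_config(n_per_class = n, canvas = canvas,
                     separation = separation, seed = seed),
    dir
  )
}
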