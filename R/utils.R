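`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation so independent pipeline stages (and
# independent images) draw from disjoint, reproducible RNG streams.
# Exact in double precision for any base seed below 2^31.
derive_seed <- function(seed, k) {
  as.integer(((as.double(seed) %% 2147480000) * 7919 + as.double(k)) %% 2147483646 + 1)
}

# Squared Euclidean distances between the rows of X (n x d) and C (m x d).
dist2 <- function(X, C) {
  n <- nrow(X)
  m <- nrow(C)
  D <- matrix(rowSums(X * X), n, m) +
    matrix(rowSums(C * C), n, m, byrow = TRUE) -
    2 * tcrossprod(X, C)
  D[D < 0] <- 0
  D
}

# Per-dimension z-scoring fitted on training rows only; constant
# dimensions get unit scale so they pass through unchanged.
fit_scaler <- function(X) {
  center <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(center = center, scale = s)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

CLASS_LEVELS <- c("bleached", "unbleached")

as_class_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), CLASS_LEVELS)
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = CLASS_LEVELS)
}
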