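#' Parameters of the color-texture descriptor
#'
#' The handcrafted descriptor quantizes each RGB channel uniformly into
#' `levels` bins over `[0, 255]`, splits the patch into a `grid x grid`
#' lattice of equal sub-blocks, histograms the quantized values per
#' sub-block per channel, and concatenates everything in fixed order
#' (sub-blocks row-major, channels R,G,B within each block). Local
#' histograms capture the spatial repetition of textons; the quantized
#' palette captures color.
#'
#' @param levels Color-quantization levels per channel (Q >= 2, default 32).
#' @param grid Sub-block lattice side (default 2, i.e. 4 blocks).
#' @param normalize_blocks L1-normalize each block-channel histogram
#'   (default TRUE).
#' @return A `color_texture_params` list. Descriptor length is
#'   `3 * levels * grid^2`.
#' @export
color_texture_params <- function(levels = 32L, grid = 2L, normalize_blocks = TRUE) {
  levels <- as.integer(levels)
  grid <- as.integer(grid)
  if (is.na(levels) || levels < 2) stop("quantization levels Q must be >= 2")
  if (is.na(grid) || grid < 1) stop("sub-block grid must be >= 1")
  structure(list(levels = levels, grid = grid,
                 normalize_blocks = isTRUE(normalize_blocks)),
            class = "color_texture_params")
}

ct_length <- function(p) 3L * p$levels * p$grid^2

# Uniform quantization of 8-bit intensities into Q bins over [0,255]:
# bin(v) = floor(v * Q / 256), so bin Q-1 absorbs the top of the range.
quantize_levels <- function(px, Q) {
  (px * as.integer(Q)) %/% 256L
}

# Near-equal contiguous block boundaries for a side of length M.
block_bounds <- function(M, g) round(seq(0, M, length.out = g + 1))

#' Color-texture descriptor of one patch
#'
#' @param patch A `coral_patch` (or integer `M x M x 3` array).
#' @param p A [color_texture_params()].
#' @return Numeric vector of length `3 * levels * grid^2`. With
#'   `normalize_blocks = TRUE` every block-channel histogram sums to 1;
#'   otherwise entries are raw pixel counts.
#' @export
color_texture <- function(patch, p = color_texture_params()) {
  px <- if (inherits(patch, "coral_patch")) patch$pixels else patch
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  M <- dim(px)[1]
  if (dim(px)[2] != M) stop("color_texture expects square patches")
  if (M < p$grid) stop("patch side (", M, ") must be >= sub-block grid (", p$grid, ")")
  q <- quantize_levels(px, p$levels)
  ct_of_qpatch(q, block_bounds(M, p$grid), p)
}

# Shared descriptor kernel operating on a quantized patch (values 0..Q-1).
ct_of_qpatch <- function(q, bounds, p) {
  g <- p$grid
  Q <- p$levels
  out <- numeric(3L * Q * g^2)
  off <- 0L
  for (br in seq_len(g)) {
    rows <- (bounds[br] + 1):bounds[br + 1]
    for (bc in seq_len(g)) {
      cols <- (bounds[bc] + 1):bounds[bc + 1]
      for (ch in 1:3) {
        h <- tabulate(q[rows, cols, ch] + 1L, nbins = Q)
        if (p$normalize_blocks) h <- h / (length(rows) * length(cols))
        out[off + seq_len(Q)] <- h
        off <- off + Q
      }
    }
  }
  out
}

#' Construct a deep patch-embedding backend
#'
#' Two backends are shipped:
#'
#' * `"stub"` — a seeded fixed random linear projection of the flattened,
#'   bilinearly resized patch followed by a `tanh` nonlinearity. Fully
#'   deterministic and offline; it is the default embedding the test
#'   suite and synthetic studies run with.
#' * `"alexnet-fc7"` — penultimate fully-connected activations of a
#'   pretrained AlexNet, obtained through an external `python` with
#'   `torch`/`torchvision` importable. If that stack is absent the
#'   constructor raises a "backend unavailable" error rather than falling
#'   back silently; see the README for the manual reproduction workflow.
#'
#' @param name `"stub"` or `"alexnet-fc7"`.
#' @param dim Embedding length for the stub backend (default 64; the
#'   AlexNet backend's 4096 is fixed by the architecture).
#' @param input_size Native square input side each patch is bilinearly
#'   resized to (stub default 32; AlexNet 227).
#' @param seed Seed of the stub's fixed projection.
#' @return A `coral_backend`.
#' @export
deep_backend <- function(name = c("stub", "alexnet-fc7"), dim = 64L,
                         input_size = 32L, seed = 1L) {
  name <- match.arg(name)
  if (name == "stub") {
    dim <- as.integer(dim)
    input_size <- as.integer(input_size)
    n_in <- 3L * input_size^2
    W <- withr::with_seed(as.integer(seed),
                          matrix(stats::rnorm(dim * n_in), dim, n_in)) / sqrt(n_in)
    return(structure(list(name = name, dim = dim, input_size = input_size,
                          seed = as.integer(seed), W = W),
                     class = "coral_backend"))
  }
  if (!alexnet_available()) {
    stop("backend unavailable: 'alexnet-fc7' requires an external 'python' with ",
         "torch and torchvision importable (pretrained AlexNet weights); ",
         "see the coralbof README for this manual workflow")
  }
  structure(list(name = name, dim = 4096L, input_size = 227L, seed = NA_integer_),
            class = "coral_backend")
}

alexnet_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  code <- paste0("import importlib.util as u, sys; ",
                 "sys.exit(0 if (u.find_spec('torch') and u.find_spec('torchvision')) else 1)")
  status <- suppressWarnings(
    system2(py, c("-c", shQuote(code)), stdout = FALSE, stderr = FALSE)
  )
  identical(status, 0L)
}

#' @export
print.coral_backend <- function(x, ...) {
  cat(sprintf("<coral_backend> %s: dim=%d, input=%dx%d\n",
              x$name, x$dim, x$input_size, x$input_size))
  invisible(x)
}

# Batch transform: X is n x (3 * input_size^2), rows are flattened resized
# patches (channels R,G,B concatenated, column-major within channel,
# intensities mapped to [-0.5, 0.5]). Returns n x dim.
backend_transform <- function(backend, X) {
  if (backend$name == "stub") {
    return(tanh(tcrossprod(X, backend$W)))
  }
  alexnet_transform_batch(backend, X)
}

alexnet_transform_batch <- function(backend, X) {
  py <- Sys.which("python")
  script <- system.file("python", "alexnet_fc7.py", package = "coralbof")
  if (!nzchar(py) || !nzchar(script)) {
    stop("backend unavailable: python helper for 'alexnet-fc7' not found")
  }
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(X, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- system2(py, c(script, fin, fout, backend$input_size))
  if (!identical(status, 0L)) stop("alexnet-fc7 backend failed (python exit ", status, ")")
  as.matrix(utils::read.table(fout, sep = ","))
}

# Flatten one resized numeric patch (s x s x 3) into the backend input row.
flatten_for_backend <- function(resized) {
  as.vector(resized) / 255 - 0.5
}

#' Deep embedding of one patch
#'
#' Bilinearly resizes the patch to the backend's native input size and
#' applies the backend transform. Deterministic: identical patches give
#' identical vectors.
#'
#' @param patch A `coral_patch` (or integer `M x M x 3` array).
#' @param backend A [deep_backend()].
#' @return Numeric vector of length `backend$dim`.
#' @export
deep_feature <- function(patch, backend) {
  px <- if (inherits(patch, "coral_patch")) patch$pixels else patch
  s <- backend$input_size
  resized <- resize_bilinear(px, s, s)
  as.numeric(backend_transform(backend, matrix(flatten_for_backend(resized), nrow = 1)))
}

#' Hybrid raw feature of one patch
#'
#' The per-patch raw feature is the concatenation `[deep; color-texture]`,
#' deep part first. Slicing the vector at the backend dimension recovers
#' the two parts exactly.
#'
#' @inheritParams deep_feature
#' @param p A [color_texture_params()].
#' @return A `coral_feature`: list with patch provenance (`image_id`,
#'   `grid_i`, `grid_j`), the hybrid vector `chi` (length
#'   `backend$dim + 3 * levels * grid^2`), and `dim_deep`.
#' @export
hybrid_feature <- function(patch, backend, p = color_texture_params()) {
  a <- deep_feature(patch, backend)
  ctv <- color_texture(patch, p)
  stopifnot(length(a) > 0, length(ctv) > 0)
  prov <- if (inherits(patch, "coral_patch")) {
    patch[c("image_id", "grid_i", "grid_j")]
  } else {
    list(image_id = "patch", grid_i = NA_integer_, grid_j = NA_integer_)
  }
  structure(c(prov, list(chi = c(a, ctv), dim_deep = length(a))),
            class = "coral_feature")
}

#' Hybrid raw features of every patch of an image
#'
#' Fast path equivalent to mapping [hybrid_feature()] over
#' [extract_patches()]: extracts the 50%-overlap patch grid and computes
#' the hybrid descriptor for each patch in row-major order.
#'
#' @param img A `coral_image`.
#' @param patch_size Patch side `M` (even).
#' @param backend A [deep_backend()].
#' @param ct A [color_texture_params()].
#' @return Numeric matrix, one row per patch (row-major grid order),
#'   columns `[deep | color-texture]`. Attributes: `grid` (data frame of
#'   0-based `i`,`j`), `dim_deep`, `dim_ct`.
#' @export
image_features <- function(img, patch_size, backend, ct = color_texture_params()) {
  px <- img$pixels
  M <- as.integer(patch_size)
  if (M %% 2L != 0L) stop("patch size M must be even: 50% overlap requires stride M/2 (got M=", M, ")")
  if (M > min(dim(px)[1:2])) stop("patch size M=", M, " exceeds image extent")
  r0 <- patch_grid(dim(px)[1], M)
  c0 <- patch_grid(dim(px)[2], M)
  n <- length(r0) * length(c0)
  s <- backend$input_size
  rmap <- resize_map(M, s)
  bounds <- block_bounds(M, ct$grid)
  q <- quantize_levels(px, ct$levels)
  WY <- matrix(rmap$w, s, s)
  WX <- matrix(rmap$w, s, s, byrow = TRUE)
  dim_ct <- ct_length(ct)
  CT <- matrix(0, n, dim_ct)
  Xres <- matrix(0, n, 3L * s^2)
  grid <- data.frame(i = integer(n), j = integer(n))
  chans <- list(px[, , 1], px[, , 2], px[, , 3])
  w00 <- (1 - WY) * (1 - WX); w01 <- (1 - WY) * WX
  w10 <- WY * (1 - WX);       w11 <- WY * WX
  k <- 0L
  for (i in seq_along(r0)) {
    rr <- r0[i] + seq_len(M)
    ry0 <- r0[i] + rmap$i0
    ry1 <- r0[i] + rmap$i1
    for (j in seq_along(c0)) {
      k <- k + 1L
      cc <- c0[j] + seq_len(M)
      cx0 <- c0[j] + rmap$i0
      cx1 <- c0[j] + rmap$i1
      CT[k, ] <- ct_of_qpatch(q[rr, cc, , drop = FALSE], bounds, ct)
      row <- numeric(3L * s^2)
      for (ch in 1:3) {
        A <- chans[[ch]]
        val <- w00 * A[ry0, cx0] + w01 * A[ry0, cx1] +
               w10 * A[ry1, cx0] + w11 * A[ry1, cx1]
        row[(ch - 1L) * s^2 + seq_len(s^2)] <- as.vector(val)
      }
      Xres[k, ] <- row / 255 - 0.5
      grid$i[k] <- i - 1L
      grid$j[k] <- j - 1L
    }
  }
  A <- backend_transform(backend, Xres)
  chi <- cbind(A, CT)
  attr(chi, "grid") <- grid
  attr(chi, "dim_deep") <- backend$dim
  attr(chi, "dim_ct") <- dim_ct
  chi
}
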