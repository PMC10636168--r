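#' 0-based patch-grid origins along one axis
#'
#' Origins of all fully contained M-pixel windows at stride M/2 (50%
#' overlap) along an axis of length `L`: `0, M/2, 2*M/2, ...` while
#' `origin + M <= L`. Remainder pixels past the last full window are
#' dropped, never padded.
#'
#' @param L Axis length in pixels.
#' @param M Even window side.
#' @return Integer vector of 0-based origins,
#'   length `floor((L - M) / (M/2)) + 1`.
#' @export
patch_grid <- function(L, M) {
  seq.int(0L, as.integer(L) - as.integer(M), by = as.integer(M) %/% 2L)
}

#' Extract overlapped square patches from a canonical image
#'
#' Tiles the image into `M x M` patches with 50% overlap between
#' consecutive patches (stride `M/2` along both axes), keeping only
#' windows fully contained in the image. Patches are returned in
#' row-major grid order; pixels are copied untransformed.
#'
#' @param img A `coral_image` (or integer `H x W x 3` array).
#' @param M Patch side in pixels; must be even (50% overlap is otherwise
#'   undefined) and no larger than the smaller image side.
#' @return List of `coral_patch` objects, each with `image_id`, 0-based
#'   grid indices `grid_i`/`grid_j`, `M`, and `pixels` (`M x M x 3`).
#' @examples
#' img <- new_coral_image(array(0L, c(8, 8, 3)), "ex")
#' length(extract_patches(img, 4))  # 3 x 3 grid
#' @export
extract_patches <- function(img, M) {
  px <- if (inherits(img, "coral_image")) img$pixels else img
  image_id <- if (inherits(img, "coral_image")) img$image_id else "image"
  M <- as.integer(M)
  if (is.na(M) || M < 2) stop("patch size M must be an integer >= 2")
  if (M %% 2L != 0L) stop("patch size M must be even: 50% overlap requires stride M/2 (got M=", M, ")")
  L_r <- dim(px)[1]; L_c <- dim(px)[2]
  if (M > min(L_r, L_c)) {
    stop("patch size M=", M, " exceeds image extent ", L_r, "x", L_c)
  }
  r0 <- patch_grid(L_r, M)
  c0 <- patch_grid(L_c, M)
  out <- vector("list", length(r0) * length(c0))
  k <- 0L
  for (i in seq_along(r0)) {
    for (j in seq_along(c0)) {
      k <- k + 1L
      out[[k]] <- structure(
        list(image_id = image_id, grid_i = i - 1L, grid_j = j - 1L, M = M,
             pixels = px[r0[i] + seq_len(M), c0[j] + seq_len(M), , drop = FALSE]),
        class = "coral_patch"
      )
    }
  }
  out
}

#' @export
print.coral_patch <- function(x, ...) {
  cat(sprintf("<coral_patch> %s (%d,%d) %dx%d\n",
              x$image_id, x$grid_i, x$grid_j, x$M, x$M))
  invisible(x)
}
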