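#' Load a labeled image manifest
#'
#' Reads the dataset manifest that pairs every survey image with its class
#' label (`bleached` or `unbleached`). Two layouts are accepted:
#'
#' * a CSV file with header `path,label`, paths relative to the CSV's
#'   directory (or absolute);
#' * a directory containing two sub-directories `bleached/` and
#'   `unbleached/` of PNG/JPEG files (the layout public coral datasets
#'   ship in).
#'
#' Validation is eager: unknown labels, duplicate paths, and references to
#' missing files all fail at load time, naming the offending row.
#'
#' @param path Path to a manifest CSV or to a two-directory dataset root.
#' @return A `coral_manifest`: list with `entries` (data frame of absolute
#'   `path` and `label`, input order preserved) and `counts` (named vector
#'   `total`, `bleached`, `unbleached`).
#' @examples
#' d <- tempfile()
#' cfg <- synthetic_config(n_per_class = 2, canvas = 64, seed = 1)
#' m <- generate_dataset(cfg, d)
#' m$counts
#' @export
load_manifest <- function(path) {
  if (dir.exists(path)) {
    return(manifest_from_directory(path))
  }
  if (!file.exists(path)) {
    stop("manifest does not exist: ", path)
  }
  if (file.size(path) == 0) {
    stop("empty manifest: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    stop("empty manifest: ", path)
  }
  if (!all(c("path", "label") %in% names(df))) {
    stop("manifest must have columns 'path' and 'label': ", path)
  }
  bad <- which(!df$label %in% CLASS_LEVELS)
  if (length(bad)) {
    stop(sprintf(
      "unknown label '%s' in manifest row %d (expected 'bleached' or 'unbleached')",
      df$label[bad[1]], bad[1]
    ))
  }
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path, file.path(root, df$path))
  new_manifest(abs, df$label)
}

manifest_from_directory <- function(root) {
  paths <- character(0)
  labels <- character(0)
  for (cls in CLASS_LEVELS) {
    sub <- file.path(root, cls)
    if (!dir.exists(sub)) {
      stop("directory manifest needs sub-directories 'bleached' and 'unbleached'; missing: ", sub)
    }
    f <- sort(list.files(sub, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                         full.names = TRUE))
    paths <- c(paths, f)
    labels <- c(labels, rep(cls, length(f)))
  }
  if (length(paths) == 0) stop("empty manifest: no images under ", root)
  new_manifest(paths, labels)
}

new_manifest <- function(paths, labels) {
  dup <- anyDuplicated(paths)
  if (dup) stop("duplicate image path in manifest: ", paths[dup])
  missing <- which(!file.exists(paths))
  if (length(missing)) {
    stop(sprintf("manifest row %d references a missing file: %s",
                 missing[1], paths[missing[1]]))
  }
  labels <- as.character(labels)
  counts <- c(
    total = length(paths),
    bleached = sum(labels == "bleached"),
    unbleached = sum(labels == "unbleached")
  )
  structure(
    list(entries = data.frame(path = paths, label = labels,
                              stringsAsFactors = FALSE),
         counts = counts),
    class = "coral_manifest"
  )
}

#' @export
print.coral_manifest <- function(x, ...) {
  cat(sprintf("<coral_manifest> %d images (%d bleached, %d unbleached)\n",
              x$counts[["total"]], x$counts[["bleached"]], x$counts[["unbleached"]]))
  invisible(x)
}

#' Load an image and canonicalize it onto the analysis canvas
#'
#' Decodes a PNG/JPEG, fixes the channel order to R,G,B, replicates
#' grayscale inputs across the three channels, and resizes to the square
#' analysis canvas with pixel-center-aligned bilinear resampling. Images
#' already at canvas size pass through bit-exactly. Intensities are 8-bit
#' integers in `[0, 255]`.
#'
#' @param path Path to a decodable PNG or JPEG file.
#' @param canvas Side length of the square analysis canvas (default 512,
#'   the size every survey image is normalized to before patching).
#' @param label Optional class label to attach (`"bleached"`,
#'   `"unbleached"`, or `"unknown"`).
#' @return A `coral_image`: list with `image_id`, integer `pixels`
#'   (canvas x canvas x 3, channel order R,G,B) and `label`.
#' @export
load_and_canonicalize <- function(path, canvas = 512L, label = "unknown") {
  if (!file.exists(path)) stop("image file does not exist: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path, "': ",
                                           conditionMessage(e)))
  d <- EBImage::imageData(img)
  nd <- length(dim(d))
  if (nd == 2) {
    # grayscale: EBImage stores x (columns) first
    gm <- t(d)
    px <- array(0, dim = c(nrow(gm), ncol(gm), 3))
    px[, , 1] <- gm; px[, , 2] <- gm; px[, , 3] <- gm
  } else if (nd == 3) {
    nc <- dim(d)[3]
    if (nc == 1) {
      gm <- t(d[, , 1])
      px <- array(0, dim = c(nrow(gm), ncol(gm), 3))
      px[, , 1] <- gm; px[, , 2] <- gm; px[, , 3] <- gm
    } else {
      if (nc > 3) d <- d[, , 1:3, drop = FALSE]  # drop alpha
      px <- aperm(d, c(2, 1, 3))
    }
  } else {
    stop("unsupported image layout in '", path, "' (", nd, " dimensions)")
  }
  if (any(dim(px)[1:2] == 0)) stop("zero-area image: ", path)
  px <- round(clamp255(px * 255))
  px <- canonicalize_pixels(px, canvas)
  new_coral_image(px, image_id = sub("\\.[^.]+$", "", basename(path)),
                  label = label)
}

canonicalize_pixels <- function(px, canvas) {
  canvas <- as.integer(canvas)
  if (canvas < 1) stop("canvas must be a positive integer")
  if (dim(px)[1] == canvas && dim(px)[2] == canvas) {
    return(array(as.integer(px), dim = dim(px)))
  }
  out <- resize_bilinear(px, canvas, canvas)
  array(as.integer(round(clamp255(out))), dim = c(canvas, canvas, 3))
}

#' Construct a canonical image object
#'
#' @param pixels Integer `H x W x 3` array of intensities in `[0,255]`,
#'   channel order R,G,B.
#' @param image_id Identifier string.
#' @param label `"bleached"`, `"unbleached"`, or `"unknown"`.
#' @return A `coral_image`.
#' @export
new_coral_image <- function(pixels, image_id, label = "unknown") {
  structure(list(image_id = image_id, pixels = pixels, label = label),
            class = "coral_image")
}

#' @export
print.coral_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<coral_image> %s: %dx%dx%d, label=%s\n",
              x$image_id, d[1], d[2], d[3], x$label))
  invisible(x)
}

#' Bilinear resize with pixel-center alignment
#'
#' Maps every output pixel center to input coordinates via
#' `x_in = (x_out + 0.5) * (W_in / W_out) - 0.5` (the half-pixel
#' convention used by mainstream image libraries), clamps to the image
#' border, and interpolates bilinearly. Deterministic and exact for the
#' identity size.
#'
#' @param px Numeric `H x W x C` array (or `H x W` matrix).
#' @param out_h,out_w Output height and width in pixels.
#' @return Numeric array `out_h x out_w x C` (unrounded).
#' @export
resize_bilinear <- function(px, out_h, out_w) {
  if (is.matrix(px)) px <- array(px, dim = c(dim(px), 1L))
  h <- dim(px)[1]; w <- dim(px)[2]; nc <- dim(px)[3]
  if (h == 0 || w == 0) stop("zero-area image cannot be resized")
  map <- resize_map(h, out_h)
  iy0 <- map$i0; iy1 <- map$i1; wy <- map$w
  map <- resize_map(w, out_w)
  ix0 <- map$i0; ix1 <- map$i1; wx <- map$w
  WY <- matrix(wy, out_h, out_w)
  WX <- matrix(wx, out_h, out_w, byrow = TRUE)
  out <- array(0, dim = c(out_h, out_w, nc))
  for (ch in seq_len(nc)) {
    A <- px[, , ch]
    out[, , ch] <-
      (1 - WY) * (1 - WX) * A[iy0, ix0, drop = FALSE] +
      (1 - WY) * WX       * A[iy0, ix1, drop = FALSE] +
      WY       * (1 - WX) * A[iy1, ix0, drop = FALSE] +
      WY       * WX       * A[iy1, ix1, drop = FALSE]
  }
  out
}

# 1-based neighbor indices + interpolation weights for one axis.
resize_map <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  i0 <- floor(pos)
  w <- pos - i0
  list(i0 = as.integer(i0) + 1L, i1 = as.integer(pmin(i0 + 1, n_in - 1)) + 1L, w = w)
}

#' Write a canonical image to PNG
#'
#' 8-bit PNG output; round-trips bit-exactly through
#' [load_and_canonicalize()] at the same canvas size.
#'
#' @param img A `coral_image` (or integer `H x W x 3` array).
#' @param path Output file path (extension selects the format; use `.png`
#'   for lossless round trips).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "coral_image")) img$pixels else img
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 3)
  e <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(e, path)
  invisible(path)
}
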