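KERNELS <- c("linear", "quadratic", "cubic",
             "gaussian_fine", "gaussian_medium", "gaussian_coarse")

#' Train the SVM over encoded images
#'
#' Kernel families follow the usual presets: `quadratic`/`cubic` are
#' polynomial kernels of degree 2/3 with unit offset and `1/d` input
#' scaling, and the three Gaussian variants are RBF kernels with kernel
#' scale `sqrt(d)/4` (fine), `sqrt(d)` (medium) and `4*sqrt(d)` (coarse)
#' on the d-dimensional standardized inputs. Inputs are z-scored with
#' statistics fitted here and stored in the model. The positive class is
#' `bleached` throughout.
#'
#' @param x Numeric matrix, one row per image (e.g. L1-normalized encoded
#'   vectors).
#' @param labels Class label per row (`bleached` / `unbleached`); both
#'   classes must be present.
#' @param kernel One of `linear`, `quadratic`, `cubic`, `gaussian_fine`,
#'   `gaussian_medium`, `gaussian_coarse`.
#' @param C Box constraint (default 1).
#' @param seed Kept for interface symmetry; the libsvm fit is already
#'   deterministic for fixed inputs.
#' @return A `coral_model` usable with [predict.coral_model()].
#' @export
train_classifier <- function(x, labels, kernel = KERNELS, C = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite feature values passed to train_classifier")
  y <- droplevels(as_class_factor(labels))
  if (nlevels(y) < 2) stop("training data must contain both classes")
  y <- factor(as.character(y), levels = CLASS_LEVELS)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  d <- ncol(xs)
  args <- switch(kernel,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = 1 / d, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = 1 / d, coef0 = 1),
    gaussian_fine = list(kernel = "radial", gamma = 1 / (sqrt(d) / 4)^2),
    gaussian_medium = list(kernel = "radial", gamma = 1 / d),
    gaussian_coarse = list(kernel = "radial", gamma = 1 / (4 * sqrt(d))^2)
  )
  fit <- do.call(e1071::svm, c(list(x = xs, y = y, type = "C-classification",
                                    cost = C, scale = FALSE), args))
  # libsvm orients decision values toward the first training label it
  # sees; pin the convention "positive score = bleached" once here.
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  structure(list(fit = fit, scaler = scaler, kernel = kernel, C = C,
                 flip = if (identical(first, "bleached")) 1 else -1,
                 d = d),
            class = "coral_model")
}

#' Predict bleaching labels for encoded images
#'
#' Deterministic. The decision score is oriented so that positive values
#' mean `bleached`; a score of exactly zero is broken toward
#' `unbleached`, keeping label and score sign consistent by construction.
#'
#' @param object A `coral_model`.
#' @param newdata Numeric matrix with the training dimensionality; zero
#'   rows give a zero-row result.
#' @param ... Unused.
#' @return Data frame with `label` (factor `bleached`/`unbleached`) and
#'   numeric `score`.
#' @export
predict.coral_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == 1 && object$d > 1 && nrow(newdata) == object$d) {
    newdata <- t(newdata)
  }
  if (nrow(newdata) == 0) {
    return(data.frame(label = factor(character(0), levels = CLASS_LEVELS),
                      score = numeric(0)))
  }
  if (ncol(newdata) != object$d) {
    stop("prediction input has ", ncol(newdata), " columns; model expects ", object$d)
  }
  xs <- apply_scaler(newdata, object$scaler)
  pr <- stats::predict(object$fit, xs, decision.values = TRUE)
  score <- object$flip * attr(pr, "decision.values")[, 1]
  data.frame(
    label = factor(ifelse(score > 0, "bleached", "unbleached"),
                   levels = CLASS_LEVELS),
    score = as.numeric(score)
  )
}

#' @export
print.coral_model <- function(x, ...) {
  cat(sprintf("<coral_model> SVM kernel=%s, C=%g, d=%d, %d support vectors\n",
              x$kernel, x$C, x$d, x$fit$tot.nSV))
  invisible(x)
}
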