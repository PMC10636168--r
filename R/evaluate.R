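#' Cross-validation protocol
#'
#' The evaluation protocol: stratified K-fold cross-validation (default
#' `K = 4`, i.e. 75% training / 25% testing per run), repeated
#' `repetitions` times (default 2) with re-randomized fold assignment,
#' each fold serving as the held-out test segment exactly once per
#' repetition.
#'
#' @param K Number of folds (default 4).
#' @param repetitions Independent repetitions of the full K-fold cycle
#'   (default 2).
#' @param stratified Preserve the class ratio within folds (default TRUE).
#' @param seed Integer seed controlling fold assignment (and, derived
#'   from it, every per-fold codebook fit).
#' @return An `eval_protocol` list; `train_fraction` is `1 - 1/K`.
#' @export
eval_protocol <- function(K = 4L, repetitions = 2L, stratified = TRUE, seed = 1L) {
  K <- as.integer(K)
  repetitions <- as.integer(repetitions)
  if (is.na(K) || K < 2) stop("K must be >= 2")
  if (is.na(repetitions) || repetitions < 1) stop("repetitions must be >= 1")
  structure(list(K = K, repetitions = repetitions,
                 train_fraction = 1 - 1 / K,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "eval_protocol")
}

#' Stratified fold assignment
#'
#' Assigns each image to one of `K` folds; with stratification each
#' class is shuffled and dealt round-robin, so fold class ratios match
#' the dataset's to within one image. Depends only on
#' `(labels, K, seed)`.
#'
#' @param labels Class label per image.
#' @param K Number of folds.
#' @param seed Integer seed.
#' @param stratified Deal per class (default TRUE).
#' @return Integer fold index (1..K) per image.
#' @export
make_folds <- function(labels, K, seed = 1L, stratified = TRUE) {
  n <- length(labels)
  if (n < K) stop("need at least K images to form K folds")
  fold <- integer(n)
  withr::with_seed(as.integer(seed), {
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(K), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(K), n)
    }
  })
  fold
}

#' Pipeline parameters
#'
#' Bundles every stage parameter of the patch/feature/vocabulary/SVM
#' pipeline.
#'
#' @param canvas Analysis canvas side (default 512).
#' @param patch_size Patch side `M` (even, default 50 — the size the
#'   method performs best at on real reef imagery).
#' @param vocab_size Clusters per class `V` (default 10); the encoded
#'   vector has length `2V`.
#' @param backend A [deep_backend()] (default: the offline stub).
#' @param ct A [color_texture_params()].
#' @param assignment_mode Encoding rule, see [encode_image()].
#' @param kernel SVM kernel (default `quadratic`).
#' @param C SVM box constraint (default 1).
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(canvas = 512L, patch_size = 50L, vocab_size = 10L,
                            backend = deep_backend("stub"),
                            ct = color_texture_params(),
                            assignment_mode = c("nearest_only", "all_below_threshold"),
                            kernel = "quadratic", C = 1) {
  assignment_mode <- match.arg(assignment_mode)
  kernel <- match.arg(kernel, KERNELS)
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2L != 0L) {
    stop("patch size M must be even: 50% overlap requires stride M/2 (got M=", patch_size, ")")
  }
  structure(list(canvas = as.integer(canvas), patch_size = patch_size,
                 vocab_size = as.integer(vocab_size), backend = backend, ct = ct,
                 assignment_mode = assignment_mode, kernel = kernel, C = C),
            class = "pipeline_params")
}

#' Run the full K-fold cross-validation pipeline
#'
#' Extracts raw hybrid features once per image, then for every
#' (repetition, fold): fits the standardizer and class-wise codebook on
#' the training folds only, encodes all images against that vocabulary,
#' trains the SVM on the training folds, and predicts the held-out fold.
#' Held-out images never touch the scaler, the codebook, or the SVM fit.
#'
#' @param manifest A `coral_manifest`; both classes must appear in every
#'   training split (stratification enforces this whenever feasible).
#' @param params A [pipeline_params()].
#' @param protocol An [eval_protocol()].
#' @param keep_models Also return the per-run codebook and SVM (for
#'   audits; default FALSE).
#' @param verbose Log per-stage progress to stderr.
#' @return A `coral_eval`: `runs` (per-run accuracies), `mean_accuracy`
#'   and `sd_accuracy` in percent, pooled `confusion` counts and
#'   `f1` (positive class = bleached), and `predictions` (one row per
#'   held-out prediction with fold/repetition provenance).
#' @export
kfold_evaluate <- function(manifest, params = pipeline_params(),
                           protocol = eval_protocol(), keep_models = FALSE,
                           verbose = FALSE) {
  entries <- manifest$entries
  n <- nrow(entries)
  if (n < protocol$K) stop("need at least K images for K-fold evaluation")
  labels <- entries$label
  say <- function(...) if (verbose) message(sprintf(...))

  say("extracting raw features for %d images", n)
  feats <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    img <- load_and_canonicalize(entries$path[i], canvas = params$canvas,
                                 label = labels[i])
    feats[[i]] <- image_features(img, params$patch_size, params$backend, params$ct)
    ids[i] <- img$image_id
  }

  runs <- data.frame(repetition = integer(0), fold = integer(0),
                     n_test = integer(0), accuracy = numeric(0))
  preds <- list()
  models <- list()
  for (rep_i in seq_len(protocol$repetitions)) {
    fold <- make_folds(labels, protocol$K, derive_seed(protocol$seed, rep_i),
                       protocol$stratified)
    for (k in seq_len(protocol$K)) {
      tr <- fold != k
      if (length(unique(labels[tr])) < 2) {
        stop(sprintf("class missing from the training split (repetition %d, fold %d)",
                     rep_i, k))
      }
      Xtr <- do.call(rbind, feats[tr])
      ytr <- rep(labels[tr], vapply(feats[tr], nrow, integer(1)))
      cb <- build_codebook(Xtr, ytr, V = params$vocab_size,
                           seed = derive_seed(protocol$seed, 1000L + rep_i * 10L + k))
      enc <- lapply(feats, encode_image, cb = cb, mode = params$assignment_mode)
      E <- encoded_matrix(enc, normalize = TRUE)
      model <- train_classifier(E[tr, , drop = FALSE], labels[tr],
                                kernel = params$kernel, C = params$C)
      pr <- predict(model, E[!tr, , drop = FALSE])
      acc <- mean(as.character(pr$label) == labels[!tr])
      say("repetition %d fold %d: accuracy %.1f%% (%d test images)",
          rep_i, k, 100 * acc, sum(!tr))
      runs <- rbind(runs, data.frame(repetition = rep_i, fold = k,
                                     n_test = sum(!tr), accuracy = acc))
      preds[[length(preds) + 1L]] <- data.frame(
        image_id = ids[!tr], path = entries$path[!tr], truth = labels[!tr],
        predicted = as.character(pr$label), score = pr$score,
        fold = k, repetition = rep_i, stringsAsFactors = FALSE)
      if (keep_models) {
        models[[sprintf("rep%d_fold%d", rep_i, k)]] <-
          list(codebook = cb, model = model)
      }
    }
  }
  predictions <- do.call(rbind, preds)
  confusion <- c(
    TP = sum(predictions$truth == "bleached" & predictions$predicted == "bleached"),
    FP = sum(predictions$truth == "unbleached" & predictions$predicted == "bleached"),
    TN = sum(predictions$truth == "unbleached" & predictions$predicted == "unbleached"),
    FN = sum(predictions$truth == "bleached" & predictions$predicted == "unbleached")
  )
  m <- metrics(confusion)
  structure(
    list(runs = runs,
         mean_accuracy = mean(runs$accuracy) * 100,
         sd_accuracy = stats::sd(runs$accuracy * 100),
         f1 = m$f1, confusion = confusion,
         predictions = predictions,
         protocol = protocol,
         params = list(canvas = params$canvas, patch_size = params$patch_size,
                       vocab_size = params$vocab_size,
                       backend = params$backend$name,
                       assignment_mode = params$assignment_mode,
                       kernel = params$kernel, C = params$C),
         models = if (keep_models) models else NULL),
    class = "coral_eval"
  )
}

#' @export
print.coral_eval <- function(x, ...) {
  cat(sprintf("<coral_eval> %d-fold x %d repetitions: accuracy %.2f%% (SD %.2f), F1 %.4f\n",
              x$protocol$K, x$protocol$repetitions,
              x$mean_accuracy, x$sd_accuracy, x$f1))
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              x$confusion[["TP"]], x$confusion[["FP"]],
              x$confusion[["TN"]], x$confusion[["FN"]]))
  invisible(x)
}

#' Accuracy and F1 from confusion counts
#'
#' `accuracy = 100 * (TP + TN) / total`;
#' `F1 = 2 TP / (2 TP + FP + FN)` with `bleached` as the positive class.
#' When no positive predictions or truths exist (`TP + FP + FN = 0`),
#' F1 is defined as 0 with a warning.
#'
#' @param confusion Named counts `TP`, `FP`, `TN`, `FN` (vector or list).
#' @return List with `accuracy` (percent) and `f1`.
#' @examples
#' metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
#' @export
metrics <- function(confusion) {
  cnt <- unlist(confusion)[c("TP", "FP", "TN", "FN")]
  if (any(is.na(cnt))) stop("confusion must contain TP, FP, TN, FN")
  if (any(cnt < 0)) stop("confusion counts must be non-negative")
  total <- sum(cnt)
  if (total == 0) stop("confusion counts are all zero")
  denom <- 2 * cnt[["TP"]] + cnt[["FP"]] + cnt[["FN"]]
  f1 <- if (denom == 0) {
    warning("no positive predictions or truths; F1 defined as 0")
    0
  } else {
    2 * cnt[["TP"]] / denom
  }
  list(accuracy = 100 * (cnt[["TP"]] + cnt[["TN"]]) / total, f1 = f1)
}

#' Write the per-image localization report
#'
#' Writes every held-out prediction (image id, true and predicted label,
#' decision score, fold and repetition) as CSV — the image-level account
#' of which survey images the model flags as containing bleached corals.
#' Optionally also writes a contact-sheet PNG of the images predicted
#' bleached.
#'
#' @param report A `coral_eval`.
#' @param out_path Output CSV path.
#' @param figure_path Optional PNG path for the predicted-bleached
#'   contact sheet (`NULL` to skip).
#' @param thumb Thumbnail side for the contact sheet (default 64 px).
#' @return `out_path`, invisibly.
#' @export
localization_report <- function(report, out_path, figure_path = NULL, thumb = 64L) {
  stopifnot(inherits(report, "coral_eval"))
  utils::write.csv(report$predictions, out_path, row.names = FALSE)
  if (!is.null(figure_path)) {
    hits <- unique(report$predictions$path[report$predictions$predicted == "bleached"])
    if (length(hits)) {
      thumbs <- EBImage::combine(lapply(hits, function(p) {
        img <- load_and_canonicalize(p, canvas = thumb)
        EBImage::Image(aperm(img$pixels / 255, c(2, 1, 3)), colormode = "Color")
      }))
      sheet <- EBImage::tile(thumbs, nx = ceiling(sqrt(length(hits))))
      EBImage::writeImage(sheet, figure_path)
    } else {
      message("no images predicted bleached; contact sheet skipped")
    }
  }
  invisible(out_path)
}
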