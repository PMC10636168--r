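test_that("metrics compute accuracy and F1 from confusion counts", {
  m <- metrics(c(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 1)
  m <- metrics(c(TP = 5, FP = 5, TN = 0, FN = 0))
  expect_equal(m$accuracy, 50)
  expect_equal(m$f1, 2 * 5 / (2 * 5 + 5 + 0))
  # swapping the positive class changes F1 but not accuracy
  sw <- metrics(c(TP = 0, FP = 0, TN = 5, FN = 5))
  expect_equal(sw$accuracy, 50)
  expect_false(isTRUE(all.equal(sw$f1, m$f1)))
  expect_warning(z <- metrics(c(TP = 0, FP = 0, TN = 3, FN = 0)), "F1")
  expect_equal(z$f1, 0)
  expect_error(metrics(c(TP = -1, FP = 0, TN = 0, FN = 1)), "non-negative")
  expect_error(metrics(c(TP = 0, FP = 0, TN = 0, FN = 0)), "all zero")
})

test_that("stratified folds at the survey size give segments {85,86,86,85}", {
  labels <- rep(c("bleached", "unbleached"), c(184, 158))
  fold <- make_folds(labels, K = 4, seed = 1)
  expect_equal(sort(as.integer(table(fold))), c(85, 85, 86, 86))
  # class ratio preserved to within one image per fold
  per_fold_b <- table(fold[labels == "bleached"])
  expect_true(max(per_fold_b) - min(per_fold_b) <= 1)
  per_fold_u <- table(fold[labels == "unbleached"])
  expect_true(max(per_fold_u) - min(per_fold_u) <= 1)
  # reproducible from (labels, K, seed) alone
  expect_identical(fold, make_folds(labels, K = 4, seed = 1))
  expect_false(identical(fold, make_folds(labels, K = 4, seed = 2)))
})

test_that("an extreme-separation dataset evaluates at 100% with zero spread", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 4, canvas = 64, separation = 1, seed = 21)
  p <- pipeline_params(canvas = 64, patch_size = 32, vocab_size = 2,
                       backend = deep_backend("stub", dim = 16))
  rep <- kfold_evaluate(man, p, eval_protocol(K = 4, repetitions = 2, seed = 2))
  expect_equal(rep$mean_accuracy, 100)
  expect_equal(rep$sd_accuracy, 0)
  expect_equal(rep$f1, 1)
  expect_equal(nrow(rep$predictions), 8 * 2)
  # mean/std recomputable from stored per-run accuracies
  expect_equal(rep$mean_accuracy, mean(rep$runs$accuracy) * 100)
  expect_equal(rep$sd_accuracy, stats::sd(rep$runs$accuracy * 100))
  expect_equal(sum(rep$confusion), nrow(rep$predictions))
})

test_that("random labels on balanced data score near chance", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 6, canvas = 64, separation = 1, seed = 23)
  # break the image/label association with a seeded permutation
  man$entries$label <- withr::with_seed(9, sample(man$entries$label))
  man$counts <- c(total = 12, bleached = 6, unbleached = 6)
  p <- pipeline_params(canvas = 64, patch_size = 32, vocab_size = 2,
                       backend = deep_backend("stub", dim = 16))
  rep <- kfold_evaluate(man, p, eval_protocol(K = 4, repetitions = 2, seed = 3))
  n <- nrow(rep$predictions)
  half_width <- 100 * 1.96 * sqrt(0.25 / n)
  expect_lt(abs(rep$mean_accuracy - 50), half_width)
})

test_that("held-out images never influence the fitted scaler or codebook", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 4, canvas = 64, separation = 1, seed = 25)
  p <- pipeline_params(canvas = 64, patch_size = 32, vocab_size = 2,
                       backend = deep_backend("stub", dim = 16))
  proto <- eval_protocol(K = 4, repetitions = 1, seed = 4)
  r1 <- kfold_evaluate(man, p, proto, keep_models = TRUE)
  # corrupt one image that fold 1 held out, then re-run
  victim <- r1$predictions$path[r1$predictions$fold == 1][1]
  write_image(rand_pixels(64, 64, 99), victim)
  r2 <- kfold_evaluate(man, p, proto, keep_models = TRUE)
  cb1 <- r1$models$rep1_fold1$codebook
  cb2 <- r2$models$rep1_fold1$codebook
  expect_identical(cb1$centroids, cb2$centroids)
  expect_identical(cb1$scaler, cb2$scaler)
  expect_identical(cb1$objective, cb2$objective)
})

test_that("the localization report round-trips through CSV", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 3, canvas = 64, separation = 1, seed = 27)
  p <- pipeline_params(canvas = 64, patch_size = 32, vocab_size = 2,
                       backend = deep_backend("stub", dim = 16))
  rep <- kfold_evaluate(man, p, eval_protocol(K = 3, repetitions = 2, seed = 5))
  out <- file.path(d, "report.csv")
  fig <- file.path(d, "sheet.png")
  localization_report(rep, out, figure_path = fig)
  back <- utils::read.csv(out, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 6 * 2)  # each image tested once per repetition
  expect_equal(back, rep$predictions, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(back$predicted == back$truth))  # separable run is all-correct
  expect_true(file.exists(fig))
})

test_that("impossible protocols fail loudly", {
  d <- withr::local_tempdir()
  man <- small_dataset(d, n = 1, canvas = 64, seed = 29)
  p <- pipeline_params(canvas = 64, patch_size = 32, vocab_size = 1,
                       backend = deep_backend("stub", dim = 8))
  expect_error(kfold_evaluate(man, p, eval_protocol(K = 4, seed = 1)),
               "at least K images")
  expect_error(eval_protocol(K = 1), "K must be")
})
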