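# Small separable feature table shared across ML tests: AFIB frames carry
# much larger short-term variability, mirroring what the real features do.
make_rows <- function(n_subjects = 10, frames_each = 12, seed = 1,
                      shuffle_labels = FALSE) {
  afibkit:::with_local_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      lab <- if (i %% 2 == 0) "AFIB" else "NSR"
      base_rmssd <- if (lab == "AFIB") rnorm(1, 180, 15) else rnorm(1, 25, 5)
      nnm <- rnorm(1, 800, 60)
      rmssd <- abs(rnorm(frames_each, base_rmssd, 8))
      sdnn <- rmssd / sqrt(2)
      data.frame(
        hrmad = sdnn * 0.8, rmssd = rmssd, iqrnn = sdnn * 1.35,
        mcvnn = sdnn * 0.8 / nnm, cvnn = sdnn / nnm, cvsd = rmssd / nnm,
        hti = if (lab == "AFIB") runif(frames_each, 6, 12)
              else runif(frames_each, 1, 4),
        label = lab, subject_id = sprintf("P%02d", i),
        block_id = sprintf("P%02d_b", i),
        frame_start_s = 2 * seq_len(frames_each),
        stringsAsFactors = FALSE
      )
    }))
    if (shuffle_labels) rows$label <- sample(rows$label)
    rows
  })
}

test_that("splits are subject-wise, deterministic and leak-free", {
  rows <- make_rows(10)
  plan <- make_split(rows, 0.6, seed = 7)
  expect_length(plan$train_subjects, 6)
  expect_length(plan$test_subjects, 4)
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_setequal(c(plan$train_subjects, plan$test_subjects),
                  unique(rows$subject_id))
  plan2 <- make_split(rows, 0.6, seed = 7)
  expect_identical(plan, plan2)
  expect_equal(check_split_leakage(rows, plan), 0)
  expect_error(make_split(rows[rows$subject_id == "P01", ], 0.6, 1),
               "at least 2")
})

test_that("subject frame counts decouple subject and row fractions", {
  rows <- make_rows(10)
  # give one subject far more rows
  extra <- rows[rows$subject_id == "P01", ][rep(1:12, 10), ]
  rows2 <- rbind(rows, extra)
  plan <- make_split(rows2, 0.6, seed = 3)
  train_rows <- mean(rows2$subject_id %in% plan$train_subjects)
  expect_false(isTRUE(all.equal(train_rows, 0.6, tolerance = 0.01)))
})

test_that("all three learners separate the synthetic feature classes", {
  rows <- make_rows(10)
  plan <- make_split(rows, 0.6, seed = 5)
  test_rows <- rows[rows$subject_id %in% plan$test_subjects, ]
  for (m in c("rf", "svm", "knn")) {
    fit <- afib_train(rows, plan, m, seed = 5)
    preds <- predict_frames(fit, test_rows)
    acc <- mean(preds$predicted == preds$label)
    expect_gt(acc, 0.95)
    expect_true(all(preds$score >= 0 & preds$score <= 1))
  }
})

test_that("shuffled labels give chance-level accuracy", {
  rows <- make_rows(20, frames_each = 10, shuffle_labels = TRUE, seed = 13)
  plan <- make_split(rows, 0.6, seed = 13)
  fit <- afib_train(rows, plan, "rf", seed = 13)
  test_rows <- rows[rows$subject_id %in% plan$test_subjects, ]
  preds <- predict_frames(fit, test_rows)
  acc <- mean(preds$predicted == preds$label)
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("training input is validated", {
  rows <- make_rows(6)
  plan <- make_split(rows, 0.6, seed = 2)
  single <- rows[rows$label == "NSR", ]
  expect_error(afib_train(single, plan, "rf"), "both classes")
  empty_plan <- plan
  empty_plan$train_subjects <- character(0)
  expect_error(afib_train(rows, empty_plan, "rf"), "empty training set")
  fit <- afib_train(rows, plan, "rf", seed = 2)
  bad <- rows[rows$subject_id %in% plan$test_subjects, ]
  bad$rmssd[1] <- NA
  expect_error(predict_frames(fit, bad), "non-finite")
  nocol <- rows[, setdiff(names(rows), "hti")]
  expect_error(predict_frames(fit, nocol), "missing feature")
})

test_that("prediction is deterministic and handles empty input", {
  rows <- make_rows(8)
  plan <- make_split(rows, 0.6, seed = 4)
  fit <- afib_train(rows, plan, "rf", seed = 4)
  test_rows <- rows[rows$subject_id %in% plan$test_subjects, ]
  p1 <- predict_frames(fit, test_rows)
  p2 <- predict_frames(fit, test_rows)
  expect_identical(p1, p2)
  p0 <- predict_frames(fit, test_rows[0, ])
  expect_equal(nrow(p0), 0)
  # identical rows get identical predictions
  dup <- test_rows[c(1, 1, 1), ]
  pd <- predict_frames(fit, dup)
  expect_length(unique(pd$predicted), 1)
})

test_that("model archives round-trip through disk", {
  rows <- make_rows(6)
  plan <- make_split(rows, 0.6, seed = 9)
  fit <- afib_train(rows, plan, "rf", seed = 9)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, f)
  back <- load_model(f)
  expect_equal(back$feature_order, hrv_feature_names())
  test_rows <- rows[rows$subject_id %in% plan$test_subjects, ]
  expect_identical(predict_frames(back, test_rows),
                   predict_frames(fit, test_rows))
  saveRDS(list(), f)
  expect_error(load_model(f), "archive")
})

test_that("majority voting follows the tie rule and never degrades a good block", {
  mk <- function(block, labels) {
    data.frame(predicted = labels, score = 0.5, block_id = block,
               label = "AFIB", stringsAsFactors = FALSE)
  }
  v1 <- vote_samples(mk("b1", c("AFIB", "AFIB", "NSR")))
  expect_equal(v1$predicted, "AFIB")
  v2 <- vote_samples(mk("b2", rep("NSR", 5)))
  expect_equal(v2$predicted, "NSR")
  # exact tie defaults to AFIB, configurable to NSR
  v3 <- vote_samples(mk("b3", c("AFIB", "NSR")))
  expect_equal(v3$predicted, "AFIB")
  v4 <- vote_samples(mk("b4", c("AFIB", "NSR")), tie = "NSR")
  expect_equal(v4$predicted, "NSR")
  empty <- data.frame(predicted = character(0), score = numeric(0),
                      block_id = character(0), stringsAsFactors = FALSE)
  expect_error(vote_samples(empty), "no frame")

  # any block whose frames are >= 60% correct is voted correctly
  set.seed(31)
  for (i in 1:30) {
    n <- sample(3:25, 1)
    truth_lab <- sample(c("NSR", "AFIB"), 1)
    other <- setdiff(c("NSR", "AFIB"), truth_lab)
    n_ok <- ceiling(0.6 * n)
    labels <- sample(c(rep(truth_lab, n_ok), rep(other, n - n_ok)))
    v <- vote_samples(data.frame(predicted = labels, score = 0.5,
                                 block_id = "blk", label = truth_lab,
                                 stringsAsFactors = FALSE))
    expect_equal(v$predicted, truth_lab)
  }
})
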