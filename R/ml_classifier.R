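# Frame-level classifiers on HRV features with subject-wise splitting and
# per-sample vote aggregation.

#' Subject-wise train/test split
#'
#' Splits by subject, never by row, so no individual contributes frames to
#' both sides. Because subjects carry different numbers of frames, 60% of
#' the subjects generally does not equal 60% of the rows. Deterministic
#' given the seed.
#'
#' @param rows a feature table from [extract_dataset()].
#' @param fraction fraction of subjects assigned to training.
#' @param seed integer seed.
#' @return object of class `split_plan`: `train_subjects`,
#'   `test_subjects`, `fraction`, `seed`.
#' @export
make_split <- function(rows, fraction = 0.6, seed) {
  stopifnot(fraction > 0, fraction < 1)
  subjects <- sort(unique(rows$subject_id))
  if (length(subjects) < 2) stop("need at least 2 subjects", call. = FALSE)
  n_train <- max(1L, min(length(subjects) - 1L,
                         round(fraction * length(subjects))))
  train <- with_local_seed(seed, sort(sample(subjects, n_train)))
  structure(
    list(train_subjects = train,
         test_subjects = setdiff(subjects, train),
         fraction = fraction, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test subjects (fraction %g, seed %d)\n",
              length(x$train_subjects), length(x$test_subjects), x$fraction,
              x$seed))
  invisible(x)
}

#' Check a split for subject leakage
#'
#' @param rows a feature table.
#' @param plan a [make_split()] plan.
#' @return number of subjects appearing on both sides (0 when clean).
#' @export
check_split_leakage <- function(rows, plan) {
  both <- intersect(plan$train_subjects, plan$test_subjects)
  seen <- unique(rows$subject_id)
  length(intersect(seen, both))
}

feature_matrix <- function(rows) {
  missing_cols <- setdiff(hrv_feature_names(), names(rows))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(rows[, hrv_feature_names()])
  if (anyNA(m) || any(!is.finite(m))) {
    stop("feature matrix contains non-finite values", call. = FALSE)
  }
  m
}

#' Train a frame-level classifier
#'
#' Fits one of three learners on the training-subject rows: random forest
#' (300 trees), RBF support vector machine, or k-nearest neighbours
#' (k = 15). For SVM and KNN the features are standardized with
#' mean/SD fitted on the training rows only; the scaler and the frozen
#' feature order travel with the model. The random forest's bootstrap
#' uses `seed`.
#'
#' @param rows feature table from [extract_dataset()].
#' @param plan a [make_split()] plan.
#' @param model "rf", "svm" or "knn".
#' @param cfg an [afib_config()] (hyperparameters).
#' @param seed integer seed for the learner's randomness.
#' @return object of class `afib_model`.
#' @export
afib_train <- function(rows, plan, model = c("rf", "svm", "knn"),
                       cfg = afib_config(), seed = 1) {
  model <- match.arg(model)
  tr <- rows[rows$subject_id %in% plan$train_subjects, , drop = FALSE]
  if (!nrow(tr)) stop("empty training set", call. = FALSE)
  y <- factor(tr$label, levels = c("NSR", "AFIB"))
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  X <- feature_matrix(tr)
  scaler <- list(center = colMeans(X), scale = apply(X, 2, sd))
  scaler$scale[scaler$scale == 0] <- 1
  fit <- switch(model,
    rf = with_local_seed(seed, randomForest::randomForest(
      X, y, ntree = cfg$rf_ntree)),
    svm = {
      Xs <- scale(X, scaler$center, scaler$scale)
      with_local_seed(seed, e1071::svm(
        Xs, y, kernel = "radial", cost = cfg$svm_cost, probability = TRUE))
    },
    knn = {
      Xs <- scale(X, scaler$center, scaler$scale)
      list(train_x = Xs, train_y = y, k = cfg$knn_k)
    }
  )
  structure(
    list(model = model, fit = fit, scaler = scaler,
         feature_order = hrv_feature_names(), levels = c("NSR", "AFIB"),
         seed = as.integer(seed), version = "1",
         config_hash = digest_config(cfg)),
    class = "afib_model"
  )
}

digest_config <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                character(1)), sep = "=", collapse = ";")
  # small rolling hash; enough to detect config drift in saved models
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' @export
print.afib_model <- function(x, ...) {
  cat(sprintf("<afib_model> %s (features: %s)\n", toupper(x$model),
              paste(x$feature_order, collapse = ", ")))
  invisible(x)
}

#' Save / load a fitted model
#'
#' The archive is a versioned RDS holding the fitted learner, frozen
#' feature order, scaler and config hash.
#'
#' @param model an [afib_train()] result.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "afib_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "afib_model")) stop("not an afib model archive",
                                       call. = FALSE)
  m
}

#' Predict a label for every frame
#'
#' @param model an [afib_train()] result.
#' @param rows feature table rows to score.
#' @return `data.frame`: `predicted` ("NSR"/"AFIB"), `score` (positive-class
#'   probability), plus `label`, `subject_id`, `block_id` carried over when
#'   present.
#' @export
predict_frames <- function(model, rows) {
  carry <- intersect(c("label", "subject_id", "block_id", "frame_start_s"),
                     names(rows))
  if (!nrow(rows)) {
    return(cbind(data.frame(predicted = character(0), score = numeric(0)),
                 rows[, carry, drop = FALSE]))
  }
  X <- feature_matrix(rows)[, model$feature_order, drop = FALSE]
  if (model$model == "rf") {
    prob <- predict(model$fit, X, type = "prob")[, "AFIB"]
  } else if (model$model == "svm") {
    Xs <- scale(X, model$scaler$center, model$scaler$scale)
    pr <- predict(model$fit, Xs, probability = TRUE)
    prob <- attr(pr, "probabilities")[, "AFIB"]
  } else {
    Xs <- scale(X, model$scaler$center, model$scaler$scale)
    pred <- class::knn(model$fit$train_x, Xs, model$fit$train_y,
                       k = model$fit$k, prob = TRUE)
    win <- attr(pred, "prob")
    prob <- ifelse(pred == "AFIB", win, 1 - win)
  }
  out <- data.frame(predicted = ifelse(prob > 0.5, "AFIB", "NSR"),
                    score = as.numeric(prob), stringsAsFactors = FALSE)
  # exact knn ties (prob 0.5) fall to the sensitivity-favouring side
  out$predicted[prob == 0.5] <- "AFIB"
  cbind(out, rows[, carry, drop = FALSE])
}

#' Aggregate frame predictions to one label per sample
#'
#' Majority vote over each block's frame predictions; an exact tie goes to
#' AFIB by default (a screening context favours sensitivity; configurable
#' via `tie`).
#'
#' @param preds frame predictions from [predict_frames()] carrying
#'   `block_id`.
#' @param tie label assigned at exactly half AFIB votes.
#' @return `data.frame`: `block_id`, `predicted`, `n_frames`,
#'   `n_afib_frames`, plus `label` and `subject_id` when present.
#' @export
vote_samples <- function(preds, tie = "AFIB") {
  stopifnot(tie %in% c("AFIB", "NSR"))
  if (!nrow(preds)) stop("no frame predictions to vote on", call. = FALSE)
  if (is.null(preds$block_id)) stop("predictions lack block_id", call. = FALSE)
  pieces <- split(preds, preds$block_id)
  out <- do.call(rbind, lapply(pieces, function(p) {
    n <- nrow(p)
    n_afib <- sum(p$predicted == "AFIB")
    lab <- if (n_afib * 2 > n) "AFIB"
           else if (n_afib * 2 == n) tie
           else "NSR"
    row <- data.frame(block_id = p$block_id[1], predicted = lab,
                      n_frames = n, n_afib_frames = n_afib,
                      stringsAsFactors = FALSE)
    if (!is.null(p$label)) row$label <- p$label[1]
    if (!is.null(p$subject_id)) row$subject_id <- p$subject_id[1]
    row
  }))
  rownames(out) <- NULL
  out
}
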