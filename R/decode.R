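#' Stratified half split of labeled population responses
#'
#' Splits trials into train and test halves with the same odor composition:
#' within each odor, `floor(n/2)` trials are drawn at random for training and
#' the rest held out, so every odor appears in both halves.
#'
#' @param features Trials x units numeric matrix.
#' @param labels Odor label per trial (integer or factor-like).
#' @param split_seed Integer seed; the partition is deterministic given it.
#' @return List with `train` and `test`, each a list of `x` (matrix) and `y`.
#' @export
split_half <- function(features, labels, split_seed = 1L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every odor needs at least 2 trials to appear in both halves")
  }
  set.seed(child_seed(split_seed, "half-split"))
  by_class <- split(seq_along(labels), labels)
  train_idx <- sort(unlist(lapply(by_class, function(ix) {
    sample(ix, floor(length(ix) / 2))
  }), use.names = FALSE))
  list(
    train = list(x = features[train_idx, , drop = FALSE],
                 y = labels[train_idx]),
    test = list(x = features[-train_idx, , drop = FALSE],
                y = labels[-train_idx])
  )
}

#' Train a Gaussian naive Bayes classifier
#'
#' Fits an independent Gaussian per class and feature (maximum-likelihood
#' mean and variance) with uniform class priors. Variances below `var_floor`
#' (e.g. for units silent in every training trial of a class) are floored.
#'
#' @param x Train trials x units matrix.
#' @param y Class label per train trial; >= 2 trials per class.
#' @param var_floor Variance floor in Hz^2.
#' @param warn Warn when any variance is floored.
#' @return A `gnb_model` with `classes`, `means`, `vars` (classes x units),
#'   `log_prior`, and `n_floored`.
#' @export
train_gnb <- function(x, y, var_floor = 1e-6, warn = TRUE) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.character(y)
  counts <- table(y)
  if (any(counts < 2L)) stop("need at least 2 training trials per class")
  classes <- names(counts)
  n_k <- as.numeric(counts[classes])
  means <- rowsum(x, y)[classes, , drop = FALSE] / n_k
  vars <- rowsum(x^2, y)[classes, , drop = FALSE] / n_k - means^2
  vars <- pmax(vars, 0) # guard tiny negative values from cancellation
  n_floored <- sum(vars < var_floor)
  if (n_floored > 0L) {
    vars[vars < var_floor] <- var_floor
    if (warn) {
      warning(n_floored, " class-feature variance(s) floored at ", var_floor)
    }
  }
  structure(list(classes = classes, means = means, vars = vars,
                 log_prior = rep(-log(length(classes)), length(classes)),
                 var_floor = var_floor, n_features = ncol(x),
                 n_floored = n_floored),
            class = "gnb_model")
}

#' Predict class labels from a Gaussian naive Bayes model
#'
#' @param model A `gnb_model` from [train_gnb()].
#' @param x Test trials x units matrix with the same feature ordering used
#'   in training.
#' @return Character vector of predicted class labels.
#' @export
predict_gnb <- function(model, x) {
  stopifnot(inherits(model, "gnb_model"), is.matrix(x))
  if (ncol(x) != model$n_features) {
    stop("feature count mismatch: model has ", model$n_features,
         ", data has ", ncol(x))
  }
  k <- length(model$classes)
  ll <- matrix(0, nrow(x), k)
  x2 <- x^2
  for (j in seq_len(k)) {
    iv <- 1 / model$vars[j, ]
    m <- model$means[j, ]
    ll[, j] <- -0.5 * (x2 %*% iv - 2 * (x %*% (m * iv)) +
                         sum(m^2 * iv) + sum(log(model$vars[j, ]))) +
      model$log_prior[j]
  }
  model$classes[max.col(ll, ties.method = "first")]
}

#' Classification accuracy on held-out trials
#'
#' @param model A `gnb_model`.
#' @param x,y Test features and labels.
#' @return Fraction of correctly identified trials, in `[0, 1]`.
#' @export
gnb_accuracy <- function(model, x, y) {
  mean(predict_gnb(model, x) == as.character(y))
}

# LDA backend used for sensitivity analysis; near-constant features are
# dropped before fitting since lda() rejects within-group-constant variables
.lda_accuracy <- function(train, test, tol = 1e-8) {
  keep <- apply(train$x, 2, stats::sd) > tol
  if (!any(keep)) return(1 / length(unique(train$y)))
  fit <- suppressWarnings(
    MASS::lda(train$x[, keep, drop = FALSE], grouping = factor(train$y))
  )
  pred <- stats::predict(fit, test$x[, keep, drop = FALSE])$class
  mean(as.character(pred) == as.character(test$y))
}

#' Half-split decoding accuracy for one panel of responses
#'
#' Convenience wrapper: stratified half split, train, and score.
#'
#' @param features Trials x units matrix of steady-state rates.
#' @param labels Odor label per trial.
#' @param split_seed Seed for the split.
#' @param classifier `"gnb"` (default) or `"lda"`.
#' @return Fraction correct on the held-out half.
#' @export
decode_accuracy <- function(features, labels, split_seed = 1L,
                            classifier = c("gnb", "lda")) {
  classifier <- match.arg(classifier)
  halves <- split_half(features, labels, split_seed)
  if (classifier == "lda") {
    return(.lda_accuracy(halves$train, halves$test))
  }
  model <- train_gnb(halves$train$x, halves$train$y, warn = FALSE)
  gnb_accuracy(model, halves$test$x, halves$test$y)
}
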