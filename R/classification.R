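# Cohort-membership classification harness: stratified splitting, repeated
# cross-validation and ROC/AUC. The base learner is pluggable; the default
# is a bagged random forest.

#' Stratified train/test split
#'
#' Splits samples into train and test sets preserving class proportions.
#' Per class, `floor(train_frac * n_class)` samples go to train; remaining
#' whole samples implied by rounding are assigned to the classes with the
#' largest fractional parts, so per-class train counts are within one sample
#' of `train_frac * n_class`.
#'
#' @param samples character vector of sample ids.
#' @param labels class label per sample.
#' @param train_frac fraction in (0, 1); default 0.70.
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(samples, labels, train_frac = 0.70, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    rlang::abort("train_frac must be strictly between 0 and 1")
  labels <- as.factor(labels)
  if (nlevels(labels) < 2 || any(table(labels) < 2))
    rlang::abort("need >= 2 classes with >= 2 samples each")
  n_by <- table(labels)
  exact <- train_frac * as.numeric(n_by)
  base <- floor(exact)
  extra <- round(sum(exact)) - sum(base)
  if (extra > 0) {
    give <- order(exact - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  train <- with_seed(seed, {
    unlist(lapply(seq_along(n_by), function(i) {
      ids <- samples[labels == names(n_by)[i]]
      sample(ids, base[i])
    }))
  })
  list(train = train, test = setdiff(samples, train))
}

#' Default bagged random-forest learner
#'
#' Returns a learner function for [repeated_cv()]: trained on a features x
#' samples matrix subset, it yields a scoring function giving the
#' probability of the first class level.
#'
#' @param ntree trees per forest; default 200.
#' @return a function `(x_train, y_train) -> function(x_new) -> scores`.
#' @export
rf_learner <- function(ntree = 200) {
  function(x_train, y_train) {
    y_train <- droplevels(as.factor(y_train))
    fit <- randomForest::randomForest(x_train, y_train, ntree = ntree)
    ref <- levels(y_train)[1]
    function(x_new) {
      pr <- stats::predict(fit, x_new, type = "prob")
      as.numeric(pr[, ref])
    }
  }
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin, so per-fold class proportions are within 1 of global
.stratified_folds <- function(labels, folds) {
  out <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- sample(which(labels == lv))
    out[idx] <- rep_len(seq_len(folds), length(idx))
  }
  out
}

#' Repeated stratified cross-validation
#'
#' `repeats` rounds of `folds`-fold stratified CV (default 10 x 10 = 100
#' model fits). Out-of-fold scores are pooled per repeat into one AUC. The
#' final model is refit on the full training data.
#'
#' @param x features x samples numeric matrix.
#' @param labels two-level class per sample.
#' @param folds,repeats CV design; defaults 10 and 10.
#' @param learner a learner factory as from [rf_learner()].
#' @param seed integer seed.
#' @return list with `auc_per_repeat`, `auc_mean`, `auc_sd`, `scores`
#'   (pooled out-of-fold scores, last repeat), and `model` (the refit
#'   scoring function).
#' @export
repeated_cv <- function(x, labels, folds = 10, repeats = 10,
                        learner = rf_learner(), seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (folds > length(labels))
    rlang::abort("more folds than samples")
  xt <- t(x)  # samples x features for the learner
  n <- nrow(xt)
  aucs <- numeric(repeats)
  scores <- numeric(n)
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      fold <- .stratified_folds(labels, folds)
      for (f in seq_len(folds)) {
        tr <- fold != f
        score_fun <- learner(xt[tr, , drop = FALSE], labels[tr])
        scores[!tr] <- score_fun(xt[!tr, , drop = FALSE])
      }
      aucs[r] <- roc_auc(scores, labels)$auc
    }
  })
  final <- learner(xt, labels)
  list(auc_per_repeat = aucs, auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
       scores = scores, model = final)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores; the positive class is the
#' first factor level of `labels` (higher scores = more positive). The AUC
#' is the trapezoidal integral of the curve, identical to the normalised
#' Mann-Whitney U statistic with the mid-rank tie convention.
#'
#' @param scores numeric classifier scores.
#' @param labels two-level class per score.
#' @return a `roc_result`: `curve` (tibble `threshold`, `fpr`, `tpr`),
#'   `auc`, `auc_u` (U-statistic form, equal to `auc`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) rlang::abort("need scores from both classes")
  pos <- labels == levels(labels)[1]
  np <- sum(pos); nn <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # collapse tied thresholds
  last <- cumsum(rle(s)$lengths)
  tpr <- c(0, cumsum(y)[last] / np)
  fpr <- c(0, cumsum(!y)[last] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  # U-statistic with mid-rank ties
  r <- rank(scores, ties.method = "average")
  u <- sum(r[pos]) - np * (np + 1) / 2
  curve <- tibble::tibble(threshold = c(Inf, s[last]), fpr = fpr, tpr = tpr)
  structure(list(curve = curve, auc = auc, auc_u = u / (np * nn),
                 n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f (%d pos / %d neg)>\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_u = x$auc_u, n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' @describeIn roc_auc ROC curve plot.
#' @param object a `roc_result`.
#' @param ... unused.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Full classification workflow for a two-cohort table
#'
#' Stratified 70:30 split, repeated stratified CV on the training set, and
#' a held-out test AUC from the refit model.
#'
#' @param table an [abundance_table()] (counts or relative).
#' @param labels class per sample (named by sample id or in column order).
#' @inheritParams repeated_cv
#' @param train_frac training fraction; default 0.70.
#' @return list with `split`, `cv` (from [repeated_cv()]), `test_roc` (a
#'   [roc_auc()] result on the test set) and `summary` (one-row tibble).
#' @export
classify_cohorts <- function(table, labels, train_frac = 0.70, folds = 10,
                             repeats = 10, learner = rf_learner(),
                             seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (!is.null(names(labels))) labels <- labels[colnames(v)]
  labels <- droplevels(as.factor(labels))
  split <- stratified_split(colnames(v), labels, train_frac, seed = seed)
  tr_idx <- match(split$train, colnames(v))
  te_idx <- match(split$test, colnames(v))
  cv <- repeated_cv(v[, tr_idx, drop = FALSE], labels[tr_idx],
                    folds = folds, repeats = repeats, learner = learner,
                    seed = seed + 1L)
  test_scores <- cv$model(t(v[, te_idx, drop = FALSE]))
  test_roc <- roc_auc(test_scores, labels[te_idx])
  list(split = split, cv = cv, test_roc = test_roc,
       summary = tibble::tibble(cv_auc_mean = cv$auc_mean,
                                cv_auc_sd = cv$auc_sd,
                                test_auc = test_roc$auc,
                                n_train = length(split$train),
                                n_test = length(split$test)))
}
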