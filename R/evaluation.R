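# Stratified k-fold evaluation: confusion matrix, per-class accuracy,
# one-vs-rest ROC.  Feature selection and standardization are refit
# inside each training fold so no statistic ever sees held-out data.

#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param y_true,y_pred integer labels in 1..n_classes.
#' @param n_classes matrix dimension.
#' @return A `confusion_matrix` (integer matrix with class dimnames).
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = N_VOWEL_CLASSES) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (any(c(y_true, y_pred) < 1 | c(y_true, y_pred) > n_classes))
    stop("labels outside 1..", n_classes)
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class accuracy (percent)
#'
#' `100 * diagonal / row sum`; a class with no trials reports `NA`
#' rather than crashing.
#' @param cm a `confusion_matrix`.
#' @return numeric vector of percentages (NA for empty classes).
#' @export
per_class_accuracy <- function(cm) {
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, 100 * diag(cm) / rs, NA_real_)
  names(out) <- rownames(cm)
  out
}

#' Overall accuracy (percent)
#' @param cm a `confusion_matrix`.
#' @return `100 * trace / total`.
#' @export
overall_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' One-vs-rest ROC curves
#'
#' For each class the class-column score is swept over its sorted unique
#' values as thresholds; curves run from (0,0) to (1,1) and are monotone
#' staircases.  AUC is computed by the rank (Mann-Whitney) identity.
#'
#' @param scores matrix (samples x n_classes) of continuous scores.
#' @param y_true integer labels.
#' @return list of `roc_curve` objects (fpr, tpr, thresholds, auc,
#'   defined); a class absent from `y_true` is flagged undefined.
#' @export
roc_one_vs_rest <- function(scores, y_true) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  n_classes <- ncol(scores)
  lapply(seq_len(n_classes), function(k) {
    s <- scores[, k]
    pos <- y_true == k
    np <- sum(pos); nn <- sum(!pos)
    if (np == 0 || nn == 0) {
      return(structure(list(fpr = c(0, 1), tpr = c(0, 1),
                            thresholds = c(Inf, -Inf), auc = NA,
                            class_id = k, defined = FALSE),
                       class = "roc_curve"))
    }
    o <- order(s, decreasing = TRUE)
    tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
    # collapse threshold ties: keep last point of each distinct score
    keep <- c(diff(s[o]) != 0, TRUE)
    tpr <- c(0, tp[keep] / np); fpr <- c(0, fp[keep] / nn)
    auc <- (mean(rank(s)[pos]) - (np + 1) / 2) / nn
    structure(list(fpr = fpr, tpr = tpr,
                   thresholds = c(Inf, s[o][keep]), auc = auc,
                   class_id = k, defined = TRUE),
              class = "roc_curve")
  })
}

#' Fold assignment: class-stratified or group-wise
#'
#' Default is stratified by class.  If `groups` is given (e.g. subject
#' ids), whole groups are assigned to folds so no group straddles a
#' train/test boundary — the leave-subjects-out protocol.
#'
#' @param y labels.
#' @param k_folds number of folds.
#' @param seed RNG seed.
#' @param groups optional group id per sample.
#' @return integer fold id per sample.
#' @export
make_folds <- function(y, k_folds = 10, seed = 1, groups = NULL) {
  n <- length(y)
  withr_seed(seed, {
    if (!is.null(groups)) {
      stopifnot(length(groups) == n)
      ug <- unique(groups)
      if (length(ug) < k_folds)
        stop("need at least k_folds distinct groups for group-wise folds")
      gf <- rep_len(sample(k_folds), length(ug))[sample(length(ug))]
      return(gf[match(groups, ug)])
    }
    fold <- integer(n)
    for (g in split(seq_len(n), y)) {
      g <- sample(g)
      fold[g] <- rep_len(sample(k_folds), length(g))
    }
    fold
  })
}

#' Cross-validated pipeline evaluation
#'
#' Outer stratified k-fold drives the reported accuracy; inside each
#' training fold, mRMR selection (k features) is refit and the network is
#' trained with its own internal 70/15/15 split for early stopping, then
#' evaluated once on the held-out fold.  Standardization lives inside
#' [train_scg()] and also only sees training-fold data.
#'
#' @param features numeric matrix (trials x 57).
#' @param labels integer class labels.
#' @param n_select number of mRMR-selected features per fold.
#' @param k_folds number of outer folds.
#' @param seed seed for fold assignment, network init and splits.
#' @param tc a [train_config()] for the inner training runs.
#' @param n_classes number of classes.
#' @param fixed_selection optionally a fixed integer vector of feature
#'   indices, bypassing per-fold mRMR (the simpler protocol reading).
#' @param groups optional group (subject) id per trial; folds then keep
#'   whole groups together (subject-wise CV, `k_folds` <= n groups).
#' @return A `cv_result`: per-fold accuracy, pooled confusion matrix,
#'   mean/sd accuracy, per-class accuracy, fold assignment, ROC curves,
#'   per-fold selections.
#' @export
cross_validate <- function(features, labels, n_select = 12, k_folds = 10,
                           seed = 1, tc = NULL,
                           n_classes = max(labels),
                           fixed_selection = NULL, groups = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (is.null(groups) && min(table(labels)) < k_folds)
    stop("need at least k_folds trials per class for stratification")
  if (is.null(tc)) tc <- train_config(seed = seed)
  fold <- make_folds(labels, k_folds, seed = seed, groups = groups)
  y_pred <- integer(n)
  scores <- matrix(NA_real_, n, n_classes)
  fold_acc <- numeric(k_folds)
  selections <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    sel <- if (is.null(fixed_selection)) {
      mrmr_rank(features[tr, , drop = FALSE], labels[tr],
                k = n_select)$ranked_indices
    } else fixed_selection
    selections[[f]] <- sel
    cfg <- network_config(length(sel), n_outputs = n_classes,
                          seed = seed + f)
    tcf <- tc; tcf$seed <- seed + 1000 + f
    model <- init_network(cfg)
    model <- train_scg(model, features[tr, sel, drop = FALSE], labels[tr],
                       tcf)
    pr <- predict_network(model, features[te, sel, drop = FALSE])
    y_pred[te] <- pr$labels
    scores[te, ] <- pr$scores
    fold_acc[f] <- 100 * mean(pr$labels == labels[te])
  }
  cm <- confusion_matrix(labels, y_pred, n_classes)
  structure(list(fold_accuracy = fold_acc,
                 confusion = cm,
                 mean_accuracy = mean(fold_acc),
                 sd_accuracy = stats::sd(fold_acc),
                 overall_accuracy = overall_accuracy(cm),
                 per_class_accuracy = per_class_accuracy(cm),
                 folds = fold, seed = seed,
                 roc = roc_one_vs_rest(scores, labels),
                 selections = selections),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Stratified ", length(x$fold_accuracy), "-fold cross-validation\n",
      sep = "")
  cat(sprintf("  pooled accuracy: %.2f %%\n", x$overall_accuracy))
  cat(sprintf("  per-fold mean +/- sd: %.2f +/- %.2f %%\n",
              x$mean_accuracy, x$sd_accuracy))
  cat("  per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 1))
  invisible(x)
}
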