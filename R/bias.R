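#' Sine/cosine phase features
#'
#' Expands each phase column into its sine and cosine components, making the
#' feature representation continuous on the circle (invariant to adding
#' 2 pi).
#'
#' @param phases data.frame or matrix of phases (rad), one column per limb
#'   pair.
#' @return numeric matrix with columns \code{sin_<col>} and
#'   \code{cos_<col>}.
#' @export
phase_features <- function(phases) {
  M <- as.matrix(as.data.frame(phases))
  out <- do.call(cbind, lapply(colnames(M), function(cn)
    cbind(sin(M[, cn]), cos(M[, cn]))))
  colnames(out) <- as.vector(t(outer(colnames(M), c("sin_", "cos_"),
                                     function(a, b) paste0(b, a))))
  out
}

# balanced subsample: equal label counts within each mouse
.balance_indices <- function(labels, mouse, idx) {
  keep <- integer(0)
  for (m in unique(mouse[idx])) {
    im <- idx[mouse[idx] == m]
    tab <- split(im, labels[im])
    tab <- tab[lengths(tab) > 0]
    # order groups by content, not label name, so mirrored relabelings
    # consume the RNG identically
    tab <- tab[order(vapply(tab, min, numeric(1)))]
    if (length(tab) < 2) { keep <- c(keep, im); next }
    n_min <- min(lengths(tab))
    for (cls in names(tab))
      keep <- c(keep, if (length(tab[[cls]]) > n_min)
        sample(tab[[cls]], n_min) else tab[[cls]])
  }
  sort(keep)
}

#' Train a stimulation-side classifier on phase features
#'
#' Linear support-vector classifier predicting a binary label (side of
#' stimulation) from sine/cosine phase features. Data are split 75/25 into
#' train and test, stratified by mouse and label; the training partition is
#' balanced by subsampling to equal label counts within each mouse.
#' Held-out accuracy and an ROC curve from the decision values are
#' reported.
#'
#' @param features numeric matrix from [phase_features()].
#' @param labels binary labels (factor or coercible), both classes present.
#' @param mouse per-observation mouse ids (at least 2 mice).
#' @param split training fraction (default 0.75).
#' @param seed integer seed.
#' @param kernel SVM kernel (default \code{"linear"}).
#' @param cost SVM cost parameter.
#' @return list of class \code{"bias_result"}: \code{accuracy},
#'   \code{roc_points} (data.frame fpr/tpr), \code{auc}, \code{n_train},
#'   \code{n_test}, \code{model}. The permutation p-value is added by
#'   [permutation_test()].
#' @export
train_side_classifier <- function(features, labels, mouse, split = 0.75,
                                  seed = 1L, kernel = "linear", cost = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("both classes must be present")
  if (length(unique(mouse)) < 2) stop("need at least 2 mice")
  set.seed(seed)
  n <- nrow(features)
  strata <- interaction(mouse, labels, drop = TRUE)
  groups <- split(seq_len(n), strata)
  groups <- groups[order(vapply(groups, min, numeric(1)))] # label-symmetric order
  train_idx <- unlist(lapply(groups, function(ii) {
    k <- max(1L, round(split * length(ii)))
    if (length(ii) == 1) ii else sample(ii, k)
  }))
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0) stop("no held-out observations; reduce split")
  train_idx <- .balance_indices(labels, mouse, train_idx)

  fit <- e1071::svm(x = features[train_idx, , drop = FALSE],
                    y = labels[train_idx], kernel = kernel, cost = cost,
                    scale = TRUE)
  pred <- predict(fit, features[test_idx, , drop = FALSE], decision.values = TRUE)
  acc <- mean(pred == labels[test_idx])
  dv <- as.numeric(attr(pred, "decision.values"))
  roc <- suppressMessages(pROC::roc(labels[test_idx], dv, quiet = TRUE,
                                    direction = "auto"))
  structure(list(
    accuracy = acc,
    roc_points = data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities),
    auc = as.numeric(pROC::auc(roc)),
    n_train = length(train_idx), n_test = length(test_idx),
    model = fit, seed = seed, split = split
  ), class = "bias_result")
}

#' @exportS3Method base::print
print.bias_result <- function(x, ...) {
  cat(sprintf("<bias_result: accuracy %.3f (train %d / test %d), AUC %.3f%s>\n",
              x$accuracy, x$n_train, x$n_test, x$auc,
              if (!is.null(x$permutation_p))
                sprintf(", permutation p = %.4g", x$permutation_p) else ""))
  invisible(x)
}

#' Permutation test of classifier accuracy
#'
#' Re-trains the side classifier on label-shuffled data and reports the
#' add-one permutation p-value
#' \code{(1 + #\{perm accuracy >= observed\}) / (1 + n_perm)}, which cannot
#' reach zero.
#'
#' @param features,labels,mouse as in [train_side_classifier()].
#' @param n_perm number of label shuffles (default 1000).
#' @param seed integer seed.
#' @param ... passed to [train_side_classifier()].
#' @return the observed \code{"bias_result"} with elements
#'   \code{permutation_p} and \code{perm_accuracies} added.
#' @export
permutation_test <- function(features, labels, mouse, n_perm = 1000,
                             seed = 1L, ...) {
  obs <- train_side_classifier(features, labels, mouse, seed = seed, ...)
  set.seed(seed + 7L)
  perm_acc <- vapply(seq_len(n_perm), function(b) {
    lb <- sample(labels)
    tryCatch(
      train_side_classifier(features, lb, mouse, seed = seed + b, ...)$accuracy,
      error = function(e) NA_real_)
  }, numeric(1))
  perm_acc <- perm_acc[!is.na(perm_acc)]
  obs$permutation_p <- (1 + sum(perm_acc >= obs$accuracy)) / (1 + length(perm_acc))
  obs$perm_accuracies <- perm_acc
  obs
}
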