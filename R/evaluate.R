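#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence is scored above a randomly
#' chosen (pseudo-)absence, ties counted one half; 0.5 is a random
#' prediction.  Computed from midranks, so it is invariant to any strictly
#' monotone transform of the scores.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

sens_spec_at <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  pos <- labels == 1
  c(sensitivity = sum(pred & pos) / sum(pos),
    specificity = sum(!pred & !pos) / sum(!pos))
}

#' Sensitivity and specificity under a thresholding rule
#'
#' Three rules convert continuous suitability scores into presence/absence
#' classifications: `fixed_0.5` classifies scores >= 0.5 as presence;
#' `sens_eq_spec` picks, among the observed scores, the threshold
#' minimizing `|sensitivity - specificity|` (ties broken toward the lower
#' threshold); `sens_0.95` picks the largest observed-score threshold
#' keeping sensitivity >= 0.95.
#'
#' @inheritParams auc_score
#' @param rule one of `"fixed_0.5"`, `"sens_eq_spec"`, `"sens_0.95"`.
#' @return List with `rule`, `threshold`, `sensitivity`, `specificity`.
#' @export
threshold_metrics <- function(scores, labels,
                              rule = c("fixed_0.5", "sens_eq_spec",
                                       "sens_0.95")) {
  rule <- match.arg(rule)
  labels <- as.integer(as.logical(labels))
  if (!sum(labels == 1) || !sum(labels == 0))
    stop("both classes must be present")
  thr <- switch(rule,
    fixed_0.5 = 0.5,
    sens_eq_spec = {
      cand <- sort(unique(scores))
      gap <- vapply(cand, function(t) {
        ss <- sens_spec_at(scores, labels, t)
        abs(ss[1] - ss[2])
      }, numeric(1))
      cand[which.min(gap)]   # which.min takes the first = lowest threshold
    },
    sens_0.95 = {
      cand <- sort(unique(scores), decreasing = TRUE)
      sens <- vapply(cand, function(t)
        sens_spec_at(scores, labels, t)[1], numeric(1))
      cand[which(sens >= 0.95)[1]]
    })
  ss <- sens_spec_at(scores, labels, thr)
  list(rule = rule, threshold = unname(thr),
       sensitivity = unname(ss[1]), specificity = unname(ss[2]))
}

.threshold_rules <- c("fixed_0.5", "sens_eq_spec", "sens_0.95")

#' Stratified k-fold cross-validation of a seasonal model
#'
#' Rows are partitioned into `k` label-stratified folds.  For each fold the
#' model is refit on the remaining folds with the supplied (pre-selected)
#' term set and the held-out fold is scored with population-level
#' predictions (year random intercept at zero, since validation folds may
#' contain unseen years); AUC and the three thresholded metric pairs are
#' computed per fold.  A randomization that leaves a validation fold with
#' one class is re-drawn once before erroring.
#'
#' @inheritParams fit_sdm
#' @param k number of folds (each class must have >= `k` members).
#' @param seed integer seed for the fold randomization.
#' @return A `cv_report` data.frame (`fold, rule, threshold, auc, sens,
#'   spec`) with a per-rule `summary` attribute of means.
#' @export
cross_validate <- function(data, terms, k = 5, seed = 1L,
                           use_mixed = c("auto", "always", "never")) {
  use_mixed <- match.arg(use_mixed)
  lab <- data$label
  if (min(sum(lab == 1), sum(lab == 0)) < k)
    stop(sprintf("need >= %d members of each class for %d-fold CV", k, k))
  make_folds <- function(s) {
    set.seed(s)
    fold <- integer(nrow(data))
    for (cl in c(0, 1)) {
      idx <- sample(which(lab == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    fold
  }
  fold <- make_folds(seed)
  ok <- function(f) all(vapply(seq_len(k), function(i)
    length(unique(lab[f == i])) == 2, logical(1)))
  if (!ok(fold)) {
    fold <- make_folds(seed + 1L)
    if (!ok(fold)) stop("a validation fold contains a single class")
  }
  rows <- list()
  for (i in seq_len(k)) {
    train <- data[fold != i, , drop = FALSE]
    val <- data[fold == i, , drop = FALSE]
    fit <- fit_sdm(train, terms, use_mixed)
    sc <- predict(fit, val)
    a <- auc_score(sc, val$label)
    for (rule in .threshold_rules) {
      tm <- threshold_metrics(sc, val$label, rule)
      rows[[length(rows) + 1]] <- data.frame(
        fold = i, rule = rule, threshold = tm$threshold, auc = a,
        sens = tm$sensitivity, spec = tm$specificity)
    }
  }
  rep_df <- do.call(rbind, rows)
  summ <- aggregate(cbind(auc, sens, spec) ~ rule, rep_df, mean)
  structure(rep_df, summary = summ, folds = fold,
            class = c("cv_report", "data.frame"))
}

#' @exportS3Method base::print
print.cv_report <- function(x, ...) {
  cat("cv_report:", max(x$fold), "folds\n")
  print(attr(x, "summary"))
  invisible(x)
}
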