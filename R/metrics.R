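#' Per-group (molecular) F1 scores
#'
#' For each functional group g, F1_g = 2 TP / (2 TP + FP + FN) computed
#' over samples (molecules). A group with TP = FP = FN = 0 on the
#' evaluated samples has an undefined F1 and is reported as `NA`; such
#' groups are excluded from macro averages rather than imputed as 0,
#' which would distort averages on datasets where a group never occurs.
#'
#' @param predictions n x 17 0/1 matrix of predicted labels.
#' @param labels n x 17 0/1 matrix of true labels.
#' @return Named numeric vector of 17 F1 scores (NA where undefined).
#' @export
per_group_f1 <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  stopifnot(all(dim(predictions) == dim(labels)))
  tp <- colSums(predictions == 1 & labels == 1)
  fp <- colSums(predictions == 1 & labels == 0)
  fn <- colSums(predictions == 0 & labels == 1)
  f1 <- ifelse(tp + fp + fn == 0, NA_real_, 2 * tp / (2 * tp + fp + fn))
  names(f1) <- if (ncol(labels) == fg_count()) fg_names()
               else colnames(labels)
  f1
}

#' Macro-mean F1 over defined groups
#'
#' @param f1 Output of [per_group_f1()].
#' @return Mean of the defined (non-NA) per-group F1 scores.
#' @export
macro_f1 <- function(f1) mean(f1, na.rm = TRUE)

#' Perfect-match table by number of true groups
#'
#' A sample is a perfect match when its full predicted 17-bit vector
#' equals the ground truth — present and absent groups alike. Results are
#' grouped by the number of groups truly present in the molecule.
#'
#' @inheritParams per_group_f1
#' @return List with `by_count` (data.frame: `n_groups`, `n`, `n_perfect`,
#'   `ratio`) and `overall_ratio`.
#' @export
perfect_match_table <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  stopifnot(all(dim(predictions) == dim(labels)))
  perfect <- rowSums(predictions != labels) == 0
  n_true <- rowSums(labels == 1)
  counts <- sort(unique(n_true))
  by_count <- data.frame(
    n_groups = counts,
    n = vapply(counts, function(k) sum(n_true == k), numeric(1)),
    n_perfect = vapply(counts, function(k) sum(perfect[n_true == k]),
                       numeric(1))
  )
  by_count$ratio <- by_count$n_perfect / by_count$n
  list(by_count = by_count, overall_ratio = mean(perfect))
}

#' Mean false-positive / false-negative rates by number of true groups
#'
#' Per sample, over its 17 bits: FPR = FP / (FP + TN), undefined when the
#' sample has no true negatives; FNR = FN / (FN + TP), undefined when it
#' has no true positives. Bucket means are taken over the samples for
#' which the rate is defined.
#'
#' @inheritParams per_group_f1
#' @return data.frame with `n_groups`, `n`, `mean_fpr`, `mean_fnr`.
#' @export
fpr_fnr_table <- function(predictions, labels) {
  predictions <- as.matrix(predictions); labels <- as.matrix(labels)
  stopifnot(all(dim(predictions) == dim(labels)))
  fp <- rowSums(predictions == 1 & labels == 0)
  tn <- rowSums(predictions == 0 & labels == 0)
  fn <- rowSums(predictions == 0 & labels == 1)
  tp <- rowSums(predictions == 1 & labels == 1)
  fpr <- ifelse(fp + tn == 0, NA_real_, fp / (fp + tn))
  fnr <- ifelse(fn + tp == 0, NA_real_, fn / (fn + tp))
  n_true <- rowSums(labels == 1)
  counts <- sort(unique(n_true))
  data.frame(
    n_groups = counts,
    n = vapply(counts, function(k) sum(n_true == k), numeric(1)),
    mean_fpr = vapply(counts, function(k)
      mean(fpr[n_true == k], na.rm = TRUE), numeric(1)),
    mean_fnr = vapply(counts, function(k)
      mean(fnr[n_true == k], na.rm = TRUE), numeric(1))
  )
}

#' Evaluate a trained model on a labeled set
#'
#' @param params A `splitnet_params`.
#' @param X n x p intensity matrix (or list of `dataset_record`s).
#' @param Y n x 17 label matrix (ignored when `X` is a record list).
#' @param threshold Decision threshold (default from the model config).
#' @return List with `prob`, `pred`, `f1`, `macro_f1`, `perfect_match`,
#'   `fpr_fnr`.
#' @export
evaluate_model <- function(params, X, Y = NULL, threshold = NULL) {
  if (is.list(X) && !is.matrix(X) && inherits(X[[1]], "dataset_record")) {
    mats <- records_to_matrices(X)
    X <- mats$X; Y <- mats$Y
  }
  if (is.null(threshold)) threshold <- params$config$threshold
  prob <- splitnet_forward(params, X, training = FALSE)
  pred <- predict_labels(prob, threshold)
  f1 <- per_group_f1(pred, Y)
  list(prob = prob, pred = pred, f1 = f1, macro_f1 = macro_f1(f1),
       perfect_match = perfect_match_table(pred, Y),
       fpr_fnr = fpr_fnr_table(pred, Y))
}
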