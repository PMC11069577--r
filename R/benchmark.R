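# Benchmarking harness: evaluation-set construction, point metrics, ROC/PR
# curves with the prevalence baseline, and the pairwise window-identity
# redundancy audit.
#
# Two evaluation sets are used: the "testing" set at a 1:3 editing to
# non-editing ratio (the held-out fraction of the train/test split) and the
# "proportional" set, which keeps the same positives but tops negatives up
# to the realistic 1:468 prevalence. Because positives are shared, recall of
# any fixed classifier is identical on the two sets.

#' Stratified train/test split
#'
#' @param sites List of [labeled_site()] objects.
#' @param fraction Training fraction (default 0.7).
#' @param seed Seed for the split.
#' @return List with `train` and `test` site lists (disjoint, stratified by
#'   label).
#' @export
split_train_test <- function(sites, fraction = 0.7, seed = 1L) {
  lab <- site_labels(sites)
  if (sum(lab) < 2L || sum(!lab) < 2L) {
    stop("stratified split needs at least 2 sites per class", call. = FALSE)
  }
  with_seed(seed, {
    take <- logical(length(sites))
    for (cls in c(TRUE, FALSE)) {
      idx <- which(lab == cls)
      take[sample(idx, round(fraction * length(idx)))] <- TRUE
    }
    list(train = sites[take], test = sites[!take])
  })
}

#' Top a testing set up to a realistic class ratio
#'
#' Keeps the testing positives unchanged and adds seeded draws from a
#' disjoint negative pool until the negative:positive ratio reaches `ratio`.
#'
#' @param test Testing-set site list.
#' @param neg_pool Extra negative [labeled_site()]s, disjoint from training.
#' @param ratio Target negatives per positive (default 468).
#' @param seed Sampling seed.
#' @param train Optional training site list; any pool site sharing a
#'   (gene, position) identity with a training site raises a leakage error.
#' @return Site list at the requested ratio (all pool negatives, with a
#'   warning, when the pool is too small).
#' @export
make_proportional_set <- function(test, neg_pool, ratio = 468, seed = 1L,
                                  train = NULL) {
  lab <- site_labels(test)
  pos <- test[lab]
  neg <- test[!lab]
  pool_lab <- site_labels(neg_pool)
  if (any(pool_lab)) {
    stop("negative pool contains editing sites", call. = FALSE)
  }
  if (!is.null(train)) {
    key <- function(sites) vapply(sites, function(s) {
      paste0(s$window$gene, ":", s$window$c_pos)
    }, character(1))
    overlap <- intersect(key(neg_pool), key(train))
    if (length(overlap) > 0L) {
      stop("negative pool leaks training sites: ",
           paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
    }
  }
  need <- round(ratio * length(pos)) - length(neg)
  if (need < 0L) {
    stop("testing set already exceeds the requested ratio", call. = FALSE)
  }
  extra <- if (need > length(neg_pool)) {
    warning("negative pool (", length(neg_pool), ") smaller than needed (",
            need, "); taking all", call. = FALSE)
    neg_pool
  } else {
    with_seed(seed, neg_pool[sample(length(neg_pool), need)])
  }
  c(pos, neg, extra)
}

# Point metrics ----------------------------------------------------------------

#' Confusion counts from truth and calls
#'
#' @param truth Logical vector (TRUE = editing site).
#' @param call Logical vector of model calls.
#' @return List with `tp`, `fp`, `fn`, `tn`, class `confusion_counts`.
#' @export
confusion_counts <- function(truth, call) {
  stopifnot(length(truth) == length(call))
  structure(
    list(tp = sum(truth & call), fp = sum(!truth & call),
         fn = sum(truth & !call), tn = sum(!truth & !call)),
    class = "confusion_counts"
  )
}

#' Point metrics from confusion counts
#'
#' Standard closed forms. Ratios with a zero denominator are reported as
#' `NA` with a warning, never silently as 0.
#'
#' @param counts A [confusion_counts()] object (or list with tp/fp/fn/tn).
#' @return List with `recall`, `precision`, `f1` and `mcc`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reporting NA",
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  recall <- safe_div(tp, tp + fn, "recall")
  precision <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.na(recall) || is.na(precision) || (recall + precision) == 0) {
    if (!is.na(recall) && !is.na(precision)) {
      warning("F1 undefined (zero denominator); reporting NA", call. = FALSE)
    }
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reporting NA", call. = FALSE)
    NA_real_
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  list(recall = recall, precision = precision, f1 = f1, mcc = mcc)
}

# Curves -----------------------------------------------------------------------

#' ROC and precision-recall curves by threshold sweep
#'
#' Sweeps the unique score values as thresholds (call positive iff
#' score >= threshold). AUROC is the trapezoidal area under the ROC curve;
#' AUPRC is the step-wise (non-interpolated) average precision. The
#' no-structure sentinel of the rules model should be passed as `-Inf` so it
#' ranks below every integer score, capping the model's maximum recall.
#'
#' @param scores Numeric scores (`-Inf` allowed; higher = more positive).
#' @param labels Logical truth vector.
#' @return List with `auroc`, `auprc`, `baseline_auprc` (= prevalence),
#'   `roc` and `pr` data frames.
#' @export
score_curves <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (all(labels) || !any(labels)) {
    stop("curves undefined: both classes must be present", call. = FALSE)
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum_by_threshold(scores, labels, thr)
  fp <- cumsum_by_threshold(scores, !labels, thr)
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  # step-wise average precision: sum over recall increments
  auprc <- sum(diff(c(0, recall)) * precision)
  list(
    auroc = auroc,
    auprc = auprc,
    baseline_auprc = n_pos / (n_pos + n_neg),
    roc = data.frame(threshold = thr, fpr = fpr[-1], tpr = tpr[-1]),
    pr = data.frame(threshold = thr, recall = recall, precision = precision)
  )
}

# counts of `mask` with score >= each threshold (thresholds descending)
cumsum_by_threshold <- function(scores, mask, thr) {
  counts <- vapply(thr, function(t) sum(mask & scores >= t), numeric(1))
  counts
}

#' Full metrics report for one model on one evaluation set
#'
#' @param truth Logical truth vector.
#' @param call Logical calls at the operating threshold.
#' @param scores Optional continuous scores for AUROC/AUPRC (primary models
#'   only).
#' @param set_name Label for the evaluation set.
#' @return List combining point metrics, curve areas and the set name.
#' @export
metrics_report <- function(truth, call, scores = NULL,
                           set_name = c("testing", "proportional")) {
  set_name <- match.arg(set_name)
  out <- compute_metrics(confusion_counts(truth, call))
  if (!is.null(scores)) {
    cur <- score_curves(scores, truth)
    out$auroc <- cur$auroc
    out$auprc <- cur$auprc
    out$baseline_auprc <- cur$baseline_auprc
  }
  out$set_name <- set_name
  out
}

# Redundancy audit ---------------------------------------------------------------

#' Pairwise sequence-identity audit of 25-nt windows
#'
#' Computes the identity (matching positions / 25) of every within-class
#' window pair and reports the fraction of pairs exceeding 75% identity
#' (at least 19 of 25 nucleotides in common) and 30% identity.
#'
#' @param windows Character vector of 25-nt context strings (see
#'   [context_string()]) or a list of [site_window()]s.
#' @return List with `n_pairs`, `frac_over_75` and `frac_over_30`.
#' @export
redundancy_audit <- function(windows) {
  if (is.list(windows)) {
    windows <- vapply(windows, context_string, character(1))
  }
  if (any(nchar(windows) != 25L)) {
    stop("all windows must be exactly 25 nt", call. = FALSE)
  }
  n <- length(windows)
  if (n < 2L) stop("need at least two windows", call. = FALSE)
  M <- t(vapply(strsplit(windows, "", fixed = TRUE), identity, character(25)))
  matches <- matrix(0L, n, n)
  for (b in c("A", "C", "G", "U")) {
    B <- (M == b) * 1L
    matches <- matches + tcrossprod(B)
  }
  id <- matches[upper.tri(matches)] / 25
  list(
    n_pairs = length(id),
    frac_over_75 = mean(id > 0.75),
    frac_over_30 = mean(id > 0.30)
  )
}
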