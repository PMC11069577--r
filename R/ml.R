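# Random-forest sequence classifier.
#
# Each site is represented by the 25 nucleotides around its cytosine (15
# upstream, 10 downstream; the C itself is fixed and carries no
# information). Every nucleotide contributes two bits, in position-major
# order (positions -15..-1 then +1..+10), isPurine before pairsGC:
# A = (1,0), G = (1,1), C = (0,1), U = (0,0). Padding residues are U and
# therefore encode (0,0).

N_FEATURES <- 50L
RF_THRESHOLD <- 0.5

ENCODE_BITS <- list(
  A = c(1, 0), G = c(1, 1), C = c(0, 1), U = c(0, 0)
)

#' Encode a site window as a 50-bit feature vector
#'
#' @param window A [site_window()].
#' @return Named numeric vector of length 50 with values in `{0,1}`.
#' @export
encode_window <- function(window) {
  ctx <- strsplit(context_string(window), "", fixed = TRUE)[[1]]
  if (length(ctx) != 25L) stop("window context must be 25 nt", call. = FALSE)
  if (any(!ctx %in% names(ENCODE_BITS))) {
    stop("cannot encode residue outside {A,C,G,U}", call. = FALSE)
  }
  bits <- unlist(ENCODE_BITS[ctx], use.names = FALSE)
  names(bits) <- feature_names()
  bits
}

#' Decode a 50-bit feature vector back to a window
#'
#' Inverse of [encode_window()] (exact on unpadded windows; padding U is
#' indistinguishable from a genuine U by construction).
#'
#' @param bits Numeric vector of length 50 over `{0,1}`.
#' @param gene,c_pos Optional identity for the reconstructed window.
#' @return A [site_window()].
#' @export
decode_window <- function(bits, gene = "decoded", c_pos = 16L) {
  if (length(bits) != N_FEATURES || any(!bits %in% c(0, 1))) {
    stop("expected 50 binary features", call. = FALSE)
  }
  pur <- bits[seq(1, 49, by = 2)]
  gc <- bits[seq(2, 50, by = 2)]
  res <- ifelse(pur == 1, ifelse(gc == 1, "G", "A"),
                ifelse(gc == 1, "C", "U"))
  site_window(gene, c_pos,
              paste(res[1:15], collapse = ""),
              paste(res[16:25], collapse = ""))
}

# Labeled sites ---------------------------------------------------------------

#' Create a labeled site
#'
#' @param window A [site_window()].
#' @param label `"editing"` or `"non_editing"`.
#' @param provenance `"curated"` or `"synthetic"`.
#' @return Object of class `labeled_site`.
#' @export
labeled_site <- function(window, label = c("editing", "non_editing"),
                         provenance = c("synthetic", "curated")) {
  label <- match.arg(label)
  provenance <- match.arg(provenance)
  stopifnot(inherits(window, "site_window"))
  structure(list(window = window, label = label, provenance = provenance),
            class = "labeled_site")
}

#' Logical labels of a site list
#' @param sites List of [labeled_site()]s.
#' @return Logical vector, `TRUE` for editing sites.
#' @export
site_labels <- function(sites) {
  vapply(sites, function(s) s$label, character(1)) == "editing"
}

feature_names <- function() {
  pos <- c(-15:-1, 1:10)
  paste0(rep(ifelse(pos < 0, paste0("m", -pos), paste0("p", pos)), each = 2),
         c("_pur", "_gc"))
}

sites_design_matrix <- function(sites) {
  X <- t(vapply(sites, function(s) encode_window(s$window),
                numeric(N_FEATURES)))
  colnames(X) <- feature_names()
  rownames(X) <- vapply(sites, function(s) {
    paste0(s$window$gene, ":", s$window$c_pos)
  }, character(1))
  X
}

# Training configuration ------------------------------------------------------

#' Training configuration for the random forest
#'
#' Controls the imbalance-aware construction of the training design matrix:
#' all editing sites are kept and non-editing sites are downsampled to
#' `neg_pos_ratio` per positive, with a fraction drawn preferentially from
#' "hard" negatives that score highly under the rules model. SMOTE-style
#' interpolation of the minority class is available but off by default.
#'
#' @param neg_pos_ratio Negatives sampled per positive (default 3, the
#'   testing-set ratio).
#' @param hard_negative_fraction Fraction of sampled negatives drawn from
#'   the high-rules-score pool (default 0.5).
#' @param hard_negative_min_score Rules total at or above which a negative
#'   counts as hard (default 6).
#' @param use_smote Inflate positives to class balance by interpolation.
#' @param split_fraction Training fraction of the train/test split.
#' @param seed Mandatory seed; all sampling is reproducible.
#' @return Object of class `training_config`.
#' @export
training_config <- function(neg_pos_ratio = 3, hard_negative_fraction = 0.5,
                            hard_negative_min_score = 6L, use_smote = FALSE,
                            split_fraction = 0.7, seed = 1L) {
  stopifnot(neg_pos_ratio > 0,
            hard_negative_fraction >= 0, hard_negative_fraction <= 1,
            split_fraction > 0, split_fraction < 1)
  structure(
    list(neg_pos_ratio = neg_pos_ratio,
         hard_negative_fraction = hard_negative_fraction,
         hard_negative_min_score = as.integer(hard_negative_min_score),
         use_smote = isTRUE(use_smote),
         split_fraction = split_fraction,
         seed = as.integer(seed)),
    class = "training_config"
  )
}

#' Build an imbalance-aware training set
#'
#' Retains all positives; samples negatives without replacement to
#' `neg_pos_ratio` per positive, drawing `hard_negative_fraction` of them
#' (uniformly, seeded) from negatives whose rules total is at least
#' `hard_negative_min_score` when enough exist (falling back to random with
#' a warning). Optionally inflates positives to class balance by SMOTE-style
#' interpolation. The output row order is shuffled under the seed.
#'
#' @param sites List of [labeled_site()] objects (both classes present).
#' @param cfg A [training_config()].
#' @param convention Loop convention used when scoring hard negatives.
#' @return List with `x` (design matrix), `y` (factor with levels
#'   `non_editing`, `editing`) and `hard_negatives` (count actually drawn
#'   from the hard pool).
#' @export
build_training_set <- function(sites, cfg = training_config(),
                               convention = "three_prime") {
  stopifnot(inherits(cfg, "training_config"))
  lab <- site_labels(sites)
  if (!any(lab) || !any(!lab)) {
    stop("need at least one site of each label", call. = FALSE)
  }
  pos <- sites[lab]
  neg <- sites[!lab]
  n_neg_want <- min(length(neg), round(cfg$neg_pos_ratio * length(pos)))
  if (n_neg_want < round(cfg$neg_pos_ratio * length(pos))) {
    warning("fewer negatives available (", length(neg),
            ") than requested; taking all", call. = FALSE)
  }

  with_seed(cfg$seed, {
    n_hard_want <- round(cfg$hard_negative_fraction * n_neg_want)
    hard_idx <- integer(0)
    if (n_hard_want > 0L) {
      scores <- vapply(neg, function(s) {
        tot <- rules_total_string(window_string(s$window), convention)
        if (is.na(tot)) -Inf else as.numeric(tot)
      }, numeric(1))
      pool <- which(scores >= cfg$hard_negative_min_score)
      if (length(pool) < n_hard_want) {
        warning("hard-negative pool (", length(pool),
                ") smaller than requested (", n_hard_want,
                "); topping up with random negatives", call. = FALSE)
        n_hard_want <- length(pool)
      }
      hard_idx <- if (n_hard_want > 0L) {
        sample(pool, n_hard_want)
      } else {
        integer(0)
      }
    }
    rest_pool <- setdiff(seq_along(neg), hard_idx)
    rest_idx <- sample(rest_pool, n_neg_want - length(hard_idx))
    chosen <- c(pos, neg[c(hard_idx, rest_idx)])
    X <- sites_design_matrix(chosen)
    y <- c(rep("editing", length(pos)),
           rep("non_editing", n_neg_want))
    if (cfg$use_smote && length(pos) < n_neg_want) {
      extra <- smote_interpolate(X[seq_along(pos), , drop = FALSE],
                                 n_neg_want - length(pos))
      X <- rbind(X, extra)
      y <- c(y, rep("editing", nrow(extra)))
    }
    ord <- sample(length(y))
    list(
      x = X[ord, , drop = FALSE],
      y = factor(y[ord], levels = c("non_editing", "editing")),
      hard_negatives = length(hard_idx)
    )
  })
}

# SMOTE-style minority interpolation: new points on segments between a
# minority sample and one of its k nearest minority neighbours. Caller is
# responsible for seeding.
smote_interpolate <- function(Xmin, n_new, k = 5L) {
  n <- nrow(Xmin)
  if (n < 2L) stop("SMOTE needs at least 2 minority samples", call. = FALSE)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(Xmin))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- sample(n, n_new, replace = TRUE)
  j <- nn[cbind(i, sample(k, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  out <- Xmin[i, , drop = FALSE] * (1 - gap) + Xmin[j, , drop = FALSE] * gap
  rownames(out) <- paste0("smote_", seq_len(n_new))
  out
}

# Model ------------------------------------------------------------------------

#' Train the random-forest editing-site classifier
#'
#' A standard random forest (500 trees, sqrt(p) features per split,
#' unlimited depth) over the 50-bit encoding, fit under the configured seed.
#'
#' @param x,y Design matrix and labels from [build_training_set()].
#' @param cfg The [training_config()] used (stored with the model).
#' @param ntree,mtry Forest hyperparameters.
#' @return Object of class `csee_rf` wrapping the fitted forest.
#' @export
train_rf <- function(x, y, cfg = training_config(), ntree = 500L,
                     mtry = floor(sqrt(ncol(x)))) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  fit <- with_seed(cfg$seed, {
    randomForest::randomForest(x = x, y = y, ntree = ntree, mtry = mtry)
  })
  structure(
    list(forest = fit, config = cfg, n_features = ncol(x),
         version = as.character(utils::packageVersion("cueditscan"))),
    class = "csee_rf"
  )
}

#' @export
print.csee_rf <- function(x, ...) {
  cat("<csee_rf> random-forest editing-site classifier (",
      x$forest$ntree, " trees, ", x$n_features, " features, seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Editing-site probability for windows
#'
#' @param model A `csee_rf` from [train_rf()] (or [load_model()]).
#' @param windows A [site_window()], a list of them, or a pre-encoded
#'   feature matrix.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, windows) {
  if (!inherits(model, "csee_rf")) {
    stop("model has not been trained (expected a 'csee_rf' object)",
         call. = FALSE)
  }
  X <- if (is.matrix(windows)) {
    windows
  } else if (inherits(windows, "site_window")) {
    matrix(encode_window(windows), nrow = 1)
  } else {
    t(vapply(windows, encode_window, numeric(N_FEATURES)))
  }
  colnames(X) <- feature_names()
  as.numeric(stats::predict(model$forest, X, type = "prob")[, "editing"])
}

#' Random-forest classification
#'
#' Positive iff the probability is strictly greater than 0.5.
#' @param prob Probability vector from [predict_prob()].
#' @return Logical vector.
#' @export
ml_classify <- function(prob) {
  stopifnot(all(prob >= 0 & prob <= 1, na.rm = TRUE))
  !is.na(prob) & prob > RF_THRESHOLD
}

#' Save / load a trained model
#'
#' Persists the model together with its training configuration and a
#' package-version stamp in a single artifact file.
#' @param model A `csee_rf`.
#' @param path Destination / source file.
#' @return `load_model` returns the `csee_rf`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "csee_rf"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "csee_rf")) {
    stop("'", path, "' does not contain a cueditscan model", call. = FALSE)
  }
  model
}
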