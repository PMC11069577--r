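test_that("train/test split is stratified, disjoint and seeded", {
  sites <- withr::with_seed(41, c(
    lapply(1:100, function(i) make_site("editing", gene = paste0("p", i))),
    lapply(1:300, function(i) make_site("non_editing", gene = paste0("n", i)))
  ))
  sp <- split_train_test(sites, 0.7, seed = 8)
  expect_equal(sum(site_labels(sp$test)), 30)
  expect_equal(sum(!site_labels(sp$test)), 90)
  expect_equal(length(sp$train) + length(sp$test), 400)
  key <- function(ss) vapply(ss, function(s) s$window$gene, character(1))
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  sp2 <- split_train_test(sites, 0.7, seed = 8)
  expect_identical(key(sp2$test), key(sp$test))
  expect_error(split_train_test(sites[1:3], 0.7, 1), "per class")
})

test_that("proportional sets keep positives and top negatives up", {
  sites <- make_benchmark(10, ratio = 3, seed = 77)
  pool <- withr::with_seed(78, lapply(1:150, function(i) {
    make_site("non_editing", gene = paste0("pool", i))
  }))
  prop <- make_proportional_set(sites, pool, ratio = 15, seed = 9)
  expect_equal(sum(site_labels(prop)), 10)
  expect_equal(sum(!site_labels(prop)), 150)

  # recall of a fixed classifier is identical on both sets
  rules_recall <- function(ss) {
    truth <- site_labels(ss)
    calls <- vapply(ss, function(s) {
      rules_classify(cueditscan:::rules_total_string(window_string(s$window)))
    }, logical(1))
    sum(truth & calls) / sum(truth)
  }
  expect_equal(rules_recall(prop), rules_recall(sites))

  expect_error(make_proportional_set(sites, sites[site_labels(sites)],
                                     ratio = 5, seed = 1),
               "contains editing sites")
  expect_error(make_proportional_set(sites, pool, ratio = 15, seed = 1,
                                     train = pool[1:5]),
               "leaks")
  expect_warning(make_proportional_set(sites, pool[1:10], ratio = 400,
                                       seed = 1),
                 "taking all")
})

test_that("point metrics match hand-derived closed forms", {
  m <- compute_metrics(confusion_counts(
    truth = c(rep(TRUE, 4), rep(FALSE, 6)),
    call = c(rep(TRUE, 3), FALSE, TRUE, rep(FALSE, 5))
  ))
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, (3 * 5 - 1 * 1) / sqrt((3 + 1) * (3 + 1) * (5 + 1) * (5 + 1)))

  perfect <- compute_metrics(list(tp = 5, fp = 0, fn = 0, tn = 20))
  expect_equal(unlist(perfect), c(recall = 1, precision = 1, f1 = 1, mcc = 1))

  noinfo <- compute_metrics(list(tp = 2, fp = 2, fn = 2, tn = 2))
  expect_equal(noinfo$mcc, 0)
})

test_that("zero-denominator metrics are NA with a warning, never 0", {
  w1 <- capture_warnings(m <- compute_metrics(list(tp = 0, fp = 0,
                                                   fn = 3, tn = 5)))
  expect_match(w1, "precision undefined", all = FALSE)
  expect_true(is.na(m$precision))
  expect_equal(m$recall, 0)
  w2 <- capture_warnings(m2 <- compute_metrics(list(tp = 0, fp = 2,
                                                    fn = 0, tn = 5)))
  expect_match(w2, "recall undefined", all = FALSE)
  expect_true(is.na(m2$recall))
})

test_that("MCC is invariant under the tp<->tn, fp<->fn swap", {
  set.seed(91)
  for (i in 1:50) {
    cts <- as.list(stats::setNames(sample(1:10, 4, replace = TRUE),
                                   c("tp", "fp", "fn", "tn")))
    swapped <- list(tp = cts$tn, fp = cts$fn, fn = cts$fp, tn = cts$tp)
    expect_equal(compute_metrics(cts)$mcc, compute_metrics(swapped)$mcc)
  }
})

test_that("curves handle perfect, random and sentinel scorers", {
  perfect <- score_curves(c(5, 4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$auprc, 1)

  constant <- score_curves(rep(1, 40), rep(c(TRUE, FALSE), 20))
  expect_equal(constant$auroc, 0.5)

  expect_error(score_curves(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # rules sentinel (-Inf) ranks below every integer score
  scores <- c(12, 10, -Inf, 3, -Inf, -Inf)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cur <- score_curves(scores, labels)
  # at every threshold above -Inf, the sentinel positive is missed
  expect_lt(max(cur$roc$tpr[cur$roc$threshold > -Inf]), 1)
  expect_equal(cur$baseline_auprc, 0.5)
})

test_that("AUROC equals the normalized Mann-Whitney statistic", {
  set.seed(13)
  for (i in 1:10) {
    n <- 60
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.3, 0.7))
    if (all(labels) || !any(labels)) next
    scores <- round(rnorm(n) + 1.2 * labels, 1)  # ties included
    got <- score_curves(scores, labels)$auroc
    w <- stats::wilcox.test(scores[labels], scores[!labels],
                            exact = FALSE)$statistic
    expect_equal(got, unname(w) / (sum(labels) * sum(!labels)))
  }
})

test_that("AUROC and AUPRC agree with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  scores <- rnorm(80) + labels
  got <- score_curves(scores, labels)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(got$auroc, ref, tolerance = 1e-10)
})

test_that("baseline AUPRC equals prevalence", {
  set.seed(15)
  labels <- c(rep(TRUE, 2), rep(FALSE, 2 * 468))
  scores <- rnorm(length(labels))
  cur <- score_curves(scores, labels)
  expect_equal(cur$baseline_auprc, 1 / 469)
  expect_equal(signif(cur$baseline_auprc, 3), 0.00213)
})

test_that("pairwise identity audit applies the 75% and 30% thresholds", {
  base <- strrep("A", 25)
  w19 <- paste0(strrep("G", 6), strrep("A", 19))   # 19/25 = 76%
  w18 <- paste0(strrep("G", 7), strrep("A", 18))   # 18/25 = 72%
  w7 <- paste0(strrep("A", 7), strrep("G", 18))    # 7/25 = 28%

  both <- redundancy_audit(c(base, base))
  expect_equal(both$frac_over_75, 1)
  expect_equal(both$frac_over_30, 1)

  r19 <- redundancy_audit(c(base, w19))
  expect_equal(r19$frac_over_75, 1)
  r18 <- redundancy_audit(c(base, w18))
  expect_equal(r18$frac_over_75, 0)
  expect_equal(r18$frac_over_30, 1)
  r7 <- redundancy_audit(c(base, w7))
  expect_equal(r7$frac_over_75, 0)
  expect_equal(r7$frac_over_30, 0)

  expect_error(redundancy_audit(c("ACG", "ACG")), "25 nt")
})
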