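flat_curve <- function(precision, n_pos = 10, n_neg = 10) {
  cv <- data.frame(margin = c(1, -Inf), recall = c(0, 1),
                   precision = c(precision, precision))
  attr(cv, "n_pos") <- n_pos
  attr(cv, "n_neg") <- n_neg
  class(cv) <- c("pr_curve", "data.frame")
  cv
}

test_that("contingency tables count the four outcome cells", {
  tab <- contingency_table(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(tab[c("tp", "fn", "fp", "tn")], list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  perfect <- contingency_table(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  set.seed(109)
  y <- sample(0:1, 25, replace = TRUE)
  p <- sample(0:1, 25, replace = TRUE)
  tab2 <- contingency_table(y, p)
  expect_equal(tab2$tp + tab2$fp + tab2$tn + tab2$fn, 25L)
  expect_error(contingency_table(c(1, 0), c(1, 0, 0)), "lengths")
})

test_that("precision-recall curves enumerate margins with the full-recall endpoint", {
  cv <- precision_recall_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))
  expect_true(any(cv$recall == 0.5 & cv$precision == 1.0))
  expect_true(any(cv$recall == 1.0 & abs(cv$precision - 2 / 3) < 1e-12))
  expect_equal(cv$recall[nrow(cv)], 1)
  expect_true(all(diff(cv$recall) >= 0))
  expect_true(all(cv$recall >= 0 & cv$recall <= 1))
  expect_true(all(cv$precision >= 0 & cv$precision <= 1))

  perfect <- precision_recall_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(perfect$recall == 1 & perfect$precision == 1))

  ties <- precision_recall_curve(c(1, 0, 0, 1), rep(0.4, 4))
  expect_equal(nrow(ties), 2)  # left endpoint + all-positive endpoint
  expect_equal(ties$precision[2], 0.5)
  expect_error(precision_recall_curve(c(0, 0), c(0.1, 0.2)), "positive")
})

test_that("step-integrated AUCPR matches closed forms", {
  expect_equal(aucpr(flat_curve(0.37)), 0.37)
  perfect <- precision_recall_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(aucpr(perfect), 1.0)
  uninformative <- precision_recall_curve(c(1, 0, 0, 1), rep(0.4, 4))
  expect_equal(aucpr(uninformative), 0.5)  # prevalence
})

test_that("precision at full recall is the positive prevalence", {
  expect_equal(p_at_full_recall(c(rep(1, 25), rep(0, 75))), 0.25)
  expect_equal(p_at_full_recall(rep(1, 8)), 1)
  expect_equal(p_at_full_recall(c(1, 0, 1, 0)), 0.5)
  expect_error(p_at_full_recall(c(0, 0)), "positive")
})

test_that("AUCPR_adj subtracts the prevalence floor", {
  y <- c(1, rep(0, 3))
  flat <- precision_recall_curve(y, rep(0.3, 4))
  expect_identical(aucpr_adj(flat, y), 0)  # no discrimination: exactly zero
  y2 <- c(1, 1, 0, 0, 0, 0, 0, 0)
  perfect <- precision_recall_curve(y2, seq(1, 0.3, length.out = 8))
  expect_equal(aucpr_adj(perfect, y2), 0.75)
  expect_equal(aucpr_adj(perfect), aucpr(perfect) - p_at_full_recall(y2))
})

test_that("PR metrics match the brute-force margin-enumeration oracle", {
  set.seed(110)
  for (i in 1:150) {
    inst <- random_instance()
    cv <- precision_recall_curve(inst$y, inst$s)
    orc <- oracle_pr(inst$y, inst$s)
    expect_equal(aucpr(cv), orc$aucpr, tolerance = 1e-12)
    expect_equal(p_at_full_recall(inst$y), orc$p_r1, tolerance = 1e-12)
    expect_equal(aucpr_adj(cv, inst$y), orc$aucpr_adj, tolerance = 1e-12)
    if (any(inst$y == 0)) {
      expect_equal(roc_auc(inst$y, inst$s), oracle_roc(inst$y, inst$s),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant to record order and monotone score transforms", {
  set.seed(111)
  for (i in 1:25) {
    inst <- random_instance()
    perm <- sample(seq_along(inst$y))
    expect_equal(aucpr(precision_recall_curve(inst$y, inst$s)),
                 aucpr(precision_recall_curve(inst$y[perm], inst$s[perm])),
                 tolerance = 1e-12)
    trans <- exp(3 * inst$s) - 0.5  # strictly monotone
    expect_equal(aucpr_adj(precision_recall_curve(inst$y, inst$s), inst$y),
                 aucpr_adj(precision_recall_curve(inst$y, trans), inst$y),
                 tolerance = 1e-12)
    expect_equal(roc_auc(inst$y, inst$s), roc_auc(inst$y, trans),
                 tolerance = 1e-12)
  }
})

test_that("the margin-0.5 curve point matches the contingency table", {
  set.seed(112)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    y <- sample(0:1, n, replace = TRUE)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    if (!any(y == 1) || !(0.5 %in% s)) next
    cv <- precision_recall_curve(y, s)
    pt <- cv[!is.na(cv$margin) & cv$margin == 0.5, ]
    tab <- contingency_table(y, classify(s, 0.5))
    expect_equal(pt$recall, tab$tp / (tab$tp + tab$fn))
    expected_prec <- if (tab$tp + tab$fp == 0) 1 else tab$tp / (tab$tp + tab$fp)
    expect_equal(pt$precision, expected_prec)
  }
})

test_that("ROC AUC uses the ties-half convention and agrees with pROC", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")

  set.seed(113)
  for (i in 1:20) {
    inst <- random_instance()
    if (!any(inst$y == 0)) next
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      inst$y, inst$s, direction = "<", quiet = TRUE))))
    expect_equal(roc_auc(inst$y, inst$s), ref, tolerance = 1e-12)
  }
})

test_that("min-max normalization maps collections onto 0-100", {
  expect_equal(normalize_scores(c(0.1, 0.5, 0.9)), c(0, 50, 100))
  expect_equal(normalize_scores(c(-0.2, 0.8)), c(0, 100))
  expect_equal(normalize_scores(rep(0.3, 5)), rep(0, 5))
  expect_equal(normalize_scores(7), 0)
})

test_that("vertical curve averaging works on the shared recall grid", {
  set.seed(114)
  inst <- random_instance()
  cv <- precision_recall_curve(inst$y, inst$s)
  avg_same <- average_pr_curves(list(cv, cv, cv))
  grid <- seq(0, 1, length.out = 101)
  expect_equal(avg_same$recall, grid)
  single <- average_pr_curves(list(cv))
  expect_equal(avg_same$precision, single$precision)

  avg_flat <- average_pr_curves(list(flat_curve(0.4), flat_curve(0.6)))
  expect_equal(avg_flat$precision, rep(0.5, 101))
  expect_equal(aucpr(avg_flat), 0.5, tolerance = 1e-9)
  expect_error(average_pr_curves(list()), "non-empty")
})

test_that("classifier evaluation bundles curve, areas and table consistently", {
  d_sites <- c(poly_site("A"), poly_site("A"), poly_site("U"), poly_site("U"),
               poly_site("C"), poly_site("G"))
  X <- t(vapply(d_sites, one_hot_encode, numeric(80)))
  y <- c(1, 1, 0, 0, 0, 0)
  m <- train_linear_freqdiff(X, y)
  ev <- evaluate_classifier(m, X, y)
  expect_s3_class(ev, "model_evaluation")
  expect_equal(ev$aucpr_adj, ev$aucpr - ev$p_r1, tolerance = 1e-12)
  expect_equal(ev$p_r1, 1 / 3)
  expect_equal(ev$table$tp + ev$table$fp + ev$table$tn + ev$table$fn, 6L)
  expect_true(is.na(ev$normalized_adj))
})
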