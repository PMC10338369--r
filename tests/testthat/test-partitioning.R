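test_that("equal-count thresholds are lower-quantile boundaries", {
  expect_equal(select_equal_count_thresholds(1:100, 10), seq(10, 90, by = 10))
  expect_equal(select_equal_count_thresholds(sample(1:100), 10), seq(10, 90, by = 10))
  expect_equal(select_equal_count_thresholds(1:20, 4), c(5, 10, 15))
  expect_error(select_equal_count_thresholds(rep(44, 356), 10), "distinct")
  expect_error(select_equal_count_thresholds(c(rep(1, 30), 2:10), 10), "degenerate")
})

test_that("threshold-pair enumeration is exhaustive and ordered", {
  pairs45 <- enumerate_threshold_pairs(c(15, 22, 29, 35, 40, 46, 53, 65, 82))
  expect_length(pairs45, 45)

  expect_equal(enumerate_threshold_pairs(7), list(threshold_pair(7, 7)))
  p2 <- enumerate_threshold_pairs(c(1, 2))
  expect_equal(p2, list(threshold_pair(1, 1), threshold_pair(1, 2),
                        threshold_pair(2, 2)))
  expect_error(enumerate_threshold_pairs(c(3, 1, 2)), "increasing")
  expect_error(threshold_pair(5, 3), "h1")
})

test_that("pair count matches the brute-force n(n+1)/2 oracle for n in 1..12", {
  for (n in 1:12) {
    th <- seq_len(n)
    # oracle: explicit double loop
    count <- 0
    for (i in th) for (j in th) if (i <= j) count <- count + 1
    expect_length(enumerate_threshold_pairs(th), count)
    expect_equal(count, n * (n + 1) / 2)
  }
})

test_that("trichotomous labels follow the <=h1 / >h2 rules", {
  pair <- threshold_pair(15, 82)
  expect_equal(as.character(assign_classes(c(15, 50, 90), pair)),
               c("effective", "undefined", "ineffective"))
  expect_equal(as.character(assign_classes(c(14.9, 15.01, 82, 82.01), pair)),
               c("effective", "undefined", "undefined", "ineffective"))

  same <- threshold_pair(22, 22)
  cls <- assign_classes(c(22, 22.5, 4, 120), same)
  expect_equal(as.character(cls),
               c("effective", "ineffective", "effective", "ineffective"))
  expect_equal(sum(cls == "undefined"), 0L)
})

test_that("class sets partition the dataset and respond monotonically to thresholds", {
  set.seed(104)
  eff <- runif(200, 4, 120)
  th <- select_equal_count_thresholds(eff, 10)
  for (pair in enumerate_threshold_pairs(th)[c(1, 9, 23, 45)]) {
    cls <- assign_classes(eff, pair)
    expect_equal(sum(table(cls)), 200)
  }
  # lowering h1 never adds effectives; raising h2 never adds ineffectives
  for (i in 1:8) {
    c_lo <- assign_classes(eff, threshold_pair(th[i], th[9]))
    c_hi <- assign_classes(eff, threshold_pair(th[i + 1], th[9]))
    expect_lte(sum(c_lo == "effective"), sum(c_hi == "effective"))
    d_lo <- assign_classes(eff, threshold_pair(th[1], th[i]))
    d_hi <- assign_classes(eff, threshold_pair(th[1], th[i + 1]))
    expect_gte(sum(d_lo == "ineffective"), sum(d_hi == "ineffective"))
  }
})

test_that("stratified split preserves sizes and class proportions", {
  set.seed(105)
  records <- tiny_dataset(runif(8, 4, 120))
  classes <- factor(rep(c("effective", "ineffective"), each = 4),
                    levels = c("effective", "ineffective", "undefined"))
  sp <- stratified_holdout_split(records, classes, seed = 3)
  expect_equal(nrow(sp$training), 6)
  expect_equal(nrow(sp$holdout), 2)
  expect_equal(as.vector(table(sp$training$class)[c("effective", "ineffective")]),
               c(3, 3))
  expect_equal(as.vector(table(sp$holdout$class)[c("effective", "ineffective")]),
               c(1, 1))
})

test_that("undefined records are excluded before splitting", {
  records <- tiny_dataset(c(10, 11, 12, 90, 91, 50, 51, 52, 53, 54))
  classes <- assign_classes(records, threshold_pair(20, 80))
  expect_equal(sum(classes == "undefined"), 5)
  sp <- stratified_holdout_split(records, classes, seed = 1)
  expect_equal(nrow(sp$training) + nrow(sp$holdout), 5)
  expect_false(any(c(sp$training$efficacy_pct, sp$holdout$efficacy_pct) > 20 &
                     c(sp$training$efficacy_pct, sp$holdout$efficacy_pct) <= 80))
})

test_that("split errors when a class is empty or too small", {
  records <- tiny_dataset(c(10, 11, 12, 13))
  classes <- factor(rep("effective", 4),
                    levels = c("effective", "ineffective", "undefined"))
  expect_error(stratified_holdout_split(records, classes, seed = 1),
               "stratified")
})

test_that("split and K-fold plans are disjoint, exhaustive and seed-reproducible", {
  set.seed(106)
  records <- tiny_dataset(runif(40, 4, 120))
  classes <- assign_classes(records, threshold_pair(40, 40))
  for (seed in 1:200) {
    sp <- stratified_holdout_split(records, classes, seed = seed)
    expect_length(intersect(sp$train_idx, sp$holdout_idx), 0)
    expect_setequal(c(sp$train_idx, sp$holdout_idx), 1:40)
    plan <- make_kfold_plan(sp$training$class, K = 5, seed = seed)
    all_idx <- unlist(plan$folds)
    expect_equal(sort(all_idx), seq_len(nrow(sp$training)))
    expect_equal(anyDuplicated(all_idx), 0L)
    expect_lte(diff(range(lengths(plan$folds))), 1)
  }
  sp1 <- stratified_holdout_split(records, classes, seed = 77)
  sp2 <- stratified_holdout_split(records, classes, seed = 77)
  expect_identical(sp1$train_idx, sp2$train_idx)
  p1 <- make_kfold_plan(sp1$training$class, K = 5, seed = 7)
  p2 <- make_kfold_plan(sp2$training$class, K = 5, seed = 7)
  expect_identical(p1$folds, p2$folds)
})

test_that("K-fold sizes and class balance match the near-equal contract", {
  # 267 training records: seven folds of 27 and three of 26
  classes <- factor(c(rep("effective", 100), rep("ineffective", 167)),
                    levels = c("effective", "ineffective"))
  plan <- make_kfold_plan(classes, K = 10, seed = 9)
  sizes <- sort(lengths(plan$folds), decreasing = TRUE)
  expect_equal(sizes, c(rep(27, 7), rep(26, 3)))
  for (f in plan$folds) {
    ne <- sum(classes[f] == "effective")
    expect_true(ne %in% c(10, 11))  # 100/10 per fold, within 1
  }

  # 20 records, 10E/10I, K=10: ten folds of 2, each 1E/1I
  cls2 <- factor(rep(c("effective", "ineffective"), 10),
                 levels = c("effective", "ineffective"))
  plan2 <- make_kfold_plan(cls2, K = 10, seed = 2)
  expect_equal(lengths(plan2$folds), rep(2L, 10))
  for (f in plan2$folds) {
    expect_equal(sum(cls2[f] == "effective"), 1L)
  }

  expect_error(make_kfold_plan(cls2, K = 21, seed = 1), "exceeds")
})
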