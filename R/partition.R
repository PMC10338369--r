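# Trichotomous two-threshold partitioning, threshold-pair enumeration,
# stratified holdout splitting and class-balanced K-fold planning.
#
# Efficacy is percent reporter expression remaining, so LOW values mean
# effective silencing: records with efficacy <= h1 are labeled "effective",
# records with efficacy > h2 "ineffective", and everything in between
# "undefined" and excluded from model development. Sweeping all pairs
# h1 <= h2 drawn from equal-count (decile) boundaries turns an arbitrary
# single-cutoff choice into a systematic evaluation.

#' Equal-count classification thresholds
#'
#' Partitions the empirical efficacy distribution into `n_groups` groups of
#' (approximately) equal size and returns the `n_groups - 1` interior
#' boundaries. Threshold `k` is the largest observed value `v` such that at
#' most `k * n / n_groups` values are `<= v` (lower empirical quantile), so
#' thresholds always sit at observed data values.
#'
#' @param efficacies numeric vector of efficacy values (percent reporter
#'   expression remaining).
#' @param n_groups number of equal-count groups (default 10, giving 9
#'   thresholds and hence 45 threshold pairs).
#' @return strictly increasing numeric vector of `n_groups - 1` thresholds.
#' @export
select_equal_count_thresholds <- function(efficacies, n_groups = 10L) {
  stopifnot(is.numeric(efficacies), n_groups >= 2L)
  n <- length(efficacies)
  if (length(unique(efficacies)) < n_groups) {
    stop("need at least ", n_groups, " distinct efficacy values for ",
         n_groups, " equal-count groups")
  }
  s <- sort(efficacies)
  idx <- floor(seq_len(n_groups - 1L) * n / n_groups)
  th <- s[idx]
  if (any(diff(th) <= 0)) {
    dup <- th[which(diff(th) <= 0)[1] + 1L]
    stop("degenerate equal-count thresholds: boundary value ", dup,
         " is duplicated; the efficacy distribution is too discrete for ",
         n_groups, " groups")
  }
  th
}

#' Construct a threshold pair
#'
#' @param h1 effective cutoff: records with efficacy `<= h1` are effective.
#' @param h2 ineffective cutoff: records with efficacy `> h2` are ineffective.
#'   Must satisfy `h1 <= h2`.
#' @return object of class `threshold_pair`.
#' @export
threshold_pair <- function(h1, h2) {
  stopifnot(is.numeric(h1), is.numeric(h2), length(h1) == 1L, length(h2) == 1L)
  if (h1 > h2) stop("invalid threshold pair: h1 (", h1, ") > h2 (", h2, ")")
  structure(list(h1 = h1, h2 = h2), class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("threshold pair %g/%g (effective <= %g, ineffective > %g)\n",
              x$h1, x$h2, x$h1, x$h2))
  invisible(x)
}

#' Enumerate all ordered threshold pairs
#'
#' All pairs `(h1, h2)` with `h1 <= h2` drawn from a strictly increasing
#' threshold list; `n` thresholds give `n (n + 1) / 2` pairs. Order is
#' deterministic: `h1` ascending, then `h2` ascending.
#'
#' @param thresholds strictly increasing numeric vector.
#' @return list of [threshold_pair()] objects.
#' @export
enumerate_threshold_pairs <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  if (any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing")
  }
  pairs <- list()
  for (i in seq_along(thresholds)) {
    for (j in i:length(thresholds)) {
      pairs[[length(pairs) + 1L]] <- threshold_pair(thresholds[i], thresholds[j])
    }
  }
  pairs
}

#' Assign trichotomous class labels
#'
#' @param records siRNA dataset data frame (or a numeric vector of
#'   efficacies).
#' @param pair a [threshold_pair()].
#' @return factor with levels `effective`, `ineffective`, `undefined`.
#'   When `h1 == h2` no record is undefined.
#' @export
assign_classes <- function(records, pair) {
  stopifnot(inherits(pair, "threshold_pair"))
  eff <- if (is.data.frame(records)) records$efficacy_pct else records
  stopifnot(is.numeric(eff))
  out <- ifelse(eff <= pair$h1, "effective",
                ifelse(eff > pair$h2, "ineffective", "undefined"))
  factor(out, levels = c("effective", "ineffective", "undefined"))
}

#' Stratified 75/25 holdout split
#'
#' Splits the effective/ineffective records (undefined records are dropped
#' first) into training and holdout sets of sizes
#' `round(train_fraction * n)` and the remainder, preserving per-class
#' proportions within one record (largest-remainder allocation) and sampling
#' without replacement under a seeded generator.
#'
#' @param records siRNA dataset data frame.
#' @param classes factor from [assign_classes()] (same length as `records`).
#' @param train_fraction fraction of labeled records used for training
#'   (default 0.75).
#' @param seed integer seed for reproducibility.
#' @return object of class `dataset_split`: list with `training` and
#'   `holdout` data frames (each carrying a `class` column), the index
#'   vectors `train_idx`/`holdout_idx` into `records`, and `seed`.
#' @export
stratified_holdout_split <- function(records, classes, train_fraction = 0.75,
                                     seed = 1L) {
  stopifnot(is.data.frame(records), length(classes) == nrow(records),
            train_fraction > 0, train_fraction < 1)
  classes <- factor(as.character(classes),
                    levels = c("effective", "ineffective", "undefined"))
  keep <- which(classes != "undefined")
  cls <- droplevels(classes[keep])
  counts <- table(cls)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("stratified split needs at least 2 records in each of the ",
         "effective and ineffective classes (have: ",
         paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  }
  n <- length(keep)
  n_train <- round_half_up(train_fraction * n)
  # Largest-remainder allocation of n_train across classes keeps per-class
  # proportions within one record of exact stratification.
  quota <- as.numeric(counts) * train_fraction
  alloc <- floor(quota)
  shortfall <- n_train - sum(alloc)
  if (shortfall > 0) {
    ord <- order(quota - alloc, as.numeric(counts), decreasing = TRUE)
    alloc[ord[seq_len(shortfall)]] <- alloc[ord[seq_len(shortfall)]] + 1L
  } else if (shortfall < 0) {
    ord <- order(quota - alloc, as.numeric(counts))
    alloc[ord[seq_len(-shortfall)]] <- alloc[ord[seq_len(-shortfall)]] - 1L
  }
  train_idx <- integer(0)
  local_seed(seed, {
    for (k in seq_along(counts)) {
      members <- keep[cls == names(counts)[k]]
      train_idx <- c(train_idx, sample(members, alloc[k]))
    }
  })
  train_idx <- sort(train_idx)
  holdout_idx <- setdiff(keep, train_idx)
  training <- records[train_idx, , drop = FALSE]
  training$class <- droplevels(classes[train_idx])
  holdout <- records[holdout_idx, , drop = FALSE]
  holdout$class <- droplevels(classes[holdout_idx])
  rownames(training) <- rownames(holdout) <- NULL
  structure(list(training = training, holdout = holdout,
                 train_idx = train_idx, holdout_idx = holdout_idx,
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' Class-balanced K-fold plan
#'
#' Partitions training indices into `K` folds of near-equal size (differing
#' by at most one) with per-fold class counts within one of balance. Each
#' class is shuffled and chunked independently; remainder chunks of the two
#' classes are placed at opposite ends of the fold list so total fold sizes
#' stay near-equal.
#'
#' @param classes factor of training-set class labels
#'   (`effective`/`ineffective`).
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @return object of class `kfold_plan`: list with `folds` (list of `K`
#'   disjoint index vectors into the training set), `K` and `seed`.
#' @export
make_kfold_plan <- function(classes, K = 10L, seed = 1L) {
  classes <- factor(as.character(classes), levels = c("effective", "ineffective"))
  if (anyNA(classes)) stop("classes must be effective/ineffective only")
  n <- length(classes)
  if (K > n) stop("K (", K, ") exceeds the number of training records (", n, ")")
  if (nlevels(droplevels(classes)) < 2L) {
    stop("both classes must be present in the training set")
  }
  folds <- rep(list(integer(0)), K)
  local_seed(seed, {
    for (k in seq_len(nlevels(classes))) {
      members <- which(classes == levels(classes)[k])
      members <- sample(members)
      sizes <- chunk_sizes(length(members), K, front = (k == 1L))
      stops <- cumsum(sizes)
      starts <- stops - sizes + 1L
      for (f in seq_len(K)) {
        if (sizes[f] > 0) {
          folds[[f]] <- sort(c(folds[[f]], members[starts[f]:stops[f]]))
        }
      }
    }
  })
  structure(list(folds = folds, K = as.integer(K), seed = as.integer(seed)),
            class = "kfold_plan")
}
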