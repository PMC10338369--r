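# The two model families: a shallow random forest and the linear
# base-frequency-difference classifier, behind a common train/score contract.

#' Random-forest hyperparameters
#'
#' Defaults follow the fixed configuration used throughout the framework:
#' 200 trees of maximum depth 3 with at least one sample per leaf. Deliberately
#' not tuned; the framework's contribution is the labeling/evaluation scheme,
#' not hyperparameter search.
#'
#' @param n_trees number of trees (default 200).
#' @param max_depth maximum tree depth (default 3).
#' @param min_samples_leaf minimum samples per leaf (default 1).
#' @param seed integer seed controlling tree construction.
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200L, max_depth = 3L,
                          min_samples_leaf = 1L, seed = 1L) {
  stopifnot(n_trees >= 1, max_depth >= 1, min_samples_leaf >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 seed = as.integer(seed)),
            class = "forest_config")
}

check_training_input <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  pos <- as_positive(y)
  if (nrow(X) != length(pos)) stop("X and y lengths differ")
  if (nrow(X) < 2L) stop("need at least 2 training records")
  if (all(pos) || !any(pos)) {
    stop("training labels contain a single class; both effective and ",
         "ineffective records are required")
  }
  list(X = X, pos = pos)
}

#' Train a random-forest efficacy classifier
#'
#' Fits a classification forest on one-hot position-base features. The forest
#' is the non-linear family of the framework: its branching structure can
#' capture base-position interactions (e.g. motifs) invisible to the linear
#' model.
#'
#' @param X numeric feature matrix (rows = records, 80 columns from
#'   [encode_dataset()]).
#' @param y binary labels: `effective`/`ineffective` factor, logical, or 0/1
#'   with 1 = effective.
#' @param config a [forest_config()].
#' @param ids optional record identifiers; when supplied, rows are pre-sorted
#'   by id before fitting so the model is independent of input row order.
#' @return object of class `trained_classifier` (family `"forest"`).
#' @export
train_random_forest <- function(X, y, config = forest_config(), ids = NULL) {
  stopifnot(inherits(config, "forest_config"))
  inp <- check_training_input(X, y)
  X <- inp$X; pos <- inp$pos
  if (!is.null(ids)) {
    ord <- order(as.character(ids))
    X <- X[ord, , drop = FALSE]
    pos <- pos[ord]
  }
  df <- as.data.frame(X)
  cls <- factor(ifelse(pos, "effective", "ineffective"),
                levels = c("ineffective", "effective"))
  fit <- ranger::ranger(
    x = df, y = cls,
    num.trees = config$n_trees,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_leaf,
    seed = config$seed,
    num.threads = 1L,
    respect.unordered.factors = FALSE
  )
  structure(list(family = "forest", fit = fit, config = config,
                 feature_names = colnames(df),
                 n_train = nrow(X), n_pos = sum(pos)),
            class = "trained_classifier")
}

#' Train the linear base-frequency-difference classifier
#'
#' The linear family scores a sequence by position-base weights
#' `w(p, b) = freq(b at p | effective) - freq(b at p | ineffective)`,
#' the per-position base-frequency difference between the effective and
#' ineffective training records. The raw score of a sequence is the sum of
#' the weights of its observed bases (equivalently, the inner product of the
#' one-hot encoding with the flattened weight matrix).
#'
#' @inheritParams train_random_forest
#' @return object of class `trained_classifier` (family `"linear"`) carrying
#'   the 20 x 4 weight matrix and the training-score range used to map raw
#'   scores to `[0, 1]` confidences.
#' @export
train_linear_freqdiff <- function(X, y, ids = NULL) {
  inp <- check_training_input(X, y)
  X <- inp$X; pos <- inp$pos
  if (!is.null(ids)) {
    ord <- order(as.character(ids))
    X <- X[ord, , drop = FALSE]
    pos <- pos[ord]
  }
  freq_e <- colMeans(X[pos, , drop = FALSE])
  freq_i <- colMeans(X[!pos, , drop = FALSE])
  w <- freq_e - freq_i
  scores <- as.numeric(X %*% w)
  structure(list(family = "linear",
                 weights = vector_to_matrix(unname(w)),
                 w_vec = unname(w),
                 score_min = min(scores), score_max = max(scores),
                 feature_names = colnames(X),
                 n_train = nrow(X), n_pos = sum(pos)),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("trained %s classifier (n_train = %d, %d effective)\n",
              x$family, x$n_train, x$n_pos))
  if (x$family == "forest") {
    cat(sprintf("  %d trees, max depth %d, min %d sample(s)/leaf, seed %d\n",
                x$config$n_trees, x$config$max_depth,
                x$config$min_samples_leaf, x$config$seed))
  } else {
    cat(sprintf("  base-frequency-difference weights; raw score range [%.3f, %.3f]\n",
                x$score_min, x$score_max))
  }
  invisible(x)
}

#' Extract the raw linear weight matrix
#'
#' @param model a linear `trained_classifier`.
#' @return 20 x 4 matrix of base-frequency differences (entries in `[-1, 1]`).
#' @export
linear_weights <- function(model) {
  stopifnot(inherits(model, "trained_classifier"))
  if (model$family != "linear") {
    stop("linear_weights() requires a linear model, got family '",
         model$family, "'")
  }
  model$weights
}

#' Predict confidence scores in [0, 1]
#'
#' Forest models return the fraction of trees voting "effective". Linear
#' models map raw frequency-difference scores to `[0, 1]` by min-max scaling
#' over the training-set scores, clipping out-of-range probes; the mapping is
#' monotone, so rankings (and hence precision-recall curves) are unaffected
#' by it. Higher scores mean more likely effective.
#'
#' @param model a `trained_classifier`.
#' @param X feature matrix of probes (80 columns).
#' @return numeric vector of confidences in `[0, 1]`.
#' @export
predict_confidence <- function(model, X) {
  stopifnot(inherits(model, "trained_classifier"))
  if (!is.matrix(X)) X <- matrix(X, ncol = 80L, byrow = TRUE)
  if (ncol(X) != 80L) stop("probe matrix must have 80 feature columns")
  if (model$family == "forest") {
    df <- as.data.frame(X)
    colnames(df) <- model$feature_names
    votes <- stats::predict(model$fit, data = df, predict.all = TRUE,
                            num.threads = 1L)$predictions
    pos_level <- which(model$fit$forest$levels == "effective")
    rowMeans(votes == pos_level)
  } else {
    s <- as.numeric(X %*% model$w_vec)
    rng <- model$score_max - model$score_min
    if (rng <= 0) return(rep(0.5, length(s)))  # degenerate: all train scores equal
    pmin(1, pmax(0, (s - model$score_min) / rng))
  }
}

#' Binarize confidence scores at a margin
#'
#' Positive (effective) iff score strictly exceeds the margin; ties at the
#' margin are classified negative — the conservative choice for siRNA design,
#' where false positives are costly.
#'
#' @param scores numeric confidences in `[0, 1]`.
#' @param margin confidence margin (default 0.5; deliberately not tuned).
#' @return integer vector of 0/1 predictions (1 = effective).
#' @export
classify <- function(scores, margin = 0.5) {
  if (!is.numeric(margin) || length(margin) != 1L || margin < 0 || margin > 1) {
    stop("margin must be a single value in [0, 1]")
  }
  as.integer(scores > margin)
}
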