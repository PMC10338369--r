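# Model-agnostic proxy extraction of position-base weight matrices.
#
# The extraction is evaluation-centered: it needs only the classification
# outputs of a model, never its internals, so the same procedure applies to
# the forest, the linear model, or any other classifier. Records are split
# into the four contingency groups at the confidence margin; the one-hot
# feature vectors within each group are averaged; the false-positive and
# false-negative group means are negated (they represent incorrect
# predictions); the four group vectors are summed and reshaped to a 20 x 4
# position-by-base matrix.

#' Contingency groups of evaluated records
#'
#' @param model a `trained_classifier`.
#' @param X feature matrix of the evaluated records.
#' @param y_true binary ground-truth labels (1 = effective).
#' @param margin confidence margin (default 0.5).
#' @return list of index vectors `tp`, `tn`, `fp`, `fn` partitioning
#'   `seq_len(nrow(X))`.
#' @export
classification_groups <- function(model, X, y_true, margin = 0.5) {
  yt <- as_positive(y_true)
  pred <- classify(predict_confidence(model, X), margin) == 1L
  list(tp = which(yt & pred), tn = which(!yt & !pred),
       fp = which(!yt & pred), fn = which(yt & !pred))
}

#' Proxy position-base weight matrix from contingency groups
#'
#' Computes `mean(TP) + mean(TN) - mean(FP) - mean(FN)` over the one-hot
#' feature vectors of the four groups and reshapes to 20 x 4. An empty group
#' contributes the zero vector (the unique neutral element of the sum).
#' Group means are unweighted by group size by default; `weighted = TRUE`
#' weights each group mean by its share of records (sensitivity variant).
#' `flip_tn = TRUE` enters the true-negative mean with negative sign, a
#' sensitivity variant that aligns the matrix with "positive = favored in
#' effective" for error-free models; the literal positive-TN formula is the
#' default.
#'
#' @param groups list from [classification_groups()].
#' @param X feature matrix the group indices refer to.
#' @param weighted weight group means by group size (default `FALSE`).
#' @param flip_tn negate the TN contribution (default `FALSE`).
#' @return raw (unnormalized) 20 x 4 weight matrix with attribute
#'   `normalized = FALSE`.
#' @export
proxy_feature_weights <- function(groups, X, weighted = FALSE, flip_tn = FALSE) {
  stopifnot(is.list(groups), all(c("tp", "tn", "fp", "fn") %in% names(groups)))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (sum(lengths(groups[c("tp", "tn", "fp", "fn")])) == 0L) {
    stop("all four classification groups are empty")
  }
  n_total <- nrow(X)
  group_mean <- function(idx) {
    if (length(idx) == 0L) return(numeric(ncol(X)))
    m <- colMeans(X[idx, , drop = FALSE])
    if (weighted) m <- m * (length(idx) / n_total)
    m
  }
  sign_tn <- if (flip_tn) -1 else 1
  w <- group_mean(groups$tp) + sign_tn * group_mean(groups$tn) -
    group_mean(groups$fp) - group_mean(groups$fn)
  W <- vector_to_matrix(unname(w))
  attr(W, "normalized") <- FALSE
  W
}

#' Normalize a weight matrix to the -100..100 scale
#'
#' Scales sign-preservingly so the largest absolute entry becomes 100, then
#' zeroes entries with absolute value below 20 to suppress low-weight noise.
#' Zero stays the middle weight meaning "no importance". An all-zero matrix
#' is returned unchanged. Idempotent.
#'
#' @param W_raw 20 x 4 numeric weight matrix.
#' @param zero_below magnitude under which scaled weights are set to 0
#'   (default 20).
#' @return normalized weight matrix with attribute `normalized = TRUE`.
#' @export
normalize_weight_matrix <- function(W_raw, zero_below = 20) {
  stopifnot(is.matrix(W_raw), all(dim(W_raw) == c(SIRNA_SITE_LENGTH, 4L)))
  if (any(!is.finite(W_raw))) stop("weight matrix contains non-finite entries")
  m <- max(abs(W_raw))
  W <- if (m == 0) W_raw else W_raw * (100 / m)
  W[abs(W) < zero_below] <- 0
  attr(W, "normalized") <- TRUE
  W
}

#' Directly extracted (normalized) linear weight matrix
#'
#' For the linear family the weight matrix is available exactly — it is the
#' base-frequency difference the model was built from. Returned on the same
#' normalized -100..100 scale as the proxy matrices for comparison.
#'
#' @param model a linear `trained_classifier`.
#' @return normalized 20 x 4 weight matrix.
#' @export
direct_linear_weights <- function(model) {
  normalize_weight_matrix(linear_weights(model))
}

#' Per-position AU - GC weight trend
#'
#' `trend(p) = (W[p, A] + W[p, U]) - (W[p, G] + W[p, C])`: summed weights of
#' the weakly pairing bases minus the strongly pairing ones, a proxy for the
#' local duplex thermodynamic-stability preference at each target position.
#'
#' @param W 20 x 4 weight matrix (columns A, U, C, G).
#' @return named numeric vector of length 20 (t1..t20).
#' @export
au_gc_trend <- function(W) {
  if (!is.matrix(W) || !all(dim(W) == c(SIRNA_SITE_LENGTH, 4L))) {
    stop("expected a 20 x 4 weight matrix")
  }
  trend <- (W[, "A"] + W[, "U"]) - (W[, "G"] + W[, "C"])
  names(trend) <- rownames(W)
  trend
}

#' Write an AU - GC trend vector as TSV
#'
#' @param trend vector from [au_gc_trend()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trend <- function(trend, path) {
  utils::write.table(
    data.frame(position = names(trend), trend = as.numeric(trend)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
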