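# Orchestration: the full threshold-pair sweep, the label-shuffle control,
# and the transcript-scanning siRNA design application.

#' Sweep configuration
#'
#' @param families model families to train per pair: any of `"forest"`,
#'   `"linear"`.
#' @param n_groups equal-count groups for threshold selection (default 10).
#' @param K cross-validation folds (default 10).
#' @param train_fraction training share of the labeled records (default
#'   0.75).
#' @param margin confidence margin for contingency tables (default 0.5).
#' @param forest a [forest_config()]; its seed field is overridden per pair
#'   by seeds derived from `seed`.
#' @param seed master seed; all per-pair split, fold and forest seeds are
#'   derived from it deterministically.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(families = c("forest", "linear"), n_groups = 10L,
                         K = 10L, train_fraction = 0.75, margin = 0.5,
                         forest = forest_config(), seed = 1L) {
  families <- match.arg(families, c("forest", "linear"), several.ok = TRUE)
  structure(list(families = families, n_groups = as.integer(n_groups),
                 K = as.integer(K), train_fraction = train_fraction,
                 margin = margin, forest = forest, seed = as.integer(seed)),
            class = "sweep_config")
}

train_family <- function(family, X, y, ids, config, seed) {
  if (family == "forest") {
    fc <- config$forest
    fc$seed <- seed
    train_random_forest(X, y, fc, ids = ids)
  } else {
    train_linear_freqdiff(X, y, ids = ids)
  }
}

# Single-pair pipeline: label, split, K-fold CV, final train, holdout
# evaluation. Returns NULL fields plus a reason when the pair is degenerate
# (a split or fold without both classes, or a fold without a positive).
run_pair_pipeline <- function(records, X, pair, config, pair_seed) {
  classes <- assign_classes(records, pair)
  n_eff <- sum(classes == "effective")
  n_ineff <- sum(classes == "ineffective")
  n_undef <- sum(classes == "undefined")
  out <- list(pair = pair, n_eff = n_eff, n_ineff = n_ineff,
              n_undef = n_undef, degenerate = FALSE, reason = NA_character_,
              families = list())
  if (n_eff < 2L || n_ineff < 2L) {
    out$degenerate <- TRUE
    out$reason <- sprintf("class too small for stratified split (E=%d, I=%d)",
                          n_eff, n_ineff)
    return(out)
  }
  split <- stratified_holdout_split(records, classes,
                                    train_fraction = config$train_fraction,
                                    seed = derive_seed(pair_seed, 1L))
  if (nlevels(droplevels(split$training$class)) < 2L ||
      nlevels(droplevels(split$holdout$class)) < 2L) {
    out$degenerate <- TRUE
    out$reason <- "training or holdout set lost a class in the split"
    return(out)
  }
  K <- min(config$K, nrow(split$training))
  plan <- make_kfold_plan(split$training$class, K = K,
                          seed = derive_seed(pair_seed, 2L))
  # every CV round needs both classes in training and >= 1 positive + 1
  # negative in the evaluation fold
  for (f in seq_len(K)) {
    fold_cls <- split$training$class[plan$folds[[f]]]
    rest_cls <- split$training$class[-plan$folds[[f]]]
    if (sum(fold_cls == "effective") < 1L || sum(fold_cls == "ineffective") < 1L ||
        length(unique(rest_cls)) < 2L) {
      out$degenerate <- TRUE
      out$reason <- sprintf("fold %d lacks a class (E=%d in training)", f, n_eff)
      return(out)
    }
  }
  out$split <- split
  out$plan <- plan
  X_train <- X[split$train_idx, , drop = FALSE]
  y_train <- split$training$class
  X_hold <- X[split$holdout_idx, , drop = FALSE]
  y_hold <- split$holdout$class

  for (family in config$families) {
    fold_curves <- vector("list", K)
    fold_roc <- numeric(K)
    fold_tables <- list()
    for (f in seq_len(K)) {
      idx <- plan$folds[[f]]
      m <- train_family(family, X_train[-idx, , drop = FALSE], y_train[-idx],
                        ids = split$training$id[-idx], config,
                        seed = derive_seed(pair_seed, 10L + f))
      scores <- predict_confidence(m, X_train[idx, , drop = FALSE])
      yt <- as_positive(y_train[idx])
      fold_curves[[f]] <- precision_recall_curve(yt, scores)
      fold_roc[f] <- roc_auc(yt, scores)
      fold_tables[[f]] <- contingency_table(yt, classify(scores, config$margin))
    }
    cv_curve <- average_pr_curves(fold_curves)
    cv_aucpr <- aucpr(cv_curve)
    cv_p1 <- attr(cv_curve, "n_pos") / (attr(cv_curve, "n_pos") + attr(cv_curve, "n_neg"))
    cv_table <- structure(as.list(colSums(do.call(
      rbind, lapply(fold_tables, function(t) unlist(t[c("tp", "fp", "tn", "fn")]))))),
      class = "contingency_table")
    cv_eval <- structure(list(curve = cv_curve, aucpr = cv_aucpr, p_r1 = cv_p1,
                              aucpr_adj = cv_aucpr - cv_p1,
                              roc_auc = mean(fold_roc), table = cv_table,
                              margin = config$margin,
                              normalized_adj = NA_real_),
                         class = "model_evaluation")
    final <- train_family(family, X_train, y_train, ids = split$training$id,
                          config, seed = derive_seed(pair_seed, 30L))
    holdout_eval <- evaluate_classifier(final, X_hold, y_hold,
                                        margin = config$margin)
    out$families[[family]] <- list(cv = cv_eval, holdout = holdout_eval,
                                   model = final)
  }
  out
}

#' Run the full threshold-pair sweep
#'
#' Selects equal-count thresholds from the efficacy distribution, enumerates
#' all pairs with `h1 <= h2`, and for every pair runs the complete pipeline:
#' trichotomous labeling, stratified 75/25 split, class-balanced K-fold
#' cross-validation with vertical curve averaging, final training on the
#' full training set, and holdout evaluation. AUCPR_adj values are min-max
#' normalized to 0-100 within each evaluation stage (all CV results
#' together; all holdout results together), separately per family. Pairs
#' that leave a split or fold without both classes are marked degenerate and
#' skipped with a recorded reason rather than aborting the sweep.
#'
#' @param records validated siRNA dataset data frame.
#' @param config a [sweep_config()].
#' @return object of class `sweep_result`: list with `thresholds`, `pairs`,
#'   `summary` (one data-frame row per pair x family), `details` (per-pair
#'   pipeline results including fitted models), and `config`.
#' @export
run_threshold_sweep <- function(records, config = sweep_config()) {
  stopifnot(inherits(config, "sweep_config"))
  records <- validate_sirna_dataset(records)
  thresholds <- select_equal_count_thresholds(records$efficacy_pct,
                                              config$n_groups)
  pairs <- enumerate_threshold_pairs(thresholds)
  X <- encode_dataset(records)
  details <- vector("list", length(pairs))
  rows <- list()
  for (i in seq_along(pairs)) {
    res <- run_pair_pipeline(records, X, pairs[[i]], config,
                             pair_seed = derive_seed(config$seed, i))
    details[[i]] <- res
    for (family in config$families) {
      fam <- res$families[[family]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_index = i, family = family,
        h1 = pairs[[i]]$h1, h2 = pairs[[i]]$h2,
        n_eff = res$n_eff, n_ineff = res$n_ineff, n_undef = res$n_undef,
        degenerate = res$degenerate, reason = res$reason,
        cv_aucpr = if (is.null(fam)) NA_real_ else fam$cv$aucpr,
        cv_p_r1 = if (is.null(fam)) NA_real_ else fam$cv$p_r1,
        cv_aucpr_adj = if (is.null(fam)) NA_real_ else fam$cv$aucpr_adj,
        cv_roc_auc = if (is.null(fam)) NA_real_ else fam$cv$roc_auc,
        holdout_aucpr = if (is.null(fam)) NA_real_ else fam$holdout$aucpr,
        holdout_p_r1 = if (is.null(fam)) NA_real_ else fam$holdout$p_r1,
        holdout_aucpr_adj = if (is.null(fam)) NA_real_ else fam$holdout$aucpr_adj,
        holdout_roc_auc = if (is.null(fam)) NA_real_ else fam$holdout$roc_auc,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  summary$cv_norm_adj <- NA_real_
  summary$holdout_norm_adj <- NA_real_
  for (family in config$families) {
    sel <- summary$family == family & !summary$degenerate
    if (any(sel)) {
      summary$cv_norm_adj[sel] <- normalize_scores(summary$cv_aucpr_adj[sel])
      summary$holdout_norm_adj[sel] <- normalize_scores(summary$holdout_aucpr_adj[sel])
      for (k in which(sel)) {
        fam <- details[[summary$pair_index[k]]]$families[[family]]
        fam$cv$normalized_adj <- summary$cv_norm_adj[k]
        fam$holdout$normalized_adj <- summary$holdout_norm_adj[k]
        details[[summary$pair_index[k]]]$families[[family]] <- fam
      }
    }
  }
  structure(list(thresholds = thresholds, pairs = pairs, summary = summary,
                 details = details, config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("threshold sweep: %d thresholds, %d pairs, families: %s\n",
              length(x$thresholds), length(x$pairs),
              paste(x$config$families, collapse = ", ")))
  ok <- !x$summary$degenerate
  cat(sprintf("  %d/%d pair evaluations non-degenerate\n",
              sum(ok), nrow(x$summary)))
  if (any(ok)) {
    best <- x$summary[ok, ][which.max(x$summary$holdout_aucpr_adj[ok]), ]
    cat(sprintf("  best holdout AUCPR_adj: %.4f (%s, pair %g/%g)\n",
                best$holdout_aucpr_adj, best$family, best$h1, best$h2))
  }
  invisible(x)
}

#' Serialize a sweep summary as JSON
#'
#' Deterministic serialization of the per-pair summary table (models and
#' curves are not included).
#'
#' @param sweep a `sweep_result`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string, or `path` invisibly when writing.
#' @export
sweep_summary_json <- function(sweep, path = NULL) {
  stopifnot(inherits(sweep, "sweep_result"))
  obj <- list(thresholds = sweep$thresholds, summary = sweep$summary)
  if (is.null(path)) {
    as.character(jsonlite::toJSON(obj, digits = NA, na = "null"))
  } else {
    jsonlite::write_json(obj, path, digits = NA, na = "null")
    invisible(path)
  }
}

#' Label-shuffle control for one threshold pair
#'
#' Re-runs the single-pair pipeline, then permutes the holdout efficacies
#' against their sequences with a seeded permutation, re-assigns classes and
#' re-evaluates the final model. The permutation preserves the efficacy
#' multiset, so class counts are unchanged; only the sequence-efficacy
#' association is destroyed. A model fitted to genuine sequence signal
#' degrades sharply under the shuffle.
#'
#' @param records validated siRNA dataset data frame.
#' @param pair a [threshold_pair()].
#' @param config a [sweep_config()] (first listed family is used).
#' @param shuffle_seed seed for the permutation.
#' @return list with `original` and `shuffled` `model_evaluation`s, the
#'   `permutation`, the fitted `model` and the `pair`.
#' @export
shuffle_labels_control <- function(records, pair, config = sweep_config(),
                                   shuffle_seed = 1L) {
  records <- validate_sirna_dataset(records)
  X <- encode_dataset(records)
  family <- config$families[1]
  res <- run_pair_pipeline(records, X, pair, config,
                           pair_seed = derive_seed(config$seed, 997L))
  if (res$degenerate) {
    stop("pair ", pair$h1, "/", pair$h2, " is degenerate: ", res$reason)
  }
  fam <- res$families[[family]]
  holdout <- res$split$holdout
  X_hold <- X[res$split$holdout_idx, , drop = FALSE]
  perm <- local_seed(shuffle_seed, sample.int(nrow(holdout)))
  shuffled_eff <- holdout$efficacy_pct[perm]
  shuffled_classes <- assign_classes(shuffled_eff, pair)
  keep <- shuffled_classes != "undefined"  # counts match the original labeling
  shuffled_eval <- evaluate_classifier(fam$model, X_hold[keep, , drop = FALSE],
                                       shuffled_classes[keep],
                                       margin = config$margin)
  list(original = fam$holdout, shuffled = shuffled_eval, permutation = perm,
       model = fam$model, pair = pair)
}

#' Scan a transcript for siRNA design candidates
#'
#' Slides a 20-nt window at stride 1 over the transcript (5' to 3'; window
#' sequence taken as the t1..t20 target-site register), producing `L - 19`
#' candidates, each scored and classified at the 0.5 margin.
#'
#' @param transcript one-row data frame from [read_transcripts()] or
#'   [generate_transcript()] (or a list with `id` and `sequence`).
#' @param model a `trained_classifier`.
#' @param margin confidence margin (default 0.5).
#' @return data frame of candidates: `transcript_id`, `start`, `end`
#'   (1-based, inclusive), `target_site`, `confidence`, `predicted`
#'   (`"effective"`/`"ineffective"`).
#' @export
scan_transcript <- function(transcript, model, margin = 0.5) {
  id <- transcript$id[1]
  seq <- transcript$sequence[1]
  L <- nchar(seq)
  if (L < SIRNA_SITE_LENGTH) {
    stop("transcript ", id, " is shorter than 20 nt (", L, ")")
  }
  starts <- seq_len(L - SIRNA_SITE_LENGTH + 1L)
  sites <- substring(seq, starts, starts + SIRNA_SITE_LENGTH - 1L)
  X <- t(vapply(sites, one_hot_encode, numeric(80L)))
  conf <- predict_confidence(model, X)
  pred <- classify(conf, margin)
  data.frame(transcript_id = id, start = starts,
             end = starts + SIRNA_SITE_LENGTH - 1L,
             target_site = unname(sites), confidence = conf,
             predicted = ifelse(pred == 1L, "effective", "ineffective"),
             stringsAsFactors = FALSE)
}

#' Select top design candidates
#'
#' Returns the `n` predicted-effective candidates with the highest
#' confidence and the `n` predicted-ineffective candidates with the lowest
#' confidence. Ties are broken by ascending window start; when fewer than
#' `n` candidates exist in a group, all are returned with a warning.
#'
#' @param candidates data frame from [scan_transcript()] (rows from several
#'   transcripts may be concatenated).
#' @param n number of candidates per group (default 10).
#' @return list with data frames `effective` and `ineffective`.
#' @export
select_candidates <- function(candidates, n = 10L) {
  stopifnot(is.data.frame(candidates),
            all(c("confidence", "predicted", "start") %in% names(candidates)))
  eff <- candidates[candidates$predicted == "effective", , drop = FALSE]
  ineff <- candidates[candidates$predicted == "ineffective", , drop = FALSE]
  eff <- eff[order(-eff$confidence, eff$start), , drop = FALSE]
  ineff <- ineff[order(ineff$confidence, ineff$start), , drop = FALSE]
  if (nrow(eff) < n) {
    warning("only ", nrow(eff), " predicted-effective candidate(s) available")
  }
  if (nrow(ineff) < n) {
    warning("only ", nrow(ineff), " predicted-ineffective candidate(s) available")
  }
  out <- list(effective = utils::head(eff, n), ineffective = utils::head(ineff, n))
  rownames(out$effective) <- rownames(out$ineffective) <- NULL
  out
}
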