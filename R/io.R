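# Readers and writers for the delimited dataset table, FASTA transcripts and
# weight-matrix TSVs.

#' Read an siRNA efficacy dataset from a delimited table
#'
#' Expects UTF-8 delimited text (comma or tab, auto-detected from the header
#' line) with required columns `id`, `gene`, `target_site`, `efficacy_pct`
#' and optional replicate columns named `rep1`, `rep2`, ... Efficacy is percent
#' reporter expression remaining relative to untreated cells (lower = more
#' effective silencing).
#'
#' Each row is validated: target sites are normalized with
#' [validate_target_site()], efficacies must be finite and non-negative,
#' duplicate ids are rejected, and when replicates are present their mean must
#' match `efficacy_pct` within 0.5 percentage points (printed efficacies are
#' typically rounded).
#'
#' @param path path to the table file.
#' @return data frame of validated records, in file order.
#' @seealso [write_sirna_dataset()]
#' @export
read_sirna_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          comment.char = "", quote = "\"")
  validate_sirna_dataset(df)
}

#' Validate an in-memory siRNA dataset
#'
#' Applies the same schema and row checks as [read_sirna_dataset()].
#'
#' @param df data frame with columns `id`, `gene`, `target_site`,
#'   `efficacy_pct` and optional `rep*` columns.
#' @param replicate_tol absolute tolerance (percentage points) for the
#'   mean-of-replicates consistency check.
#' @return the validated data frame (target sites normalized).
#' @export
validate_sirna_dataset <- function(df, replicate_tol = 0.5) {
  required <- c("id", "gene", "target_site", "efficacy_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("dataset is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) return(df)
  df$id <- as.character(df$id)
  df$gene <- as.character(df$gene)
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup) > 0) {
    stop("duplicate id(s) in dataset: ", paste(dup, collapse = ", "))
  }
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    site <- tryCatch(validate_target_site(df$target_site[i]),
                     error = function(e) e)
    if (inherits(site, "error")) {
      errors <- c(errors, sprintf("row %d (id %s): %s", i, df$id[i],
                                  conditionMessage(site)))
    } else {
      df$target_site[i] <- site
    }
    eff <- df$efficacy_pct[i]
    if (!is.numeric(eff) || !is.finite(eff) || eff < 0) {
      errors <- c(errors, sprintf("row %d (id %s): efficacy_pct must be finite and >= 0",
                                  i, df$id[i]))
    }
  }
  rep_cols <- grep("^rep[0-9]+$", names(df), value = TRUE)
  if (length(rep_cols) > 0) {
    rep_mean <- rowMeans(as.matrix(df[rep_cols]))
    off <- which(abs(rep_mean - df$efficacy_pct) > replicate_tol)
    for (i in off) {
      errors <- c(errors, sprintf(
        "row %d (id %s): mean of replicates (%.2f) differs from efficacy_pct (%.2f) by more than %.2f",
        i, df$id[i], rep_mean[i], df$efficacy_pct[i], replicate_tol))
    }
  }
  if (length(errors) > 0) {
    stop("invalid dataset rows:\n  ", paste(errors, collapse = "\n  "))
  }
  rownames(df) <- NULL
  df
}

#' Write an siRNA dataset as a tab-delimited table
#'
#' @param records data frame of siRNA records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sirna_dataset <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read transcript sequences from a FASTA file
#'
#' Sequences are normalized to the RNA alphabet (uppercased, T mapped to U).
#' Records shorter than 20 nt cannot be scanned for siRNA target sites; each
#' is dropped with a warning, and an error is raised only if no usable record
#' remains.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id`, `sequence`, `length`, in file order.
#' @export
read_transcripts <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("T", "U", toupper(as.character(set)))
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), SIRNA_BASES)
    if (length(bad) > 0) {
      stop("transcript ", ids[i], " contains invalid character(s): ",
           paste(bad, collapse = ", "))
    }
  }
  lens <- nchar(seqs)
  short <- lens < SIRNA_SITE_LENGTH
  if (any(short)) {
    warning("excluding transcript(s) shorter than 20 nt: ",
            paste(ids[short], collapse = ", "))
  }
  if (all(short)) stop("no transcript of length >= 20 nt in ", path)
  data.frame(id = ids[!short], sequence = unname(seqs[!short]),
             length = lens[!short], stringsAsFactors = FALSE)
}

#' Write a position-base weight matrix as TSV
#'
#' Writes 20 rows (t1..t20) with a leading `position` column and the four
#' labeled base columns A, U, C, G.
#'
#' @param W 20 x 4 weight matrix (as from [proxy_feature_weights()] or
#'   [direct_linear_weights()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(W, path) {
  stopifnot(is.matrix(W), all(dim(W) == c(SIRNA_SITE_LENGTH, 4L)))
  df <- data.frame(position = rownames(W), W, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a position-base weight matrix TSV
#'
#' @param path path written by [write_weight_matrix()].
#' @return 20 x 4 numeric matrix.
#' @export
read_weight_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  W <- as.matrix(df[SIRNA_BASES])
  rownames(W) <- df$position
  W
}
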