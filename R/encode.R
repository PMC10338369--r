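# Sequence validation and one-hot position-base encoding.
#
# Every model in the package sees an siRNA only through its 20-nt mRNA
# target-site sequence (positions t1..t20, pairing with guide positions
# g1..g20). Each position contributes four binary indicator features in the
# fixed base order A, U, C, G, giving the 80-dimensional feature vector used
# throughout.

#' Canonical base order for all position-base features
#'
#' All feature vectors, weight matrices and frequency tables in the package
#' index bases in this order.
#'
#' @format character vector `c("A", "U", "C", "G")`.
#' @export
SIRNA_BASES <- c("A", "U", "C", "G")

#' Number of target-site positions
#' @format integer, 20.
#' @export
SIRNA_SITE_LENGTH <- 20L

#' Validate and normalize a 20-nt target-site sequence
#'
#' Accepts upper or lower case and the DNA alphabet (T is silently mapped to
#' U, matching the conventions of published external siRNA datasets).
#'
#' @param raw a single character string.
#' @return the validated sequence: 20 uppercase characters over A/C/G/U.
#' @examples
#' validate_target_site("aucgaucgaucgaucgaucg")
#' validate_target_site(strrep("ACGT", 5))  # DNA input, T -> U
#' @export
validate_target_site <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || nchar(raw) == 0L) {
    stop("target site must be a single non-empty string")
  }
  seq <- chartr("T", "U", toupper(raw))
  if (nchar(seq) != SIRNA_SITE_LENGTH) {
    stop("target site must be exactly ", SIRNA_SITE_LENGTH,
         " nt, got ", nchar(seq), " ('", raw, "')")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), SIRNA_BASES)
  if (length(bad) > 0) {
    stop("invalid character(s) in target site: ", paste(bad, collapse = ", "))
  }
  seq
}

#' One-hot encode a target-site sequence
#'
#' Encodes a validated 20-nt sequence as 80 binary features: for each position
#' t1..t20 a block of four indicators in base order A, U, C, G
#' (A = `[1,0,0,0]`, U = `[0,1,0,0]`, C = `[0,0,1,0]`, G = `[0,0,0,1]`),
#' blocks appended in sequence order.
#'
#' @param seq a 20-nt sequence (validated with [validate_target_site()]).
#' @return numeric vector of length 80.
#' @examples
#' v <- one_hot_encode(strrep("AUCG", 5))
#' sum(v)  # 20: one hot base per position
#' @export
one_hot_encode <- function(seq) {
  seq <- validate_target_site(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  base_idx <- match(chars, SIRNA_BASES)
  vec <- numeric(4L * SIRNA_SITE_LENGTH)
  vec[(seq_len(SIRNA_SITE_LENGTH) - 1L) * 4L + base_idx] <- 1
  names(vec) <- feature_names()
  vec
}

# Feature names tXX_B in block order; used as model column names.
feature_names <- function() {
  paste0(
    rep(sprintf("t%02d", seq_len(SIRNA_SITE_LENGTH)), each = 4L),
    "_",
    rep(SIRNA_BASES, times = SIRNA_SITE_LENGTH)
  )
}

#' Reshape an 80-vector of position-base values into a 20 x 4 matrix
#'
#' Inverse of the block flattening performed by [one_hot_encode()]: row `p`
#' holds the four base values of position `t<p>`, columns in base order
#' A, U, C, G. Applies equally to averaged (non-binary) vectors such as group
#' frequency means.
#'
#' @param vec numeric vector of length 80.
#' @return 20 x 4 numeric matrix with dimnames `t1..t20` by `A,U,C,G`.
#' @export
vector_to_matrix <- function(vec) {
  if (!is.numeric(vec) || length(vec) != 80L) {
    stop("expected a numeric vector of length 80, got length ", length(vec))
  }
  matrix(vec, nrow = SIRNA_SITE_LENGTH, ncol = 4L, byrow = TRUE,
         dimnames = list(paste0("t", seq_len(SIRNA_SITE_LENGTH)), SIRNA_BASES))
}

#' Flatten a 20 x 4 position-base matrix into an 80-vector
#'
#' Inverse of [vector_to_matrix()].
#'
#' @param mat 20 x 4 numeric matrix (rows t1..t20, columns A,U,C,G).
#' @return numeric vector of length 80.
#' @export
matrix_to_vector <- function(mat) {
  if (!is.matrix(mat) || !all(dim(mat) == c(SIRNA_SITE_LENGTH, 4L))) {
    stop("expected a 20 x 4 matrix")
  }
  vec <- as.numeric(t(mat))
  names(vec) <- feature_names()
  vec
}

#' Encode a dataset of siRNA records into a feature matrix
#'
#' @param records an siRNA dataset (data frame with at least `id` and
#'   `target_site` columns, as returned by [read_sirna_dataset()] or
#'   [generate_sirna_dataset()]).
#' @return numeric matrix, one row per record (rownames = ids), 80 columns.
#' @export
encode_dataset <- function(records) {
  stopifnot(is.data.frame(records), all(c("id", "target_site") %in% names(records)))
  X <- t(vapply(records$target_site, one_hot_encode, numeric(80L)))
  rownames(X) <- records$id
  colnames(X) <- feature_names()
  X
}
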