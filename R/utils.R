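# Internal helpers shared across modules.

#' Evaluate code under a local RNG state
#'
#' Runs `code` with the Mersenne-Twister generator seeded to `seed`, restoring
#' the caller's RNG state afterwards so package functions never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

# Deterministic child seed from a master seed, kept inside 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483629L + 1)
}

# Near-equal chunk sizes: n split into k parts differing by at most one,
# remainder given to the first parts when `front` else to the last.
chunk_sizes <- function(n, k, front = TRUE) {
  base <- n %/% k
  r <- n %% k
  extra <- if (front) c(rep(1L, r), rep(0L, k - r)) else c(rep(0L, k - r), rep(1L, r))
  base + extra
}

# round() with half-away-from-zero tie rule, for deterministic split sizes.
round_half_up <- function(x) floor(x + 0.5)

is_binary_labels <- function(y) {
  all(y %in% c(0, 1)) || is.logical(y)
}

# Coerce class labels to logical "is positive (effective)" flags.
as_positive <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lab <- as.character(y)
    bad <- setdiff(unique(lab), c("effective", "ineffective"))
    if (length(bad) > 0) {
      stop("labels must be 'effective'/'ineffective' (got: ",
           paste(bad, collapse = ", "), ")")
    }
    lab == "effective"
  } else if (is.logical(y)) {
    y
  } else if (is.numeric(y) && all(y %in% c(0, 1))) {
    y == 1
  } else {
    stop("labels must be binary (0/1, logical, or effective/ineffective)")
  }
}
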