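# Shared fixtures and independent oracles for the test suite.

poly_site <- function(base) strrep(base, 20)

random_site <- function() {
  paste(sample(c("A", "U", "C", "G"), 20, replace = TRUE), collapse = "")
}

# Minimal valid dataset of n records with the given efficacies.
tiny_dataset <- function(efficacies, genes = NULL, sites = NULL) {
  n <- length(efficacies)
  data.frame(
    id = sprintf("s%03d", seq_len(n)),
    gene = if (is.null(genes)) rep("geneA", n) else genes,
    target_site = if (is.null(sites)) {
      vapply(seq_len(n), function(i) random_site(), character(1))
    } else sites,
    efficacy_pct = efficacies,
    stringsAsFactors = FALSE
  )
}

# Random binary-labeled scoring instance with at least one record per class.
random_instance <- function(n_max = 30) {
  repeat {
    n <- sample(2:n_max, 1)
    y <- sample(0:1, n, replace = TRUE)
    # ties are common on purpose: draw scores from a coarse grid half the time
    s <- if (stats::runif(1) < 0.5) {
      sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    } else {
      stats::runif(n)
    }
    if (any(y == 1) && any(y == 0)) return(list(y = y, s = s))
  }
}

# Brute-force precision-recall oracle: enumerate every distinct margin
# (prediction positive iff score > margin), count cells explicitly, and
# integrate the area as sum over points, in non-decreasing recall order, of
# (r_i - r_{i-1}) * p_i with r_0 = 0. Kept deliberately naive (O(n^2)).
oracle_pr <- function(y, s) {
  margins <- c(sort(unique(s), decreasing = TRUE), -Inf)
  n_pos <- sum(y == 1)
  pts <- matrix(NA_real_, nrow = length(margins), ncol = 2)
  for (i in seq_along(margins)) {
    tp <- 0; fp <- 0
    for (j in seq_along(s)) {
      if (s[j] > margins[i]) {
        if (y[j] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    pts[i, 1] <- tp / n_pos
    pts[i, 2] <- if (tp + fp == 0) 1 else tp / (tp + fp)
  }
  area <- 0
  prev_r <- 0
  for (i in seq_len(nrow(pts))) {
    area <- area + (pts[i, 1] - prev_r) * pts[i, 2]
    prev_r <- pts[i, 1]
  }
  prevalence <- n_pos / length(y)
  list(points = pts, aucpr = area, p_r1 = prevalence,
       aucpr_adj = area - prevalence)
}

# Concordant-pair ROC oracle, ties counted half.
oracle_roc <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}
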