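#' Count single-nucleotide and paired features in a tDNA dataset
#'
#' A *feature* is a nucleotide at a Sprinzl position (single) or an ordered
#' nucleotide pair at one of the map's canonical base pairs (paired). Gaps
#' and ambiguity codes yield no features; a paired feature is counted only
#' when both member columns are ungapped.
#'
#' @param dataset A non-empty [tdna_dataset()].
#' @param use_pairs Count paired features over the map's pair list
#'   (default `TRUE`).
#' @return An object of class `"feature_counts"`: total and per-class tDNA
#'   counts plus per-feature and per-(feature, class) occurrence counts,
#'   stored densely as `single` (columns x 4 states), `single_class`
#'   (columns x 4 x 22 classes) and, when `use_pairs`, `pair`
#'   (pairs x 16 ordered states) and `pair_class`.
#' @export
count_features <- function(dataset, use_pairs = TRUE) {
  stopifnot(inherits(dataset, "tdna_dataset"))
  n <- nrow(dataset$records)
  if (n == 0) stop("empty dataset")
  M <- encode_matrix(dataset)
  ci <- class_index(dataset)
  L <- ncol(M)
  K <- length(CLASS_ALPHABET)
  n_class <- tabulate(ci, K)
  names(n_class) <- CLASS_ALPHABET

  single_class <- array(0L, c(L, 4, K))
  for (k in which(n_class > 0)) {
    Mk <- M[ci == k, , drop = FALSE]
    for (b in 1:4) single_class[, b, k] <- colSums(Mk == b)
  }
  single <- rowSums(single_class, dims = 2)

  pair <- pair_class <- NULL
  pidx <- .pair_index(dataset$sprinzl)
  if (use_pairs && nrow(pidx)) {
    P <- nrow(pidx)
    A5 <- M[, pidx[, 1], drop = FALSE]
    A3 <- M[, pidx[, 2], drop = FALSE]
    PC <- ifelse(A5 > 0 & A3 > 0, (A5 - 1L) * 4L + A3, 0L)
    pair_class <- array(0L, c(P, 16, K))
    for (k in which(n_class > 0)) {
      Pk <- PC[ci == k, , drop = FALSE]
      for (b in 1:16) pair_class[, b, k] <- colSums(Pk == b)
    }
    pair <- rowSums(pair_class, dims = 2)
  }
  structure(list(n_total = n, n_class = n_class,
                 single = single, single_class = single_class,
                 pair = pair, pair_class = pair_class,
                 use_pairs = use_pairs && nrow(pidx) > 0,
                 sprinzl = dataset$sprinzl),
            class = "feature_counts")
}

#' @export
print.feature_counts <- function(x, ...) {
  cat("Feature counts over", x$n_total, "tDNAs:",
      sum(x$single > 0), "single features",
      if (x$use_pairs) paste0("and ", sum(x$pair > 0), " paired features"),
      "\n")
  invisible(x)
}

#' Empirical class background distribution
#'
#' The background is the empirical frequency of each functional class among
#' the counted tDNAs (the taxon-set class-sampling distribution).
#'
#' @param counts A [count_features()] result.
#' @return Named numeric vector over the 22-class alphabet summing to 1
#'   (absent classes have probability 0).
#' @export
background_distribution <- function(counts) {
  stopifnot(inherits(counts, "feature_counts"), counts$n_total > 0)
  counts$n_class / counts$n_total
}

## Shannon entropy (bits) of probability vector(s); rows of a matrix
entropy_bits <- function(p) {
  if (is.matrix(p)) {
    x <- ifelse(p > 0, p * log2(p), 0)
    -rowSums(x)
  } else {
    -sum(ifelse(p > 0, p * log2(p), 0))
  }
}
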