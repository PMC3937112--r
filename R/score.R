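## Internal scoring engine.  All classifiers reduce to sums of logo letter
## heights over the features each tDNA presents, looked up in the logo's
## dense (column x state x class) arrays.

## pair-code matrix for a dataset's encode_matrix (n x P; 0 when a member
## column is gapped)
pair_code_matrix <- function(M, sprinzl) {
  pidx <- .pair_index(sprinzl)
  if (!nrow(pidx)) return(NULL)
  A5 <- M[, pidx[, 1], drop = FALSE]
  A3 <- M[, pidx[, 2], drop = FALSE]
  ifelse(A5 > 0 & A3 > 0, (A5 - 1L) * 4L + A3, 0L)
}

## per-tDNA height sums against one logo; col_weights (length L) gives each
## alignment column a multiplicity (site bootstrap); paired features ride
## their 5' member column
per_tdna_heights <- function(M, PC, ci, logo, col_weights = NULL) {
  n <- nrow(M)
  L <- ncol(M)
  K <- length(logo$classes)
  s <- numeric(n)
  idx <- which(M > 0)
  if (length(idx)) {
    i <- (idx - 1L) %% n + 1L
    l <- (idx - 1L) %/% n + 1L
    v <- logo$single_heights[l + (M[idx] - 1L) * L +
                               (ci[i] - 1L) * (L * 4L)]
    if (!is.null(col_weights)) v <- v * col_weights[l]
    acc <- rowsum(v, i)
    s[as.integer(rownames(acc))] <- acc
  }
  if (logo$use_pairs && !is.null(PC) && !is.null(logo$pair_heights)) {
    P <- ncol(PC)
    pidx <- .pair_index(logo$sprinzl)
    idx <- which(PC > 0)
    if (length(idx)) {
      i <- (idx - 1L) %% n + 1L
      p <- (idx - 1L) %/% n + 1L
      v <- logo$pair_heights[p + (PC[idx] - 1L) * P +
                               (ci[i] - 1L) * (P * 16L)]
      if (!is.null(col_weights)) v <- v * col_weights[pidx[p, 1]]
      acc <- rowsum(v, i)
      s[as.integer(rownames(acc))] <- s[as.integer(rownames(acc))] + acc
    }
  }
  s
}

## per-column mean contribution vector a (length L): the genome's mean
## per-tDNA score under column multiplicities w is sum(w * a)
column_contrib <- function(M, PC, ci, logo) {
  n <- nrow(M)
  L <- ncol(M)
  a <- numeric(L)
  idx <- which(M > 0)
  if (length(idx)) {
    i <- (idx - 1L) %% n + 1L
    l <- (idx - 1L) %/% n + 1L
    v <- logo$single_heights[l + (M[idx] - 1L) * L +
                               (ci[i] - 1L) * (L * 4L)]
    acc <- rowsum(v, l)
    a[as.integer(rownames(acc))] <- acc
  }
  if (logo$use_pairs && !is.null(PC) && !is.null(logo$pair_heights)) {
    P <- ncol(PC)
    pidx <- .pair_index(logo$sprinzl)
    idx <- which(PC > 0)
    if (length(idx)) {
      i <- (idx - 1L) %% n + 1L
      p <- (idx - 1L) %/% n + 1L
      v <- logo$pair_heights[p + (PC[idx] - 1L) * P +
                               (ci[i] - 1L) * (P * 16L)]
      l5 <- pidx[p, 1]
      acc <- rowsum(v, l5)
      a[as.integer(rownames(acc))] <- a[as.integer(rownames(acc))] + acc
    }
  }
  a / n
}

## logo with all-zero heights (e.g. an LOOCV training set emptied out)
empty_logo <- function(sprinzl, use_pairs = TRUE) {
  L <- length(sprinzl$labels)
  K <- length(CLASS_ALPHABET)
  P <- nrow(sprinzl$pairs)
  structure(list(background = stats::setNames(rep(0, K), CLASS_ALPHABET),
                 classes = CLASS_ALPHABET, sprinzl = sprinzl, n_total = 0L,
                 use_pairs = use_pairs && P > 0,
                 single_n = matrix(0L, L, 4),
                 single_info = matrix(0, L, 4),
                 single_heights = array(0, c(L, 4, K)),
                 pair_n = if (use_pairs && P > 0) matrix(0L, P, 16),
                 pair_info = if (use_pairs && P > 0) matrix(0, P, 16),
                 pair_heights = if (use_pairs && P > 0)
                   array(0, c(P, 16, K)),
                 correction = list(method = "none", height_filter = NULL)),
            class = "function_logo")
}

## feature-count subtraction (for leave-one-out logo rebuilds)
subtract_counts <- function(total, part) {
  out <- total
  out$n_total <- total$n_total - part$n_total
  out$n_class <- total$n_class - part$n_class
  out$single <- total$single - part$single
  out$single_class <- total$single_class - part$single_class
  if (!is.null(total$pair)) {
    out$pair <- total$pair - part$pair
    out$pair_class <- total$pair_class - part$pair_class
  }
  out
}

## logo from possibly-empty counts
logo_or_empty <- function(counts, sprinzl, use_pairs, correction, mc_reps,
                          seed) {
  if (counts$n_total == 0) return(empty_logo(sprinzl, use_pairs))
  logo_from_counts(counts, correction = correction, mc_reps = mc_reps,
                   seed = seed)
}
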