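#' Build class-specific sequence profiles from a taxon set
#'
#' The total-sequence control model: for every functional class, the
#' per-position relative frequency of each nucleotide among that class's
#' tDNAs (`q`), plus the class frequencies in the taxon set (`r`). Gapped
#' observations contribute no state mass.
#'
#' @param dataset A non-empty [tdna_dataset()].
#' @return An object of class `"class_profiles"` holding `q` (columns x 4
#'   states x 22 classes), `r`, per-class counts and the Sprinzl map.
#' @export
build_profiles <- function(dataset) {
  counts <- count_features(dataset, use_pairs = FALSE)
  profiles_from_counts(counts)
}

profiles_from_counts <- function(counts) {
  K <- length(CLASS_ALPHABET)
  q <- counts$single_class * 0
  for (k in which(counts$n_class > 0))
    q[, , k] <- counts$single_class[, , k] / counts$n_class[k]
  structure(list(q = q,
                 r = counts$n_class / max(counts$n_total, 1L),
                 n_class = counts$n_class,
                 n_total = counts$n_total,
                 counts = counts$single_class,
                 sprinzl = counts$sprinzl),
            class = "class_profiles")
}

#' @export
print.class_profiles <- function(x, ...) {
  cat("Class-specific sequence profiles from ", x$n_total, " tDNAs, ",
      sum(x$n_class > 0), " classes present\n", sep = "")
  invisible(x)
}

#' Total-sequence log-odds score of a genome
#'
#' Scores each tDNA by the log-odds of its full sequence under
#' class-specific profiles from two taxon sets: a class-prior term
#' `log2 rA(c) - log2 rB(c)` plus per-feature terms
#' `log2 qA(f|c) - log2 qB(f|c)`, averaged over the genome's tDNAs.
#' Four treatments of features unobserved in a training set:
#' \describe{
#'   \item{zero}{feature terms with `qA = 0` or `qB = 0` contribute 0;}
#'   \item{skip}{such features are omitted and the per-tDNA feature sum is
#'     the mean over scored features, so unscoreable features neither
#'     dilute nor zero-pad;}
#'   \item{pseudo}{frequencies are Laplace-smoothed per position-state,
#'     `(count + pseudocount) / (n_class + 4 pseudocount)`;}
#'   \item{small}{zero frequencies are replaced by `eps`, by default
#'     `1 / (2 max class count)` over both sets, below any observable
#'     nonzero frequency.}
#' }
#' Under `zero`/`skip` a class absent from a profile gets class-prior
#' term 0 with a warning; under `pseudo`/`small` priors are smoothed.
#'
#' @param genome A non-empty [tdna_dataset()].
#' @param profA,profB [build_profiles()] results for the two taxon sets.
#' @param method One of `"zero"`, `"skip"`, `"pseudo"`, `"small"`.
#' @param eps Replacement frequency for `"small"`; default
#'   `1 / (2 max(n_class))` over both profiles.
#' @param pseudocount Laplace pseudocount for `"pseudo"` (default 1).
#' @return Scalar score in bits per tDNA (positive favours set A).
#' @export
score_profile <- function(genome, profA, profB,
                          method = c("zero", "skip", "pseudo", "small"),
                          eps = NULL, pseudocount = 1) {
  method <- match.arg(method)
  if (n_tdnas(genome) == 0) stop("empty genome")
  n <- n_tdnas(genome)
  M <- encode_matrix(genome)
  ci <- class_index(genome)
  L <- ncol(M)

  if (method == "small" && is.null(eps))
    eps <- 1 / (2 * max(profA$n_class, profB$n_class, 1L))

  smooth_q <- function(prof) switch(method,
    pseudo = {
      den <- rep(prof$n_class + 4 * pseudocount, each = L * 4)
      (prof$counts + pseudocount) / array(den, dim(prof$counts))
    },
    small = ifelse(prof$q > 0, prof$q, eps),
    prof$q)
  smooth_r <- function(prof) switch(method,
    pseudo = (prof$n_class + pseudocount) /
      (prof$n_total + length(CLASS_ALPHABET) * pseudocount),
    small = ifelse(prof$r > 0, prof$r, eps),
    prof$r)

  qA <- smooth_q(profA); qB <- smooth_q(profB)
  rA <- smooth_r(profA); rB <- smooth_r(profB)

  cls_used <- unique(ci)
  prior <- numeric(length(CLASS_ALPHABET))
  bad <- cls_used[rA[cls_used] == 0 | rB[cls_used] == 0]
  if (length(bad)) {
    warning("class(es) absent from a profile, prior term set to 0: ",
            paste(CLASS_ALPHABET[bad], collapse = ", "))
    ok <- setdiff(cls_used, bad)
    prior[ok] <- log2(rA[ok]) - log2(rB[ok])
  } else {
    prior[cls_used] <- log2(rA[cls_used]) - log2(rB[cls_used])
  }

  idx <- which(M > 0)
  i <- (idx - 1L) %% n + 1L
  l <- (idx - 1L) %/% n + 1L
  lin <- l + (M[idx] - 1L) * L + (ci[i] - 1L) * (L * 4L)
  a <- qA[lin]; b <- qB[lin]
  feat <- numeric(n)
  if (method %in% c("zero", "skip")) {
    scored <- a > 0 & b > 0
    ell <- ifelse(scored, log2(ifelse(a > 0, a, 1)) -
                    log2(ifelse(b > 0, b, 1)), 0)
    if (method == "zero") {
      acc <- rowsum(ell, i)
      feat[as.integer(rownames(acc))] <- acc
    } else {
      acc <- rowsum(ell[scored], i[scored])
      cnt <- rowsum(rep(1, sum(scored)), i[scored])
      feat[as.integer(rownames(acc))] <- acc / cnt
    }
  } else {
    ell <- log2(a) - log2(b)
    acc <- rowsum(ell, i)
    feat[as.integer(rownames(acc))] <- acc
  }
  mean(prior[ci] + feat)
}

#' Profile classification with leave-one-out cross-validation
#'
#' As [loocv_binary()], with class profiles (rather than function logos)
#' rebuilt excluding the scored genome.
#'
#' @inheritParams loocv_binary
#' @inheritParams score_profile
#' @return data.frame with columns `genome_id`, `score`, `n_tdnas`,
#'   `side`.
#' @export
loocv_profile <- function(datasetA, datasetB, query_genomes = NULL,
                          method = c("zero", "skip", "pseudo", "small"),
                          eps = NULL, pseudocount = 1) {
  method <- match.arg(method)
  gA <- unique(datasetA$records$genome_id)
  gB <- unique(datasetB$records$genome_id)
  both <- intersect(gA, gB)
  if (length(both))
    stop("genome present in both taxon sets: ",
         paste(both, collapse = ", "))
  cA <- count_features(datasetA, use_pairs = FALSE)
  cB <- count_features(datasetB, use_pairs = FALSE)
  profA <- profiles_from_counts(cA)
  profB <- profiles_from_counts(cB)
  score_one <- function(genome, pA, pB, side) {
    data.frame(genome_id = genome$records$genome_id[1],
               score = score_profile(genome, pA, pB, method, eps,
                                     pseudocount),
               n_tdnas = n_tdnas(genome), side = side,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in gA) {
    part <- subset_genomes(datasetA, g)
    pA <- profiles_from_counts(
      subtract_counts(cA, count_features(part, use_pairs = FALSE)))
    rows[[length(rows) + 1]] <- score_one(part, pA, profB, "A")
  }
  for (g in gB) {
    part <- subset_genomes(datasetB, g)
    pB <- profiles_from_counts(
      subtract_counts(cB, count_features(part, use_pairs = FALSE)))
    rows[[length(rows) + 1]] <- score_one(part, profA, pB, "B")
  }
  if (!is.null(query_genomes)) {
    for (g in unique(query_genomes$records$genome_id)) {
      part <- subset_genomes(query_genomes, g)
      rows[[length(rows) + 1]] <- score_one(part, profA, profB, "query")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
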