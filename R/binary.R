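#' Binary CIF-match score of a genome
#'
#' For each tDNA of the genome, sums the differences in letter heights of
#' its features between two function logos at the tDNA's own functional
#' class, then averages over the genome's tDNA multiset (bits per tDNA).
#' Positive scores favour the taxon set behind `logoA`, negative scores
#' `logoB`; features absent from a logo contribute height 0 on that side.
#'
#' @param genome A non-empty [tdna_dataset()] (typically one genome).
#' @param logoA,logoB [function_logo()] objects sharing the genome's
#'   Sprinzl map.
#' @return Scalar score in bits per tDNA.
#' @export
score_binary <- function(genome, logoA, logoB) {
  if (n_tdnas(genome) == 0) stop("empty genome")
  M <- encode_matrix(genome)
  PC <- pair_code_matrix(M, genome$sprinzl)
  ci <- class_index(genome)
  mean(per_tdna_heights(M, PC, ci, logoA) -
         per_tdna_heights(M, PC, ci, logoB))
}

#' Per-class breakout of binary CIF scores
#'
#' Splits a genome's binary score into per-functional-class contributions;
#' each class's entry is the mean per-tDNA score difference over that
#' class's tDNAs, so the count-weighted sum over classes recovers the
#' genome total.
#'
#' @inheritParams score_binary
#' @return Named numeric vector over the 22-class alphabet (classes with
#'   no tDNAs in the genome are 0), with attribute `"n_class"` holding the
#'   per-class tDNA counts.
#' @export
class_breakout <- function(genome, logoA, logoB) {
  if (n_tdnas(genome) == 0) stop("empty genome")
  M <- encode_matrix(genome)
  PC <- pair_code_matrix(M, genome$sprinzl)
  ci <- class_index(genome)
  d <- per_tdna_heights(M, PC, ci, logoA) -
    per_tdna_heights(M, PC, ci, logoB)
  K <- length(CLASS_ALPHABET)
  nc <- tabulate(ci, K)
  out <- stats::setNames(rep(0, K), CLASS_ALPHABET)
  agg <- rowsum(d, ci)
  kk <- as.integer(rownames(agg))
  out[kk] <- agg / nc[kk]
  attr(out, "n_class") <- stats::setNames(nc, CLASS_ALPHABET)
  out
}

#' Binary CIF classification with leave-one-out cross-validation
#'
#' Scores every genome of two disjoint taxon sets against function logos
#' rebuilt with that genome's own tDNAs removed from its side, and scores
#' external query genomes against the full logos.
#'
#' @param datasetA,datasetB [tdna_dataset()] objects for the two taxon
#'   sets; their genome sets must be disjoint.
#' @param query_genomes Optional [tdna_dataset()] of genomes outside both
#'   sets, scored against the full logos.
#' @param use_pairs,correction,mc_reps,seed Logo options, see
#'   [function_logo()].
#' @param height_filter Optional height threshold (bits); logos are
#'   truncated with [filter_logo()] before scoring.
#' @return data.frame with columns `genome_id`, `score` (bits/tDNA),
#'   `n_tdnas` and `side` (`"A"`, `"B"` or `"query"`).
#' @export
loocv_binary <- function(datasetA, datasetB, query_genomes = NULL,
                         use_pairs = TRUE, correction = c("mc", "none"),
                         mc_reps = 1000, seed = 1, height_filter = NULL) {
  correction <- match.arg(correction)
  gA <- unique(datasetA$records$genome_id)
  gB <- unique(datasetB$records$genome_id)
  both <- intersect(gA, gB)
  if (length(both))
    stop("genome present in both taxon sets: ",
         paste(both, collapse = ", "))
  cA <- count_features(datasetA, use_pairs)
  cB <- count_features(datasetB, use_pairs)
  mk <- function(counts, sprinzl) {
    lg <- logo_or_empty(counts, sprinzl, use_pairs, correction, mc_reps,
                        seed)
    if (!is.null(height_filter)) lg <- filter_logo(lg, height_filter)
    lg
  }
  logoA <- mk(cA, datasetA$sprinzl)
  logoB <- mk(cB, datasetB$sprinzl)

  score_one <- function(genome, lA, lB) {
    data.frame(genome_id = genome$records$genome_id[1],
               score = score_binary(genome, lA, lB),
               n_tdnas = n_tdnas(genome), stringsAsFactors = FALSE)
  }
  rows <- list()
  for (g in gA) {
    part <- subset_genomes(datasetA, g)
    lA <- mk(subtract_counts(cA, count_features(part, use_pairs)),
             datasetA$sprinzl)
    rows[[length(rows) + 1]] <- cbind(score_one(part, lA, logoB),
                                      side = "A")
  }
  for (g in gB) {
    part <- subset_genomes(datasetB, g)
    lB <- mk(subtract_counts(cB, count_features(part, use_pairs)),
             datasetB$sprinzl)
    rows[[length(rows) + 1]] <- cbind(score_one(part, logoA, lB),
                                      side = "B")
  }
  if (!is.null(query_genomes)) {
    for (g in unique(query_genomes$records$genome_id)) {
      part <- subset_genomes(query_genomes, g)
      rows[[length(rows) + 1]] <- cbind(score_one(part, logoA, logoB),
                                        side = "query")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
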