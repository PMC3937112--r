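#' Base composition of tDNA groups
#'
#' Counts A/C/G/T over the ungapped residues of all tDNAs in each group
#' (by clade via the dataset's taxon map, or by genome). Zero counts are
#' smoothed by +0.5 before proportions are formed, so downstream log-ratio
#' transforms are always defined.
#'
#' @param dataset A non-empty [tdna_dataset()].
#' @param group_by `"clade"` (requires `dataset$taxon_of`; genomes without
#'   a clade are dropped with a warning) or `"genome"`.
#' @return data.frame of class `"tdna_composition"`: one row per group
#'   with raw counts (`A,C,G,T`), smoothed proportions (`p_A..p_T`), total
#'   residues and `gc` content.
#' @export
base_composition <- function(dataset, group_by = c("clade", "genome")) {
  group_by <- match.arg(group_by)
  if (n_tdnas(dataset) == 0) stop("empty dataset")
  M <- encode_matrix(dataset)
  grp <- if (group_by == "genome") {
    dataset$records$genome_id
  } else {
    if (is.null(dataset$taxon_of))
      stop("group_by = 'clade' requires a taxon map on the dataset")
    cl <- unname(dataset$taxon_of[dataset$records$genome_id])
    if (anyNA(cl)) {
      warning("dropping ", sum(is.na(cl)), " tDNA(s) from genomes ",
              "without a clade assignment")
    }
    cl
  }
  keep <- !is.na(grp)
  M <- M[keep, , drop = FALSE]
  grp <- grp[keep]
  groups <- sort(unique(grp))
  cnt <- t(vapply(groups, function(g) {
    m <- M[grp == g, , drop = FALSE]
    if (nrow(m) == 0) stop("empty group ", dQuote(g))
    tabulate(m[m > 0], 4L)
  }, integer(4)))
  colnames(cnt) <- NUC
  sm <- cnt
  sm[sm == 0] <- 0.5
  props <- sm / rowSums(sm)
  out <- data.frame(group = groups, cnt, props,
                    total = rowSums(cnt),
                    gc = props[, "G"] + props[, "C"],
                    stringsAsFactors = FALSE)
  names(out)[6:9] <- paste0("p_", NUC)
  rownames(out) <- NULL
  class(out) <- c("tdna_composition", "data.frame")
  out
}

#' Centered log-ratio transform of base compositions
#'
#' `clr_i = log(p_i / geometric_mean(p))`; each transformed vector sums
#' to 0. Natural log by default (the log base rescales all CLR vectors by
#' a constant and leaves cluster topology unchanged); the base is recorded
#' in the `"log_base"` attribute.
#'
#' @param x A [base_composition()] result, or a numeric vector/matrix of
#'   strictly positive proportions (rows = groups).
#' @param base Log base (default `exp(1)`).
#' @return Numeric matrix of CLR coordinates (rows = groups), with
#'   attribute `"log_base"`.
#' @export
clr <- function(x, base = exp(1)) {
  p <- if (inherits(x, "tdna_composition")) {
    m <- as.matrix(x[paste0("p_", NUC)])
    rownames(m) <- x$group
    colnames(m) <- NUC
    m
  } else if (is.null(dim(x))) matrix(x, 1, dimnames = list(NULL, names(x)))
  else as.matrix(x)
  if (any(p <= 0)) stop("clr requires strictly positive proportions")
  lp <- log(p, base = base)
  out <- lp - rowMeans(lp)
  attr(out, "log_base") <- base
  out
}

#' Aitchison distance matrix of group compositions
#'
#' Euclidean distances between CLR-transformed compositions; invariant to
#' rescaling any group's counts by a positive constant.
#'
#' @param x A [base_composition()] result, a matrix of proportions (rows =
#'   groups), or a CLR matrix already produced by [clr()] (recognized by
#'   its `"log_base"` attribute).
#' @param base Log base passed to [clr()].
#' @return A symmetric `dist` object.
#' @export
composition_distance <- function(x, base = exp(1)) {
  z <- if (is.null(attr(x, "log_base"))) clr(x, base = base) else x
  stats::dist(z)
}

#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic-mean linkage; the returned
#' tree is ultrametric with branch lengths on the half-distance scale
#' (leaves joined at distance d sit at height d/2). Ties are broken
#' deterministically by label order.
#'
#' @param d A `dist` object or symmetric non-negative matrix.
#' @param labels Optional leaf labels overriding those of `d`.
#' @return An [ape::as.phylo()] tree (class `"phylo"`); write Newick with
#'   [ape::write.tree()].
#' @export
upgma <- function(d, labels = NULL) {
  m <- as.matrix(d)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) || any(m < 0))
    stop("distance matrix must be symmetric and non-negative")
  if (!is.null(labels)) rownames(m) <- colnames(m) <- labels
  if (is.null(rownames(m)))
    rownames(m) <- colnames(m) <- paste0("g", seq_len(nrow(m)))
  ## label-order leaves so hclust tie-breaking is reproducible
  ord <- order(rownames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::ladderize(ape::as.phylo(hc))
}

#' Compositional clustering of tDNA groups
#'
#' Convenience wrapper: [base_composition()] by clade or genome, [clr()],
#' Euclidean distances and [upgma()].
#'
#' @inheritParams base_composition
#' @param base Log base for the CLR transform.
#' @return List with `composition`, `clr`, `dist` and the UPGMA `tree`
#'   (`"phylo"`), plus `newick`, the tree serialized by
#'   [ape::write.tree()].
#' @export
composition_cluster <- function(dataset, group_by = c("clade", "genome"),
                                base = exp(1)) {
  comp <- base_composition(dataset, group_by = group_by)
  z <- clr(comp, base = base)
  d <- stats::dist(z)
  tree <- upgma(d)
  list(composition = comp, clr = z, dist = d, tree = tree,
       newick = ape::write.tree(tree))
}
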