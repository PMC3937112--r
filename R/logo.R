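## ---- sample-size correction ------------------------------------------------

## cache of Monte-Carlo expected-entropy deficits, keyed by
## (n, reps, seed, background); shared across logo builds in a session
.mc_cache <- new.env(parent = emptyenv())

## run code under a derived RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## E[ H(background) - H(empirical class distribution of n i.i.d. draws) ]
## estimated by mc_reps seeded multinomial replicates; vector over ns
mc_entropy_deficit <- function(ns, bg, mc_reps, seed) {
  bgp <- bg[bg > 0]
  Hbg <- entropy_bits(bgp)
  key_bg <- paste(signif(bgp, 12), collapse = ",")
  out <- numeric(length(ns))
  for (i in seq_along(ns)) {
    n <- ns[i]
    key <- paste(n, mc_reps, seed, key_bg, sep = "|")
    if (!is.null(.mc_cache[[key]])) {
      out[i] <- .mc_cache[[key]]
      next
    }
    e <- with_seed((seed + 7919 * (n %% 100000L)) %% 2147483647L, {
      X <- stats::rmultinom(mc_reps, n, bgp)
      P <- X / n
      Hemp <- -colSums(ifelse(X > 0, P * log2(P), 0))
      Hbg - mean(Hemp)
    })
    .mc_cache[[key]] <- e
    out[i] <- e
  }
  out
}

## ---- height kernel ---------------------------------------------------------

## FC: F x 22 per-class counts, nf = rowSums(FC) > 0, bg length 22.
## Returns list(info = F-vector, heights = F x 22) implementing the
## corrected-information x normalized-odds decomposition.
height_kernel <- function(FC, nf, bg, e) {
  K <- length(bg)
  pos <- bg > 0
  Hbg <- entropy_bits(bg[pos])
  post <- FC / nf
  info <- pmax(0, Hbg - entropy_bits(post) - e)
  odds <- sweep(post[, pos, drop = FALSE], 2, bg[pos], "/")
  w <- odds / rowSums(odds)
  heights <- matrix(0, nrow(FC), K, dimnames = list(NULL, names(bg)))
  heights[, pos] <- info * w
  list(info = info, heights = heights)
}

## ---- the estimator ---------------------------------------------------------

#' Estimate a function logo from aligned tDNA data
#'
#' A function logo generalizes a sequence logo: for each feature (a
#' nucleotide at a Sprinzl position, or a nucleotide pair at a canonical
#' base pair) it measures, in bits, how informative that feature is about
#' tRNA functional class within the taxon set, and apportions that
#' information across classes by the normalized odds ratio of the feature's
#' appearance in each class. A feature's stack height is
#' `max(0, H(background) - H(class posterior | feature) - e(n))`, where the
#' background is the empirical class-sampling distribution of the taxon set
#' and `e(n)` is a sample-size correction; the per-class letter height is
#' the stack height times the normalized odds ratio, so letter heights sum
#' exactly to the stack height.
#'
#' The default sample-size correction subtracts the Monte-Carlo expected
#' entropy deficit of `n` i.i.d. class draws from the background
#' (`mc_reps` seeded replicates, cached per sample size), which removes the
#' positive bias of plug-in information at small counts.
#'
#' @param dataset A non-empty [tdna_dataset()].
#' @param use_pairs Include paired features over the map's pair list.
#' @param correction `"mc"` (Monte-Carlo expected-entropy subtraction,
#'   default) or `"none"`.
#' @param mc_reps Monte-Carlo replicates per distinct sample size.
#' @param seed Seed for the correction's random draws.
#' @return An object of class `"function_logo"` with the background
#'   distribution, per-feature corrected information, per-(feature, class)
#'   heights and per-feature sample sizes. Use [as.data.frame()] for a
#'   tidy table, [extract_cifs()] to threshold, [score_binary()] and
#'   friends to classify.
#' @examples
#' gen <- generate_tdna(benchmark_config(seed = 1, n_genomes = 3,
#'                                       genes_per_class = 1))
#' logo <- function_logo(partition_tdna(gen$dataset)[["C1"]],
#'                       correction = "none")
#' summary(logo, n = 3)
#' @export
function_logo <- function(dataset, use_pairs = TRUE,
                          correction = c("mc", "none"), mc_reps = 1000,
                          seed = 1) {
  correction <- match.arg(correction)
  counts <- count_features(dataset, use_pairs = use_pairs)
  logo <- logo_from_counts(counts, correction = correction,
                           mc_reps = mc_reps, seed = seed)
  logo$call <- match.call()
  logo
}

#' Estimate a function logo from precomputed feature counts
#'
#' @param counts A [count_features()] result.
#' @inheritParams function_logo
#' @return A `"function_logo"` object; see [function_logo()].
#' @export
logo_from_counts <- function(counts, correction = c("mc", "none"),
                             mc_reps = 1000, seed = 1) {
  correction <- match.arg(correction)
  stopifnot(inherits(counts, "feature_counts"))
  bg <- background_distribution(counts)
  K <- length(bg)
  L <- dim(counts$single_class)[1]

  compute_block <- function(counts_class, nmat) {
    dd <- dim(counts_class)
    FCfull <- matrix(counts_class, dd[1] * dd[2], dd[3])
    nf <- as.vector(nmat)
    sel <- nf > 0
    info <- matrix(0, dd[1], dd[2])
    heights <- array(0, dd)
    if (any(sel)) {
      e <- if (correction == "mc") {
        uns <- sort(unique(nf[sel]))
        etab <- mc_entropy_deficit(uns, bg, mc_reps, seed)
        etab[match(nf[sel], uns)]
      } else 0
      hk <- height_kernel(FCfull[sel, , drop = FALSE], nf[sel], bg, e)
      info[sel] <- hk$info
      hfull <- matrix(0, dd[1] * dd[2], dd[3])
      hfull[sel, ] <- hk$heights
      heights <- array(hfull, dd)
    }
    list(info = info, heights = heights)
  }

  sb <- compute_block(counts$single_class, counts$single)
  logo <- list(background = bg,
               classes = CLASS_ALPHABET,
               sprinzl = counts$sprinzl,
               n_total = counts$n_total,
               use_pairs = counts$use_pairs,
               single_n = counts$single,
               single_info = sb$info,
               single_heights = sb$heights,
               pair_n = NULL, pair_info = NULL, pair_heights = NULL,
               correction = list(method = correction,
                                 mc_reps = if (correction == "mc") mc_reps,
                                 seed = if (correction == "mc") seed,
                                 height_filter = NULL))
  if (counts$use_pairs) {
    pb <- compute_block(counts$pair_class, counts$pair)
    logo$pair_n <- counts$pair
    logo$pair_info <- pb$info
    logo$pair_heights <- pb$heights
  }
  class(logo) <- "function_logo"
  logo
}

#' Corrected information of one feature
#'
#' @param counts A [count_features()] result.
#' @param pos Sprinzl label (single feature) or length-2 vector of labels
#'   matching a canonical pair (paired feature).
#' @param state Nucleotide, or length-2 nucleotide vector for a pair.
#' @param correction,mc_reps,seed As in [function_logo()].
#' @return Corrected information in bits (non-negative scalar).
#' @export
feature_information <- function(counts, pos, state,
                                correction = c("mc", "none"),
                                mc_reps = 1000, seed = 1) {
  correction <- match.arg(correction)
  loc <- locate_feature(counts, pos, state)
  fc <- if (loc$kind == "single") {
    counts$single_class[loc$i, loc$b, ]
  } else counts$pair_class[loc$i, loc$b, ]
  nf <- sum(fc)
  if (nf == 0) stop("unseen feature at ", paste(pos, collapse = ":"))
  bg <- background_distribution(counts)
  e <- if (correction == "mc") mc_entropy_deficit(nf, bg, mc_reps, seed) else 0
  hk <- height_kernel(matrix(fc, 1), nf, bg, e)
  unname(hk$info)
}

## resolve (pos, state) to block indices
locate_feature <- function(counts, pos, state) {
  pos <- as.character(pos)
  state <- toupper(chartr("U", "T", as.character(state)))
  if (length(pos) == 1) {
    i <- match(pos, counts$sprinzl$labels)
    b <- match(state, NUC)
    if (is.na(i)) stop("unknown Sprinzl label ", dQuote(pos))
    if (is.na(b)) stop("state must be one of A,C,G,T")
    list(kind = "single", i = i, b = b)
  } else if (length(pos) == 2) {
    pr <- counts$sprinzl$pairs
    i <- which(pr$p5 == pos[1] & pr$p3 == pos[2])
    if (!length(i)) stop("no canonical pair ", pos[1], ":", pos[2])
    b <- (match(state[1], NUC) - 1L) * 4L + match(state[2], NUC)
    list(kind = "pair", i = i, b = b)
  } else stop("pos must have length 1 or 2")
}

## ---- methods ---------------------------------------------------------------

#' @export
print.function_logo <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Function logo over ", x$n_total, " tDNAs, ",
      sum(x$background > 0), " classes",
      if (!is.null(x$correction$height_filter))
        paste0(" (heights filtered at ", x$correction$height_filter,
               " bits)"),
      "\n  correction: ", x$correction$method,
      if (x$correction$method == "mc")
        paste0(" (", x$correction$mc_reps, " reps, seed ",
               x$correction$seed, ")"),
      "\n  ", nrow(df), " positive-height letters, max height ",
      format(max(c(df$height, 0)), digits = 4), " bits\n", sep = "")
  invisible(x)
}

#' @export
summary.function_logo <- function(object, n = 10, ...) {
  df <- as.data.frame(object)
  df <- df[order(-df$height), , drop = FALSE]
  cat("Top class-informative letters:\n")
  print(utils::head(df, n), row.names = FALSE)
  invisible(df)
}

#' @export
as.data.frame.function_logo <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  out <- list()
  sel <- which(x$single_heights > 0, arr.ind = TRUE)
  if (nrow(sel)) {
    out[[1]] <- data.frame(
      kind = "single",
      pos = x$sprinzl$labels[sel[, 1]],
      state = NUC[sel[, 2]],
      cls = x$classes[sel[, 3]],
      height = x$single_heights[sel],
      info = x$single_info[sel[, 1:2, drop = FALSE]],
      n = x$single_n[sel[, 1:2, drop = FALSE]],
      stringsAsFactors = FALSE)
  }
  if (x$use_pairs && !is.null(x$pair_heights)) {
    sel <- which(x$pair_heights > 0, arr.ind = TRUE)
    if (nrow(sel)) {
      pr <- x$sprinzl$pairs
      b1 <- (sel[, 2] - 1L) %/% 4L + 1L
      b2 <- (sel[, 2] - 1L) %% 4L + 1L
      out[[length(out) + 1]] <- data.frame(
        kind = "pair",
        pos = paste(pr$p5[sel[, 1]], pr$p3[sel[, 1]], sep = ":"),
        state = paste(NUC[b1], NUC[b2], sep = ":"),
        cls = x$classes[sel[, 3]],
        height = x$pair_heights[sel],
        info = x$pair_info[sel[, 1:2, drop = FALSE]],
        n = x$pair_n[sel[, 1:2, drop = FALSE]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(kind = character(0), pos = character(0),
                      state = character(0), cls = character(0),
                      height = numeric(0), info = numeric(0),
                      n = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' @export
plot.function_logo <- function(x, ...) {
  info <- rowSums(pmax(x$single_info, 0) *
                    (x$single_n > 0))
  names(info) <- x$sprinzl$labels
  graphics::barplot(info, las = 2, cex.names = 0.5,
                    ylab = "summed corrected information (bits)",
                    xlab = "Sprinzl position",
                    main = "Function logo: information by position", ...)
  invisible(x)
}

## ---- CIF extraction and filtering -----------------------------------------

#' Extract Class-Informative Features from a function logo
#'
#' Thresholds the logo's per-class letter heights: a CIF is a
#' (feature, class) pair whose height reaches `threshold_bits` (strictly
#' positive when the threshold is 0).
#'
#' @param logo A [function_logo()].
#' @param threshold_bits Non-negative height threshold in bits.
#' @return An object of class `"cif_set"`: a data.frame with columns
#'   `kind`, `pos`, `state`, `cls`, `height`, `info`, `n`, ordered by
#'   decreasing height, with the threshold stored as an attribute.
#' @export
extract_cifs <- function(logo, threshold_bits = 0) {
  stopifnot(threshold_bits >= 0)
  df <- as.data.frame(logo)
  keep <- if (threshold_bits > 0) df$height >= threshold_bits
          else df$height > 0
  df <- df[keep, , drop = FALSE]
  df <- df[order(-df$height), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "threshold_bits") <- threshold_bits
  class(df) <- c("cif_set", "data.frame")
  df
}

#' @export
print.cif_set <- function(x, ...) {
  cat("CIF set: ", nrow(x), " features at threshold ",
      attr(x, "threshold_bits"), " bits\n", sep = "")
  print(utils::head(as.data.frame(x), 12), row.names = FALSE)
  invisible(x)
}

#' Truncate a function logo to CIFs above a height threshold
#'
#' Returns a scoring model in which letter heights below `min_height` are
#' zeroed (the paper-style ">= 0.5 bits" reduced models); per-feature
#' information is recomputed as the sum of surviving letter heights so the
#' stack-conservation identity continues to hold.
#'
#' @param logo A [function_logo()].
#' @param min_height Height threshold in bits.
#' @return A `"function_logo"` usable wherever a full logo is.
#' @export
filter_logo <- function(logo, min_height) {
  logo$single_heights[logo$single_heights < min_height] <- 0
  logo$single_info <- rowSums(logo$single_heights, dims = 2)
  if (logo$use_pairs && !is.null(logo$pair_heights)) {
    logo$pair_heights[logo$pair_heights < min_height] <- 0
    logo$pair_info <- rowSums(logo$pair_heights, dims = 2)
  }
  logo$correction$height_filter <- min_height
  logo
}

## ---- permutation significance ----------------------------------------------

#' Permutation p-value for a (feature, class) height
#'
#' Shuffles functional class labels across tDNAs and recomputes the
#' feature's per-class height each time; the p-value is
#' `(1 + #{permuted >= observed}) / (reps + 1)`.
#'
#' @param dataset A [tdna_dataset()].
#' @param pos,state Feature address as in [feature_information()].
#' @param cls Functional class symbol.
#' @param reps Number of permutation replicates (>= 1).
#' @param seed Seed for the permutation stream.
#' @param correction `"none"` (default) or `"mc"`; under label shuffling
#'   the correction term is a constant offset at fixed feature count, so
#'   the p-value is correction-invariant.
#' @param mc_reps Monte-Carlo replicates when `correction = "mc"`.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(dataset, pos, state, cls, reps = 999,
                               seed = 1, correction = c("none", "mc"),
                               mc_reps = 1000) {
  correction <- match.arg(correction)
  if (reps < 1) stop("reps must be >= 1")
  counts <- count_features(dataset, use_pairs = TRUE)
  loc <- locate_feature(counts, pos, state)
  k <- match(cls, CLASS_ALPHABET)
  if (is.na(k)) stop("illegal class symbol ", dQuote(cls))
  M <- encode_matrix(dataset)
  present <- if (loc$kind == "single") {
    M[, loc$i] == ((loc$b - 1L) %% 4L + 1L) & M[, loc$i] > 0
  } else {
    pidx <- .pair_index(dataset$sprinzl)[loc$i, ]
    b1 <- (loc$b - 1L) %/% 4L + 1L
    b2 <- (loc$b - 1L) %% 4L + 1L
    M[, pidx[1]] == b1 & M[, pidx[2]] == b2
  }
  ci <- class_index(dataset)
  nf <- sum(present)
  if (nf == 0 || sum(ci[present] == k) == 0)
    stop("unseen (feature, class) combination")
  bg <- background_distribution(counts)
  e <- if (correction == "mc") mc_entropy_deficit(nf, bg, mc_reps, seed)
       else 0
  K <- length(CLASS_ALPHABET)
  height_of <- function(classes) {
    fc <- tabulate(classes[present], K)
    height_kernel(matrix(fc, 1), nf, bg, e)$heights[1, k]
  }
  obs <- height_of(ci)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(reps),
               function(r) height_of(sample(ci)) >= obs, logical(1)))
  })
  (1 + hits) / (reps + 1)
}

## ---- tabular export --------------------------------------------------------

#' Export a function logo as a TSV table
#'
#' Columns `position`, `state`, `class`, `height_bits`, `info_bits`, `n`,
#' sorted by alignment position (column order, pairs after their 5'
#' member) then by descending height; re-importable with
#' [read_logo_table()].
#'
#' @param logo A [function_logo()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_logo_table <- function(logo, path) {
  df <- as.data.frame(logo)
  p5 <- sub(":.*", "", df$pos)
  ord <- order(match(p5, logo$sprinzl$labels), df$kind, df$pos, -df$height)
  df <- df[ord, , drop = FALSE]
  out <- data.frame(position = df$pos, state = df$state, class = df$cls,
                    height_bits = sprintf("%.10g", df$height),
                    info_bits = sprintf("%.10g", df$info), n = df$n)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back an exported logo table
#' @param path Path written by [export_logo_table()].
#' @return data.frame with the exported columns (numeric heights).
#' @export
read_logo_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric", "numeric", "integer"))
}
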