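#' Per-clade CIF-match score vector of a genome
#'
#' For each clade's function logo, the mean over the genome's tDNAs of the
#' summed letter heights of their features at their own functional class
#' (bits per tDNA) — the input representation of the multiway classifier.
#'
#' @param genome A non-empty [tdna_dataset()].
#' @param clade_logos Named list (>= 2) of [function_logo()] objects.
#' @param clade_datasets Optional named list of the clades' training
#'   [tdna_dataset()]s, required for `loocv_exclude`.
#' @param loocv_exclude Optional genome ID: if that genome occurs in a
#'   clade's training set, that clade's logo is rebuilt without it before
#'   scoring (leave-one-out).
#' @param use_pairs,correction,mc_reps,seed Logo rebuild options.
#' @param height_filter Optional bits threshold applied to (rebuilt) logos
#'   via [filter_logo()].
#' @return Named numeric vector of per-clade scores (fixed clade order).
#' @export
clade_score_vector <- function(genome, clade_logos, clade_datasets = NULL,
                               loocv_exclude = NULL, use_pairs = TRUE,
                               correction = "mc", mc_reps = 1000, seed = 1,
                               height_filter = NULL) {
  if (length(clade_logos) < 2) stop("at least 2 clades are required")
  if (n_tdnas(genome) == 0) stop("empty genome")
  if (!is.null(loocv_exclude)) {
    if (is.null(clade_datasets))
      stop("loocv_exclude requires clade_datasets")
    for (k in names(clade_datasets)) {
      if (loocv_exclude %in% clade_datasets[[k]]$records$genome_id) {
        ds <- subset_genomes(clade_datasets[[k]], loocv_exclude,
                             keep = FALSE)
        clade_logos[[k]] <- if (n_tdnas(ds) == 0) {
          empty_logo(genome$sprinzl, use_pairs)
        } else {
          function_logo(ds, use_pairs = use_pairs, correction = correction,
                        mc_reps = mc_reps, seed = seed)
        }
        if (!is.null(height_filter))
          clade_logos[[k]] <- filter_logo(clade_logos[[k]], height_filter)
      }
    }
  }
  M <- encode_matrix(genome)
  PC <- pair_code_matrix(M, genome$sprinzl)
  ci <- class_index(genome)
  vapply(clade_logos,
         function(lg) mean(per_tdna_heights(M, PC, ci, lg)), 0)
}

## ---- the MLP ---------------------------------------------------------------

#' Train the multiway score-vector perceptron
#'
#' Fits a single-hidden-layer perceptron (logistic hidden units, softmax
#' outputs, `nnet` backend) on labeled per-clade score vectors, with
#' standardized inputs and a stratified ten-fold cross-validation accuracy
#' report. Training is deterministic given `seed`.
#'
#' @param x Numeric matrix of score vectors (genomes x clades); column
#'   names fix the clade order.
#' @param labels Character vector of true clades, one per row of `x`.
#' @param hidden_units Hidden layer size; default
#'   `ceiling((inputs + classes) / 2)`.
#' @param epochs Maximum optimizer iterations (default 500).
#' @param seed Seed controlling weight initialization and fold models.
#' @param folds Cross-validation folds (default 10, stratified by clade).
#' @param decay Weight decay (default `1e-4`, a small stabilizer).
#' @param allow_empty Permit clades (named by `colnames(x)`) with no
#'   training vectors — used when a functional-class deletion empties a
#'   clade; default `FALSE` (error).
#' @return An object of class `"cif_mlp"`: the fitted net, input
#'   standardization, clade order, hyperparameters, training data and a
#'   `cv` component with per-genome fold predictions and accuracy.
#' @export
train_mlp <- function(x, labels, hidden_units = NULL, epochs = 500,
                      seed = 1, folds = 10, decay = 1e-4,
                      allow_empty = FALSE) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  clades <- if (!is.null(colnames(x)) && all(labels %in% colnames(x)))
    colnames(x) else sort(unique(labels))
  if (length(clades) < 2 ||
      (length(unique(labels)) < 2 && !allow_empty))
    stop("at least 2 clades are required")
  absent <- clades[!clades %in% labels]
  if (length(absent) && !allow_empty)
    stop("clade with zero vectors: ", paste(absent, collapse = ", "))
  if (is.null(hidden_units))
    hidden_units <- ceiling((ncol(x) + length(clades)) / 2)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  Y <- outer(labels, clades, "==") * 1
  colnames(Y) <- clades

  fit_net <- function(xtr, ytr, s) {
    with_seed(s, nnet::nnet(xtr, ytr, size = hidden_units,
                            softmax = TRUE, maxit = epochs,
                            decay = decay, trace = FALSE,
                            MaxNWts = 100000))
  }
  net <- fit_net(xs, Y, seed)

  ## stratified fold assignment: within each clade, round-robin in row order
  fold_id <- integer(nrow(x))
  for (cl in clades) {
    idx <- which(labels == cl)
    fold_id[idx] <- ((seq_along(idx) - 1L) %% folds) + 1L
  }
  cv_pred <- rep(NA_character_, nrow(x))
  cv_prob <- matrix(NA_real_, nrow(x), length(clades),
                    dimnames = list(rownames(x), clades))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    if (!any(tr)) next
    net_f <- fit_net(xs[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     (seed + 101 * f) %% 2147483647)
    p <- predict(net_f, xs[!tr, , drop = FALSE])
    p <- .as_prob_matrix(p, clades)
    cv_prob[!tr, ] <- p
    cv_pred[!tr] <- clades[max.col(p, ties.method = "first")]
  }
  structure(list(clades = clades, center = ctr, scale = scl, net = net,
                 hyper = list(hidden_units = hidden_units, epochs = epochs,
                              decay = decay, folds = folds, seed = seed),
                 x = x, labels = labels,
                 cv = list(fold = fold_id, predicted = cv_pred,
                           probabilities = cv_prob,
                           accuracy = mean(cv_pred == labels))),
            class = "cif_mlp")
}

.as_prob_matrix <- function(p, clades) {
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  p <- p[, clades, drop = FALSE]
  p <- pmax(p, 0)
  sw <- rowSums(p)
  sw[sw == 0] <- 1
  p / sw
}

#' @export
print.cif_mlp <- function(x, ...) {
  cat("CIF multiway perceptron: ", ncol(x$x), " inputs -> ",
      x$hyper$hidden_units, " hidden -> ", length(x$clades),
      " clades\n  ", x$hyper$folds, "-fold CV accuracy: ",
      sprintf("%.3f", x$cv$accuracy), " on ", nrow(x$x), " genomes\n",
      sep = "")
  invisible(x)
}

#' @export
predict.cif_mlp <- function(object, newdata, ...) {
  newdata <- if (is.null(dim(newdata)))
    matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  else as.matrix(newdata)
  if (ncol(newdata) != length(object$clades))
    stop("score vector arity (", ncol(newdata),
         ") does not match model clades (", length(object$clades), ")")
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$clades, drop = FALSE]
  xs <- scale(newdata, object$center, object$scale)
  .as_prob_matrix(predict(object$net, xs), object$clades)
}

#' Classify one score vector
#'
#' @param model A [train_mlp()] fit.
#' @param vector Named numeric score vector (clade order must match).
#' @return List with `probabilities` (named, summing to 1) and `predicted`
#'   (argmax clade; ties broken by clade order).
#' @export
classify <- function(model, vector) {
  p <- predict(model, vector)[1, ]
  list(probabilities = p,
       predicted = model$clades[which.max(p)])
}

## ---- high-level multiway fit ----------------------------------------------

#' Fit the multiway CIF phyloclassifier
#'
#' End-to-end fit: per-clade function logos, leave-one-out score vectors
#' for every training genome (each genome's own clade logo is rebuilt
#' without its tDNAs), and the score-vector perceptron with its ten-fold
#' cross-validation report.
#'
#' @param clade_datasets Named list (>= 2) of per-clade training
#'   [tdna_dataset()]s with disjoint genome sets.
#' @param use_pairs,correction,mc_reps,seed Logo options.
#' @param height_filter Optional bits threshold: logos are truncated with
#'   [filter_logo()] before vectors are computed and the perceptron is
#'   retrained on the filtered vectors.
#' @param hidden_units,epochs Perceptron hyperparameters, see
#'   [train_mlp()].
#' @param loocv Compute training vectors under leave-one-out (default).
#' @return An object of class `"cif_multiway"` with components `logos`,
#'   `loocv_logos`, `vectors`, `labels`, `mlp` and the fit options; use
#'   [predict.cif_multiway()] to classify new genomes with optional
#'   site-bootstrap support.
#' @export
multiway_fit <- function(clade_datasets, use_pairs = TRUE,
                         correction = "mc", mc_reps = 1000, seed = 1,
                         height_filter = NULL, hidden_units = NULL,
                         epochs = 500, loocv = TRUE) {
  if (length(clade_datasets) < 2) stop("at least 2 clades are required")
  if (is.null(names(clade_datasets)) || any(!nzchar(names(clade_datasets))))
    stop("clade_datasets must be named")
  clades <- names(clade_datasets)
  sprinzl <- clade_datasets[[1]]$sprinzl

  counts <- lapply(clade_datasets, function(ds) {
    if (n_tdnas(ds) == 0) NULL else count_features(ds, use_pairs)
  })
  logos <- lapply(seq_along(clades), function(j) {
    if (is.null(counts[[j]])) empty_logo(sprinzl, use_pairs)
    else logo_or_empty(counts[[j]], sprinzl, use_pairs, correction,
                       mc_reps, seed)
  })
  names(logos) <- clades

  ## LOOCV replacement logo for each training genome's own clade
  loocv_logos <- list()
  labels <- character(0)
  if (loocv) {
    for (j in seq_along(clades)) {
      if (is.null(counts[[j]])) next
      for (g in unique(clade_datasets[[j]]$records$genome_id)) {
        part <- count_features(subset_genomes(clade_datasets[[j]], g),
                               use_pairs)
        loocv_logos[[g]] <- logo_or_empty(
          subtract_counts(counts[[j]], part), sprinzl, use_pairs,
          correction, mc_reps, seed)
      }
    }
  }

  use_logos <- logos
  use_loocv <- loocv_logos
  if (!is.null(height_filter)) {
    use_logos <- lapply(use_logos, filter_logo, min_height = height_filter)
    use_loocv <- lapply(use_loocv, filter_logo, min_height = height_filter)
  }

  vecs <- list()
  for (j in seq_along(clades)) {
    for (g in unique(clade_datasets[[j]]$records$genome_id)) {
      lg <- use_logos
      if (loocv) lg[[clades[j]]] <- use_loocv[[g]]
      genome <- subset_genomes(clade_datasets[[j]], g)
      vecs[[g]] <- clade_score_vector(genome, lg)
      labels[g] <- clades[j]
    }
  }
  X <- do.call(rbind, vecs)
  colnames(X) <- clades

  mlp <- train_mlp(X, labels[rownames(X)], hidden_units = hidden_units,
                   epochs = epochs, seed = seed,
                   allow_empty = any(vapply(counts, is.null, TRUE)))
  structure(list(clades = clades, logos = logos, loocv_logos = loocv_logos,
                 vectors = X, labels = labels, mlp = mlp,
                 clade_datasets = clade_datasets,
                 options = list(use_pairs = use_pairs,
                                correction = correction,
                                mc_reps = mc_reps, seed = seed,
                                height_filter = height_filter,
                                epochs = epochs, loocv = loocv)),
            class = "cif_multiway")
}

#' @export
print.cif_multiway <- function(x, ...) {
  cat("Multiway CIF phyloclassifier over ", length(x$clades), " clades (",
      paste(x$clades, collapse = ", "), ")\n  ", nrow(x$vectors),
      " training genomes, LOOCV vectors: ", x$options$loocv,
      if (!is.null(x$options$height_filter))
        paste0(", height filter ", x$options$height_filter, " bits"),
      "\n", sep = "")
  print(x$mlp)
  invisible(x)
}

#' Re-fit a multiway classifier with a CIF height filter
#'
#' Truncates the stored logos (full and leave-one-out) at `height_filter`
#' bits, recomputes all training score vectors and retrains the
#' perceptron; the expensive logo estimation is reused.
#'
#' @param fit A [multiway_fit()] object.
#' @param height_filter Bits threshold.
#' @return A new `"cif_multiway"` fit.
#' @export
apply_height_filter <- function(fit, height_filter) {
  use_logos <- lapply(fit$logos, filter_logo, min_height = height_filter)
  use_loocv <- lapply(fit$loocv_logos, filter_logo,
                      min_height = height_filter)
  vecs <- list()
  for (j in seq_along(fit$clades)) {
    cl <- fit$clades[j]
    for (g in unique(fit$clade_datasets[[j]]$records$genome_id)) {
      lg <- use_logos
      if (fit$options$loocv) lg[[cl]] <- use_loocv[[g]]
      vecs[[g]] <- clade_score_vector(
        subset_genomes(fit$clade_datasets[[j]], g), lg)
    }
  }
  X <- do.call(rbind, vecs)
  colnames(X) <- fit$clades
  mlp <- train_mlp(X, fit$labels[rownames(X)],
                   hidden_units = fit$mlp$hyper$hidden_units,
                   epochs = fit$options$epochs, seed = fit$options$seed,
                   allow_empty = TRUE)
  out <- fit
  out$vectors <- X
  out$mlp <- mlp
  out$options$height_filter <- height_filter
  out
}

#' Site-bootstrap classification support for one genome
#'
#' Resamples alignment columns (Sprinzl labels) with replacement; in each
#' replicate every feature is counted with its column's sampled
#' multiplicity (paired features ride their 5' member column), the
#' replicate score vector is classified, and support for a clade is the
#' percentage of replicates predicting it. With `height_filter` set, logos
#' are truncated and the perceptron retrained before bootstrapping.
#'
#' @param genome A non-empty [tdna_dataset()] restricted to one genome.
#' @param fit A [multiway_fit()] object (logos + model + training data).
#' @param replicates Bootstrap replicates (>= 1; the paper-style default
#'   is 100).
#' @param seed Seed for column resampling.
#' @param height_filter Optional bits threshold (see [apply_height_filter()]).
#' @param loocv If the genome is part of the training data, score it
#'   against its clade's leave-one-out logo (default `TRUE`).
#' @return An object of class `"cif_classification"`: point probabilities,
#'   predicted clade, per-clade bootstrap support (percent) and the
#'   replicate count.
#' @export
bootstrap_support <- function(genome, fit, replicates = 100, seed = 1,
                              height_filter = NULL, loocv = TRUE) {
  stopifnot(inherits(fit, "cif_multiway"))
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(height_filter)) fit <- apply_height_filter(fit, height_filter)
  gid <- genome$records$genome_id[1]
  logos <- fit$logos
  if (!is.null(fit$options$height_filter) && is.null(height_filter)) {
    ## fit was already built with a filter; logos are stored unfiltered
    logos <- lapply(logos, filter_logo,
                    min_height = fit$options$height_filter)
  }
  if (loocv && gid %in% names(fit$loocv_logos)) {
    own <- fit$labels[gid]
    lo <- fit$loocv_logos[[gid]]
    if (!is.null(fit$options$height_filter))
      lo <- filter_logo(lo, fit$options$height_filter)
    logos[[own]] <- lo
  }
  M <- encode_matrix(genome)
  PC <- pair_code_matrix(M, genome$sprinzl)
  ci <- class_index(genome)
  L <- length(genome$sprinzl$labels)
  A <- vapply(logos, function(lg) column_contrib(M, PC, ci, lg),
              numeric(L))                          # L x K
  point <- classify(fit$mlp, colSums(A))
  W <- with_seed(seed, {
    vapply(seq_len(replicates),
           function(r) tabulate(sample.int(L, L, replace = TRUE), L),
           integer(L))
  })                                               # L x replicates
  S <- crossprod(W, A)                             # replicates x K
  colnames(S) <- fit$clades
  P <- predict(fit$mlp, S)
  pred <- fit$clades[max.col(P, ties.method = "first")]
  support <- 100 * vapply(fit$clades,
                          function(cl) mean(pred == cl), 0)
  structure(list(genome_id = gid,
                 probabilities = point$probabilities,
                 predicted = point$predicted,
                 bootstrap_support = support,
                 replicates = replicates),
            class = "cif_classification")
}

#' @export
print.cif_classification <- function(x, ...) {
  cat("Genome ", x$genome_id, ": predicted ", x$predicted,
      " (p = ", sprintf("%.3f", x$probabilities[x$predicted]), ")\n",
      sep = "")
  if (!is.null(x$bootstrap_support)) {
    cat("  bootstrap support (%, ", x$replicates, " replicates):\n",
        sep = "")
    print(round(x$bootstrap_support, 1))
  }
  invisible(x)
}

#' Classify genomes with a fitted multiway classifier
#'
#' @param object A [multiway_fit()] object.
#' @param newdata A [tdna_dataset()] of query genomes.
#' @param replicates Bootstrap replicates per genome (0 = no bootstrap).
#' @param seed Seed for bootstrap resampling.
#' @param loocv Leave-one-out scoring for genomes that are part of the
#'   training data (default `TRUE`).
#' @param ... Unused.
#' @return data.frame: one row per genome with `predicted`, per-clade
#'   probabilities (`prob.<clade>`) and, when bootstrapping, per-clade
#'   support percentages (`support.<clade>`).
#' @export
predict.cif_multiway <- function(object, newdata, replicates = 0,
                                 seed = 1, loocv = TRUE, ...) {
  genomes <- unique(newdata$records$genome_id)
  use_logos <- object$logos
  if (!is.null(object$options$height_filter))
    use_logos <- lapply(use_logos, filter_logo,
                        min_height = object$options$height_filter)
  rows <- lapply(seq_along(genomes), function(ii) {
    g <- genomes[ii]
    genome <- subset_genomes(newdata, g)
    if (replicates > 0) {
      bs <- bootstrap_support(genome, object, replicates = replicates,
                              seed = (seed + 977 * ii) %% 2147483647,
                              loocv = loocv)
      v <- c(list(genome_id = g, predicted = bs$predicted),
             as.list(stats::setNames(bs$probabilities,
                                     paste0("prob.", object$clades))),
             as.list(stats::setNames(bs$bootstrap_support,
                                     paste0("support.", object$clades))))
    } else {
      lg <- use_logos
      if (loocv && g %in% names(object$loocv_logos)) {
        lo <- object$loocv_logos[[g]]
        if (!is.null(object$options$height_filter))
          lo <- filter_logo(lo, object$options$height_filter)
        lg[[object$labels[g]]] <- lo
      }
      cls <- classify(object$mlp, clade_score_vector(genome, lg))
      v <- c(list(genome_id = g, predicted = cls$predicted),
             as.list(stats::setNames(cls$probabilities,
                                     paste0("prob.", object$clades))))
    }
    as.data.frame(v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Functional-class deletion robustness analysis
#'
#' For each functional class, removes all tDNAs of that class from every
#' clade's training data, refits the multiway classifier (logos and
#' perceptron) and reclassifies every query genome.
#'
#' @param training Named list of per-clade training [tdna_dataset()]s.
#' @param queries A [tdna_dataset()] of genomes to classify.
#' @param classes_to_delete Character vector of class symbols (default all
#'   22).
#' @param ... Options passed to [multiway_fit()] (`loocv = FALSE` by
#'   default here: deletion robustness is about the training signal, and
#'   queries are typically external).
#' @return List with `baseline` (predictions of the undeleted model),
#'   `table` (genomes x deleted classes matrix of predicted clades) and
#'   `changed` (per-class count of changed classifications).
#' @export
class_deletion_analysis <- function(training, queries,
                                    classes_to_delete = class_alphabet(),
                                    ...) {
  stopifnot(all(classes_to_delete %in% CLASS_ALPHABET))
  opts <- list(...)
  if (is.null(opts$loocv)) opts$loocv <- FALSE
  base_fit <- do.call(multiway_fit, c(list(training), opts))
  base_pred <- predict(base_fit, queries)
  genomes <- base_pred$genome_id
  tab <- matrix(NA_character_, length(genomes), length(classes_to_delete),
                dimnames = list(genomes, classes_to_delete))
  for (cl in classes_to_delete) {
    tr <- lapply(training, function(ds) {
      out <- ds
      out$records <- ds$records[ds$records$cls != cl, , drop = FALSE]
      rownames(out$records) <- NULL
      out
    })
    empty <- names(tr)[vapply(tr, n_tdnas, 0L) == 0]
    if (length(empty))
      warning("deleting class ", cl, " empties clade(s): ",
              paste(empty, collapse = ", "), " (retained with empty logo)")
    fit <- do.call(multiway_fit, c(list(tr), opts))
    pred <- predict(fit, queries)
    tab[pred$genome_id, cl] <- pred$predicted
  }
  changed <- colSums(tab != base_pred$predicted[match(rownames(tab),
                                                      base_pred$genome_id)])
  list(baseline = base_pred, table = tab, changed = changed)
}
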