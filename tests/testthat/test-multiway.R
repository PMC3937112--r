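test_that("clade score vectors are per-logo height sums", {
  sp <- toy_map(c("1", "2"))
  kF <- match("F", class_alphabet())
  lX <- blank_logo(sp); lX$single_heights[1, 1, kF] <- 1.0
  lY <- blank_logo(sp); lY$single_heights[2, 2, kF] <- 0.5
  g <- make_ds("AC", "F", "q1", sprinzl = sp)
  v <- clade_score_vector(g, list(X = lX, Y = lY))
  expect_equal(v, c(X = 1.0, Y = 0.5))
  ## features missing every logo -> zero vector
  g2 <- make_ds("GG", "F", "q1", sprinzl = sp)
  expect_equal(clade_score_vector(g2, list(X = lX, Y = lY)),
               c(X = 0, Y = 0))
  expect_error(clade_score_vector(g, list(X = lX)), "2 clades")
})

sep_vectors <- function(n_per = 6, k = 3, gap = 1, seed = 5) {
  set.seed(seed)
  cl <- paste0("K", seq_len(k))
  X <- matrix(stats::runif(n_per * k * k, 0, 0.2), n_per * k, k)
  labels <- rep(cl, each = n_per)
  for (i in seq_len(nrow(X))) X[i, match(labels[i], cl)] <- gap + 0.5
  colnames(X) <- cl
  list(x = X, labels = labels)
}

test_that("the perceptron is deterministic and fits separable vectors", {
  sv <- sep_vectors()
  m1 <- train_mlp(sv$x, sv$labels, seed = 9)
  m2 <- train_mlp(sv$x, sv$labels, seed = 9)
  expect_identical(m1$net$wts, m2$net$wts)
  m3 <- train_mlp(sv$x, sv$labels, seed = 10)
  expect_false(identical(m1$net$wts, m3$net$wts))
  ## training accuracy 100% on linearly separable vectors
  p <- predict(m1, sv$x)
  expect_equal(m1$clades[max.col(p, ties.method = "first")], sv$labels)
  expect_equal(m1$cv$accuracy, 1)
  ## probabilities sum to one; deep-in-cloud vectors are confident
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
  cls <- classify(m1, c(K1 = 1.5, K2 = 0.05, K3 = 0.1))
  expect_equal(cls$predicted, "K1")
  expect_gt(cls$probabilities["K1"], 0.9)
  expect_error(predict(m1, matrix(0, 1, 2)), "arity")
  expect_error(train_mlp(sv$x[1:6, ], sv$labels[1:6]), "2 clades")
})

test_that("conflicting labels on identical vectors give the majority rate", {
  X <- matrix(1, 12, 2, dimnames = list(NULL, c("K1", "K2")))
  labels <- rep(c("K1", "K2"), c(8, 4))
  m <- train_mlp(X, labels, seed = 2)
  expect_lt(abs(m$cv$accuracy - 8 / 12), 1 / 12 + 1e-9)
})

test_that("cross-validation folds stratify and partition the vectors", {
  sv <- sep_vectors(n_per = 7)
  m <- train_mlp(sv$x, sv$labels, folds = 5, seed = 1)
  expect_equal(sort(unique(m$cv$fold)), 1:5)
  expect_length(m$cv$fold, nrow(sv$x))
  for (cl in unique(sv$labels)) {
    per_fold <- table(m$cv$fold[sv$labels == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

## a small two-clade fitted classifier on generated data
small_fit <- function() {
  cfg <- bench("cfg")
  s1 <- cfg$clades[["C1"]]; s1$n_genomes <- 6L
  s2 <- cfg$clades[["C2"]]; s2$n_genomes <- 6L
  cfg2 <- cfg
  cfg2$clades <- list(C1 = s1, C2 = s2)
  cfg2$seed <- 303
  gen <- generate_tdna(cfg2)
  parts <- partition_tdna(gen$dataset)
  list(gen = gen,
       fit = multiway_fit(parts, mc_reps = 300, seed = 4))
}

test_that("bootstrap support is a normalized percentage over replicates", {
  sf <- small_fit()
  g <- subset_genomes(sf$gen$dataset, "C1_g01")
  one <- bootstrap_support(g, sf$fit, replicates = 1, seed = 3)
  expect_equal(sort(unname(one$bootstrap_support)), c(0, 100))
  many <- bootstrap_support(g, sf$fit, replicates = 25, seed = 3)
  expect_equal(sum(many$bootstrap_support), 100)
  expect_equal(sum(many$probabilities), 1, tolerance = 1e-9)
  expect_error(bootstrap_support(g, sf$fit, replicates = 0), "replicates")
  ## well-separated genome: strong support for its own clade
  expect_equal(many$predicted, "C1")
  expect_gte(many$bootstrap_support[["C1"]], 80)
})

test_that("height filtering keeps planted signal and retrains cleanly", {
  sf <- small_fit()
  ff <- apply_height_filter(sf$fit, 0.5)
  expect_equal(ff$options$height_filter, 0.5)
  pred <- predict(ff, sf$gen$dataset)
  truth <- sf$gen$truth[pred$genome_id]
  expect_gte(mean(pred$predicted == truth), 0.9)
})

test_that("class deletion: absent classes are no-ops, planted classes hurt", {
  ## two clades whose planted CIFs all sit in class H (mutually distinct),
  ## plus one clade marked by other classes: deleting H collapses the
  ## H-marked clades onto each other
  sp <- default_sprinzl()
  tmpl <- tRNAcif:::with_seed(5, tRNAcif:::.random_template(sp, 0.5))
  tchars <- strsplit(tmpl, "")[[1]]
  nt_state <- function(pos) vapply(pos, function(pp) {
    b <- match(tchars[match(pp, sp$labels)], c("A", "C", "G", "T"))
    c("A", "C", "G", "T")[b %% 4 + 1]
  }, "")
  mk_spec <- function(name, pos, cls)
    clade_spec(name, n_genomes = 5, genes_per_class = 2, gc_bias = 0.5,
               planted_cifs = data.frame(pos = pos,
                                         state = nt_state(pos),
                                         cls = cls),
               cif_fidelity = 1)
  cfg <- generator_config(
    list(mk_spec("X1", c("8", "9", "14"), c("H", "H", "H")),
         mk_spec("X2", c("32", "33", "35"), c("H", "H", "H")),
         mk_spec("Y", c("54", "55", "56"), c("D", "E", "F"))),
    sprinzl = sp,
    class_templates = stats::setNames(rep(tmpl, 22), class_alphabet()),
    background_noise = 0.02, polymorphism = 0.1, seed = 8)
  gen <- generate_tdna(cfg)
  parts <- partition_tdna(gen$dataset)
  ## fresh queries from the same lineages
  qcfg <- cfg
  qcfg$clades <- lapply(cfg$clades, function(s) { s$n_genomes <- 3L; s })
  qcfg$seed <- 9
  qgen <- generate_tdna(qcfg)
  res <- class_deletion_analysis(parts, qgen$dataset,
                                 classes_to_delete = c("H", "M"),
                                 mc_reps = 200, seed = 6)
  truth <- qgen$truth[res$baseline$genome_id]
  expect_equal(res$baseline$predicted, unname(truth))
  ## class M is planted nowhere: predictions identical to baseline
  expect_equal(unname(res$changed["M"]), 0)
  expect_true(all(res$changed <= nrow(res$baseline)))
  ## deleting H removes all of X1/X2's signal: their queries degrade
  x_rows <- truth %in% c("X1", "X2")
  acc_H <- mean(res$table[x_rows, "H"] == truth[x_rows])
  expect_lt(acc_H, 1)
  expect_gte(unname(res$changed["H"]), 1)
})

test_that("deleting a class that empties a clade warns but proceeds", {
  sp <- toy_map(c("1", "2"))
  dX <- make_ds(c("AG", "AG"), c("F", "F"), c("x1", "x2"), sprinzl = sp)
  dY <- make_ds(c("CG", "CG", "CA", "CT"), c("F", "K", "K", "K"),
                c("y1", "y1", "y2", "y2"), sprinzl = sp)
  q <- make_ds("AG", "F", "q1", sprinzl = sp)
  expect_warning(
    res <- class_deletion_analysis(list(X = dX, Y = dY), q,
                                   classes_to_delete = "F",
                                   correction = "none", epochs = 100),
    "empties clade")
  expect_equal(dim(res$table), c(1L, 1L))
})
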