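## Small construction helpers shared across the suite.

toy_map <- function(labels = c("1", "2", "3"), pairs = NULL) {
  sprinzl_map(labels, pairs)
}

## build a one-genome-per-record dataset quickly
make_ds <- function(seqs, cls, genome = paste0("g", seq_along(seqs)),
                    sprinzl = toy_map(as.character(seq_len(nchar(seqs[1])))),
                    taxon_of = NULL) {
  tdna_dataset(sprinzl,
               data.frame(genome_id = genome,
                          gene_id = sprintf("t%d", seq_along(seqs)),
                          cls = cls, seq = seqs,
                          stringsAsFactors = FALSE),
               taxon_of = taxon_of)
}

## a hand-settable all-zero logo (internal constructor)
blank_logo <- function(sprinzl, use_pairs = TRUE) {
  tRNAcif:::empty_logo(sprinzl, use_pairs)
}

## random small dataset for round-trip / oracle properties
random_ds <- function(seed, max_n = 30, labels = as.character(1:5),
                      with_pair = TRUE) {
  set.seed(seed)
  n <- sample.int(max_n, 1)
  L <- length(labels)
  pairs <- if (with_pair && L >= 2 && runif(1) < 0.7)
    data.frame(p5 = labels[1], p3 = labels[L]) else NULL
  classes <- sample(class_alphabet(), sample(2:6, 1))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "-"), L, replace = TRUE,
                 prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = ""),
    "")
  genomes <- paste0("g", sample.int(max(1, n %/% 3), n, replace = TRUE))
  tdna_dataset(sprinzl_map(labels, pairs),
               data.frame(genome_id = genomes,
                          gene_id = paste0("t", seq_len(n)),
                          cls = sample(classes, n, replace = TRUE),
                          seq = seqs, stringsAsFactors = FALSE))
}

## Brute-force function-logo oracle: recomputes every probability by direct
## enumeration over records with plain loops; independent of the package's
## counting and height code paths (correction = none).
oracle_logo_heights <- function(dataset) {
  sp <- dataset$sprinzl
  L <- length(sp$labels)
  cls <- dataset$records$cls
  n <- length(cls)
  K <- length(class_alphabet())
  chars <- do.call(rbind, strsplit(dataset$records$seq, ""))
  bg <- vapply(class_alphabet(), function(cc) sum(cls == cc) / n, 0)
  Hf <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  one <- function(carrier_rows) {
    nf <- length(carrier_rows)
    post <- vapply(class_alphabet(),
                   function(cc) sum(cls[carrier_rows] == cc) / nf, 0)
    info <- max(0, Hf(bg) - Hf(post))
    odds <- rep(0, K)
    for (k in seq_len(K)) if (bg[k] > 0) odds[k] <- post[k] / bg[k]
    h <- rep(0, K)
    if (sum(odds) > 0) h <- info * odds / sum(odds)
    list(info = info, heights = h)
  }
  single <- array(0, c(L, 4, K))
  sinfo <- matrix(0, L, 4)
  for (l in seq_len(L)) {
    for (b in 1:4) {
      rows <- which(chars[, l] == c("A", "C", "G", "T")[b])
      if (!length(rows)) next
      r <- one(rows)
      sinfo[l, b] <- r$info
      single[l, b, ] <- r$heights
    }
  }
  pair <- pinfo <- NULL
  if (nrow(sp$pairs)) {
    P <- nrow(sp$pairs)
    pair <- array(0, c(P, 16, K))
    pinfo <- matrix(0, P, 16)
    for (p in seq_len(P)) {
      i5 <- match(sp$pairs$p5[p], sp$labels)
      i3 <- match(sp$pairs$p3[p], sp$labels)
      for (b1 in 1:4) for (b2 in 1:4) {
        rows <- which(chars[, i5] == c("A", "C", "G", "T")[b1] &
                        chars[, i3] == c("A", "C", "G", "T")[b2])
        if (!length(rows)) next
        r <- one(rows)
        b <- (b1 - 1) * 4 + b2
        pinfo[p, b] <- r$info
        pair[p, b, ] <- r$heights
      }
    }
  }
  list(single = single, single_info = sinfo, pair = pair,
       pair_info = pinfo)
}
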