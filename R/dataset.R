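#' Construct a tDNA dataset
#'
#' Bundles structurally aligned tRNA gene (tDNA) records with their shared
#' Sprinzl coordinate map and an optional genome-to-clade assignment.
#' Sequences are stored as upper-case DNA over `A,C,G,T,-`; `U` is
#' normalized to `T` and `.` to `-` on construction. IUPAC ambiguity codes
#' are retained but contribute no features downstream.
#'
#' @param sprinzl A [sprinzl_map()].
#' @param records data.frame with columns `genome_id`, `gene_id`, `cls`
#'   (one of [class_alphabet()]) and `seq` (aligned sequence, length equal
#'   to the number of Sprinzl labels).
#' @param taxon_of Optional named character vector mapping genome IDs to
#'   clade labels. Genome IDs absent from `records` trigger a warning.
#' @return An object of class `"tdna_dataset"`.
#' @export
tdna_dataset <- function(sprinzl, records, taxon_of = NULL) {
  stopifnot(inherits(sprinzl, "sprinzl_map"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("genome_id", "gene_id", "cls", "seq")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  records <- records[need]
  for (cc in need) records[[cc]] <- as.character(records[[cc]])
  records$seq <- normalize_seq(records$seq)
  L <- length(sprinzl$labels)
  bad_len <- which(nchar(records$seq) != L)
  if (length(bad_len))
    stop("sequence length mismatch (expected ", L, " columns) in record(s) ",
         paste(utils::head(bad_len, 5), collapse = ", "))
  bad_cls <- which(!(records$cls %in% CLASS_ALPHABET))
  if (length(bad_cls))
    stop("illegal class symbol ", dQuote(records$cls[bad_cls[1]]),
         " in record ", bad_cls[1])
  key <- paste(records$genome_id, records$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (genome_id, gene_id): ",
         sub("\r", "/", key[duplicated(key)][1]))
  if (!is.null(taxon_of)) {
    taxon_of <- stats::setNames(as.character(taxon_of), names(taxon_of))
    missing_g <- setdiff(names(taxon_of), records$genome_id)
    if (length(missing_g))
      warning("taxon map references genome(s) absent from records: ",
              paste(missing_g, collapse = ", "))
  }
  structure(list(sprinzl = sprinzl, records = records, taxon_of = taxon_of),
            class = "tdna_dataset")
}

## upper-case, U->T, .->-
normalize_seq <- function(s) {
  s <- toupper(s)
  s <- chartr("U.", "T-", s)
  s
}

#' @export
print.tdna_dataset <- function(x, ...) {
  cat("tDNA dataset: ", nrow(x$records), " genes from ",
      length(unique(x$records$genome_id)), " genomes over ",
      length(x$sprinzl$labels), " Sprinzl columns\n", sep = "")
  tab <- sort(table(x$records$cls), decreasing = TRUE)
  cat("  classes: ", paste(names(tab), tab, sep = ":", collapse = " "),
      "\n", sep = "")
  if (!is.null(x$taxon_of))
    cat("  taxa: ", paste(sort(unique(x$taxon_of)), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of tDNA records
#' @param dataset A [tdna_dataset()].
#' @return Integer count of gene records.
#' @export
n_tdnas <- function(dataset) nrow(dataset$records)

#' Restrict a dataset to a subset of genomes
#'
#' @param dataset A [tdna_dataset()].
#' @param genomes Character vector of genome IDs to keep (`keep = TRUE`)
#'   or drop (`keep = FALSE`).
#' @param keep Keep (default) or exclude the named genomes.
#' @return A [tdna_dataset()] with the same Sprinzl map.
#' @export
subset_genomes <- function(dataset, genomes, keep = TRUE) {
  sel <- dataset$records$genome_id %in% genomes
  if (!keep) sel <- !sel
  out <- dataset
  out$records <- dataset$records[sel, , drop = FALSE]
  rownames(out$records) <- NULL
  if (!is.null(out$taxon_of))
    out$taxon_of <- out$taxon_of[names(out$taxon_of) %in%
                                   out$records$genome_id]
  out
}

#' Partition a dataset by clade
#'
#' Splits a dataset into per-clade datasets according to a genome-to-clade
#' map. The parts plus the unassigned genomes are an exact set partition of
#' the input records.
#'
#' @param dataset A [tdna_dataset()].
#' @param taxa Named character vector: names are genome IDs, values clade
#'   labels. Defaults to `dataset$taxon_of`.
#' @return Named list of [tdna_dataset()] objects, one per clade (sorted by
#'   label), with attribute `"unassigned"` holding genome IDs not covered
#'   by `taxa`.
#' @export
partition_tdna <- function(dataset, taxa = dataset$taxon_of) {
  if (is.null(taxa)) taxa <- stats::setNames(character(0), character(0))
  if (any(!nzchar(taxa))) stop("clade labels must be nonempty")
  clades <- sort(unique(unname(taxa)))
  parts <- lapply(clades, function(cl) {
    ds <- subset_genomes(dataset, names(taxa)[taxa == cl])
    ds$taxon_of <- NULL
    ds
  })
  names(parts) <- clades
  unassigned <- setdiff(unique(dataset$records$genome_id), names(taxa))
  attr(parts, "unassigned") <- unassigned
  parts
}

## integer code matrix: n_records x n_columns; 0 = gap or ambiguity,
## 1..4 = A,C,G,T.  The workhorse representation for all counting/scoring.
encode_matrix <- function(dataset) {
  L <- length(dataset$sprinzl$labels)
  n <- nrow(dataset$records)
  if (n == 0) return(matrix(integer(0), 0, L))
  chars <- matrix(unlist(strsplit(dataset$records$seq, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = n, ncol = L, byrow = TRUE)
  m <- match(chars, NUC, nomatch = 0L)
  dim(m) <- c(n, L)
  m
}

## class index vector (1..22) for records
class_index <- function(dataset) match(dataset$records$cls, CLASS_ALPHABET)
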