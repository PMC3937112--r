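#' Read a tab-delimited tDNA table
#'
#' The tDNA table is the package's native exchange format: line 1 is
#' `#SPRINZL<TAB>label1<TAB>label2...`, an optional second header line
#' `#PAIRS<TAB>5'label:3'label...` overrides the canonical pair list, and
#' each data line is `genome_id<TAB>gene_id<TAB>class<TAB>aligned sequence`.
#'
#' @param path Path to the file.
#' @param strict If `TRUE` (default) malformed rows abort with the row
#'   number; otherwise they are skipped with a warning.
#' @return A [tdna_dataset()]; records preserve file order.
#' @export
read_tdna_table <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "#SPRINZL\t"))
    stop("malformed header: first line must start with '#SPRINZL\\t'")
  labels <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  if (!length(labels)) stop("malformed header: no Sprinzl labels")
  body <- lines[-1]
  pairs <- NULL
  if (length(body) && startsWith(body[1], "#PAIRS")) {
    toks <- strsplit(body[1], "\t", fixed = TRUE)[[1]][-1]
    if (length(toks)) {
      pp <- do.call(rbind, strsplit(toks, ":", fixed = TRUE))
      pairs <- data.frame(p5 = pp[, 1], p3 = pp[, 2],
                          stringsAsFactors = FALSE)
    } else {
      pairs <- data.frame(p5 = character(0), p3 = character(0))
    }
    body <- body[-1]
  } else {
    pairs <- .default_pairs_for(labels)
  }
  sp <- sprinzl_map(labels, pairs)
  body_rows <- which(nzchar(body) & !startsWith(body, "#"))
  recs <- vector("list", length(body_rows))
  bad <- logical(length(body_rows))
  for (i in seq_along(body_rows)) {
    rowno <- body_rows[i] + if (length(lines) - length(body) == 2) 2L else 1L
    f <- strsplit(body[body_rows[i]], "\t", fixed = TRUE)[[1]]
    msg <- .validate_row(f, length(labels))
    if (!is.null(msg)) {
      if (strict) stop("row ", rowno, ": ", msg)
      warning("skipping row ", rowno, ": ", msg)
      bad[i] <- TRUE
      next
    }
    recs[[i]] <- f[1:4]
  }
  recs <- recs[!bad]
  records <- if (length(recs)) {
    m <- do.call(rbind, recs)
    data.frame(genome_id = m[, 1], gene_id = m[, 2], cls = m[, 3],
               seq = m[, 4], stringsAsFactors = FALSE)
  } else {
    data.frame(genome_id = character(0), gene_id = character(0),
               cls = character(0), seq = character(0))
  }
  tdna_dataset(sp, records)
}

## default canonical pairs restricted to the labels actually present
.default_pairs_for <- function(labels) {
  dp <- default_sprinzl()$pairs
  dp[dp$p5 %in% labels & dp$p3 %in% labels, , drop = FALSE]
}

.validate_row <- function(fields, L) {
  if (length(fields) != 4)
    return(paste0("expected 4 tab-delimited fields, found ", length(fields)))
  s <- normalize_seq(fields[4])
  if (nchar(s) != L)
    return(paste0("sequence has ", nchar(s), " characters under a ", L,
                  "-label header"))
  if (!(toupper(fields[3]) %in% CLASS_ALPHABET))
    return(paste0("illegal class symbol ", dQuote(fields[3])))
  if (grepl("[^ACGTNRYSWKMBDHV-]", s))
    return("illegal sequence character")
  NULL
}

#' Write a tDNA table
#'
#' Inverse of [read_tdna_table()]; `read_tdna_table(write_tdna_table(d))`
#' reproduces `d` bit-exactly (gap columns verbatim).
#'
#' @param dataset A [tdna_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tdna_table <- function(dataset, path) {
  sp <- dataset$sprinzl
  hdr <- paste(c("#SPRINZL", sp$labels), collapse = "\t")
  pl <- paste(c("#PAIRS", paste(sp$pairs$p5, sp$pairs$p3, sep = ":")),
              collapse = "\t")
  r <- dataset$records
  rows <- if (nrow(r)) {
    paste(r$genome_id, r$gene_id, r$cls, r$seq, sep = "\t")
  } else character(0)
  writeLines(c(hdr, pl, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a Stockholm 1.0 tDNA alignment
#'
#' Sequence names must encode `genome_id|gene_id|class`; Sprinzl labels are
#' taken from the per-column `#=GC <coord_line_tag>` annotation line, with
#' labels comma-separated (labels can exceed one character).
#'
#' @param path Path to a Stockholm 1.0 file.
#' @param coord_line_tag Tag of the coordinate annotation line (default
#'   `"SPRINZL"`).
#' @param strict Passed through to record validation as in
#'   [read_tdna_table()].
#' @return A [tdna_dataset()] identical in contract to [read_tdna_table()].
#' @export
read_stockholm <- function(path, coord_line_tag = "SPRINZL", strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM 1\\.0", lines[1]))
    stop("not a Stockholm 1.0 file")
  gc_tag <- paste0("#=GC ", coord_line_tag)
  seqs <- list()
  order_seen <- character(0)
  coords <- character(0)
  for (ln in lines[-1]) {
    if (ln == "//" || !nzchar(trimws(ln))) next
    if (startsWith(ln, gc_tag)) {
      coords <- c(coords, trimws(substring(ln, nchar(gc_tag) + 1)))
    } else if (startsWith(ln, "#")) {
      next
    } else {
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(f) != 2) stop("malformed sequence line: ", ln)
      if (is.null(seqs[[f[1]]])) order_seen <- c(order_seen, f[1])
      seqs[[f[1]]] <- paste0(seqs[[f[1]]] %||% "", f[2])
    }
  }
  if (!length(coords))
    stop("missing coordinate annotation line '", gc_tag, "'")
  labels <- strsplit(paste(coords, collapse = ","), ",", fixed = TRUE)[[1]]
  labels <- trimws(labels)
  labels <- labels[nzchar(labels)]
  sp <- sprinzl_map(labels, .default_pairs_for(labels))
  ids <- strsplit(order_seen, "|", fixed = TRUE)
  bad <- vapply(ids, length, 0L) != 3
  if (any(bad))
    stop("sequence name not parseable into genome_id|gene_id|class: ",
         order_seen[which(bad)[1]])
  m <- do.call(rbind, ids)
  records <- data.frame(genome_id = m[, 1], gene_id = m[, 2], cls = m[, 3],
                        seq = unlist(seqs[order_seen], use.names = FALSE),
                        stringsAsFactors = FALSE)
  if (!strict) {
    L <- length(labels)
    ok <- !vapply(seq_len(nrow(records)), function(i) {
      msg <- .validate_row(unlist(records[i, ], use.names = FALSE), L)
      if (!is.null(msg)) warning("skipping ", records$gene_id[i], ": ", msg)
      !is.null(msg)
    }, logical(1))
    records <- records[ok, , drop = FALSE]
  }
  tdna_dataset(sp, records)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a Stockholm 1.0 tDNA alignment
#'
#' @param dataset A [tdna_dataset()].
#' @param path Output path.
#' @param coord_line_tag Tag for the coordinate annotation line.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(dataset, path, coord_line_tag = "SPRINZL") {
  r <- dataset$records
  nm <- paste(r$genome_id, r$gene_id, r$cls, sep = "|")
  w <- max(nchar(nm), nchar(paste0("#=GC ", coord_line_tag)), 0L) + 2L
  lines <- c("# STOCKHOLM 1.0",
             if (nrow(r)) sprintf("%-*s%s", w, nm, r$seq),
             sprintf("%-*s%s", w, paste0("#=GC ", coord_line_tag),
                     paste(dataset$sprinzl$labels, collapse = ",")),
             "//")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a genome-to-clade taxon map
#'
#' Two-column tab-delimited file: `genome_id<TAB>clade`.
#'
#' @param path Path to the file.
#' @return Named character vector mapping genome IDs to clade labels.
#' @export
read_taxon_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  m <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(m) < 2) stop("taxon map must have two tab-delimited columns")
  stats::setNames(m[, 2], m[, 1])
}

#' Write a genome-to-clade taxon map
#' @param taxa Named character vector (names = genome IDs, values = clades).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxon_map <- function(taxa, path) {
  writeLines(paste(names(taxa), taxa, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}
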