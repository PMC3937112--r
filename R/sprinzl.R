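#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

## 22-letter functional class alphabet: 20 amino-acid one-letter codes,
## "X" initiator, "J" for the CAU-anticodon isoleucine class.
CLASS_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "J", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")

NUC <- c("A", "C", "G", "T")

#' Functional class alphabet
#'
#' The 22 tRNA functional classes used throughout the package: the 20 IUPAC
#' amino-acid one-letter codes plus `"X"` (initiator tRNA) and `"J"`
#' (the CAU-anticodon isoleucine class).
#'
#' @return Character vector of 22 class symbols.
#' @export
class_alphabet <- function() CLASS_ALPHABET

#' Construct a Sprinzl coordinate map
#'
#' A Sprinzl map names every column of a structural tRNA alignment by its
#' Sprinzl coordinate label ("-1", "1" ... "76", insertion labels such as
#' "17a" or "e11") and records which label pairs form the canonical
#' secondary-structure base pairs (acceptor, D, anticodon and T stems).
#'
#' @param labels Character vector of unique coordinate labels, one per
#'   alignment column, in column order.
#' @param pairs Two-column character matrix or data.frame of label pairs
#'   (5' label, 3' label); every label must occur in `labels` and no label
#'   may appear in more than one pair. May be `NULL` for no pairs.
#' @return An object of class `"sprinzl_map"`.
#' @seealso [default_sprinzl()]
#' @export
sprinzl_map <- function(labels, pairs = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("Sprinzl labels must be unique")
  if (is.null(pairs)) {
    pairs <- data.frame(p5 = character(0), p3 = character(0),
                        stringsAsFactors = FALSE)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs) <- c("p5", "p3")
    pairs$p5 <- as.character(pairs$p5)
    pairs$p3 <- as.character(pairs$p3)
    all_members <- c(pairs$p5, pairs$p3)
    if (!all(all_members %in% labels))
      stop("pair labels absent from Sprinzl labels: ",
           paste(setdiff(all_members, labels), collapse = ", "))
    if (anyDuplicated(all_members))
      stop("a Sprinzl label may appear in at most one pair")
  }
  structure(list(labels = labels, pairs = pairs), class = "sprinzl_map")
}

#' Default Sprinzl coordinate map
#'
#' The standard tRNA structural numbering: positions -1 and 1-76 plus the
#' common insertion labels 17a, 20a, 20b and the variable-arm labels
#' e11-e17, e1-e5, e21-e27, with the canonical acceptor- (1:72 ... 7:66),
#' D- (10:25 ... 13:22), anticodon- (27:43 ... 31:39) and T-stem
#' (49:65 ... 53:61) pair list.
#'
#' @return A [sprinzl_map()] with 99 labels and 21 pairs.
#' @export
default_sprinzl <- function() {
  labels <- c("-1",
              as.character(1:17), "17a", as.character(18:20), "20a", "20b",
              as.character(21:45),
              paste0("e", 11:17), paste0("e", 1:5), paste0("e", 27:21),
              as.character(46:76))
  stems <- rbind(
    cbind(1:7, 72:66),        # acceptor stem
    cbind(10:13, 25:22),      # D stem
    cbind(27:31, 43:39),      # anticodon stem
    cbind(49:53, 65:61))      # T stem
  pairs <- data.frame(p5 = as.character(stems[, 1]),
                      p3 = as.character(stems[, 2]),
                      stringsAsFactors = FALSE)
  sprinzl_map(labels, pairs)
}

#' @export
print.sprinzl_map <- function(x, ...) {
  cat("Sprinzl coordinate map: ", length(x$labels), " columns (",
      x$labels[1], " ... ", x$labels[length(x$labels)], "), ",
      nrow(x$pairs), " canonical pairs\n", sep = "")
  invisible(x)
}

## column indices of pair members; integer matrix P x 2
.pair_index <- function(sprinzl) {
  if (nrow(sprinzl$pairs) == 0)
    return(matrix(integer(0), 0, 2))
  cbind(match(sprinzl$pairs$p5, sprinzl$labels),
        match(sprinzl$pairs$p3, sprinzl$labels))
}
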