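## Alignment container: internally a DNAbin matrix (ape's standard). Public
## functions accept a DNAbin, a named character vector of equal-length strings,
## a list of strings, or a character matrix of single bases.

as_alignment <- function(x, min_seqs = 2L) {
  if (inherits(x, "DNAbin")) {
    if (is.list(x)) x <- ape::as.matrix.DNAbin(x)
    aln <- x
  } else if (is.matrix(x) && is.character(x)) {
    aln <- ape::as.DNAbin(tolower(x))
  } else if (is.character(x) || is.list(x)) {
    x <- unlist(x)
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("sequences must carry unique names", call. = FALSE)
    }
    lens <- nchar(x)
    if (length(unique(lens)) != 1L) {
      stop("aligned sequences must have equal lengths", call. = FALSE)
    }
    m <- do.call(rbind, strsplit(tolower(x), "", fixed = TRUE))
    rownames(m) <- names(x)
    aln <- ape::as.DNAbin(m)
  } else {
    stop("cannot interpret input as an alignment", call. = FALSE)
  }
  if (nrow(aln) < min_seqs) {
    stop(sprintf("alignment must contain at least %d sequences", min_seqs),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(aln))) {
    stop("alignment labels must be unique", call. = FALSE)
  }
  aln
}

## alignment as an uppercase character matrix
alignment_chars <- function(x) {
  aln <- as_alignment(x, min_seqs = 1L)
  m <- toupper(as.character(aln))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L, dimnames = list(rownames(aln)))
  m
}

#' Read and write FASTA files
#'
#' Thin wrappers around [ape::read.FASTA()] / [ape::write.FASTA()] returning
#' (and accepting) named character vectors of uppercase sequences, the form
#' used throughout the package.
#'
#' @param path file path.
#' @param x named character vector (or list) of sequences.
#' @return `read_fasta`: a named character vector; `write_fasta`: `path`,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- vapply(as.character(dna), function(s) seq_string(toupper(s)), "")
  names(out) <- names(dna)
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  x <- unlist(x)
  m <- lapply(strsplit(tolower(x), "", fixed = TRUE), identity)
  names(m) <- names(x)
  ape::write.FASTA(ape::as.DNAbin(m), path)
  invisible(path)
}

#' Read a per-position variability map
#'
#' Reads a two-column TSV (`position`, `flag`) classifying alignment positions
#' as substitutionally `high`- or `low`-variability relative to the across-site
#' average.
#'
#' @param path TSV file path.
#' @return named character vector of `"high"`/`"low"` flags, names = positions.
#' @export
read_varmap <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("position", "flag") %in% names(tab))) {
    stop("variability map must have columns 'position' and 'flag'",
         call. = FALSE)
  }
  flags <- tolower(tab$flag)
  if (!all(flags %in% c("high", "low"))) {
    stop("variability flags must be 'high' or 'low'", call. = FALSE)
  }
  stats::setNames(flags, tab$position)
}

#' Read a dot-bracket secondary-structure annotation
#'
#' Parses a Vienna-style dot-bracket file (comment/`>` lines and sequence
#' lines are ignored; the structure line consists of `(`, `)` and `.`) into a
#' structure annotation: an integer vector with, for each position, the
#' 1-based index of its pairing partner, or `NA` for unpaired positions.
#'
#' @param path file path (for `read_structure`) or a dot-bracket string (for
#'   `parse_dotbracket`).
#' @return integer partner vector of class `"rna_structure"`; pairing is an
#'   involution (`partner[partner[i]] == i`).
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  hit <- grep("^[().]+$", trimws(lines), value = TRUE)
  if (length(hit) == 0L) {
    stop("no dot-bracket line found in ", path, call. = FALSE)
  }
  parse_dotbracket(hit[[length(hit)]])
}

#' @rdname read_structure
#' @export
parse_dotbracket <- function(path) {
  db <- strsplit(trimws(path), "", fixed = TRUE)[[1L]]
  if (!all(db %in% c("(", ")", "."))) {
    stop("dot-bracket string may contain only '(', ')' and '.'", call. = FALSE)
  }
  partner <- rep(NA_integer_, length(db))
  stack <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced brackets", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced brackets", call. = FALSE)
  structure(partner, class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA secondary structure: %d positions, %d base pairs\n",
              length(x), sum(!is.na(x)) / 2L))
  invisible(x)
}

## render a partner vector back to dot-bracket (nested structures only)
structure_to_dotbracket <- function(partner) {
  db <- rep(".", length(partner))
  paired <- which(!is.na(partner))
  db[paired[paired < partner[paired]]] <- "("
  db[paired[paired > partner[paired]]] <- ")"
  paste(db, collapse = "")
}
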