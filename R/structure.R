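RNA_CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

to_rna <- function(x) {
  x <- toupper(x)
  x[x == "T"] <- "U"
  x
}

#' Call substitutions between an aligned reference and query
#'
#' One record per alignment column where both sequences carry an unambiguous
#' base (A/C/G/T/U) and the bases differ. Columns containing gaps or
#' ambiguity codes in either sequence are skipped.
#'
#' @param reference,query aligned sequences of equal length (strings or
#'   character vectors).
#' @return data frame with columns `position` (1-based alignment column),
#'   `ref_base`, `obs_base` (RNA alphabet), `class` (`NA` until
#'   [classify_substitutions()]), `variability` (`"unscored"` until
#'   [score_variability()]).
#' @export
call_substitutions <- function(reference, query) {
  r <- seq_chars(reference)
  q <- seq_chars(query)
  if (length(r) != length(q)) {
    stop("reference and query must have equal aligned lengths", call. = FALSE)
  }
  ok <- r %in% c(DNA_BASES, "U") & q %in% c(DNA_BASES, "U")
  r <- to_rna(r)
  q <- to_rna(q)
  hit <- which(ok & r != q)
  data.frame(position = hit,
             ref_base = r[hit],
             obs_base = q[hit],
             class = rep(NA_character_, length(hit)),
             variability = rep("unscored", length(hit)),
             stringsAsFactors = FALSE)
}

#' Classify substitutions as structure-conservative or disruptive
#'
#' Maps each substitution onto the reference secondary structure. A
#' substitution at an unpaired (loop) position is conservative. At a paired
#' (stem) position it is conservative iff the query's bases at the position
#' and its pairing partner still form a canonical pair (Watson-Crick A-U or
#' G-C, or the G-U wobble); otherwise it breaks the helix - a putative
#' stem-loop transition - and is disruptive. Because the partner base is read
#' from the query itself, compensatory double substitutions that restore
#' pairing are scored conservative.
#'
#' @param records substitution records from [call_substitutions()].
#' @param structure an `"rna_structure"` partner vector (see
#'   [parse_dotbracket()]) covering every record position.
#' @param query the aligned query sequence the records were called from.
#' @return `records` with the `class` column filled
#'   (`"conservative"`/`"disruptive"`).
#' @export
classify_substitutions <- function(records, structure, query) {
  q <- to_rna(seq_chars(query))
  if (any(records$position > length(structure))) {
    stop("substitution position lacks structure annotation", call. = FALSE)
  }
  cls <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    pos <- records$position[i]
    partner <- structure[pos]
    if (is.na(partner)) {
      cls[i] <- "conservative"
    } else {
      pair <- paste0(q[pos], q[partner])
      cls[i] <- if (pair %in% RNA_CANONICAL_PAIRS) "conservative" else "disruptive"
    }
  }
  records$class <- cls
  records
}

#' Score substitutions against a positional variability map
#'
#' Counts how many substitutions fall at sites whose long-run substitution
#' rate is below ("low") versus above ("high") the across-site average, and
#' summarizes the structural classification. Elevated counts at
#' low-variability sites are a signature of relaxed functional constraint.
#'
#' @param records classified records from [classify_substitutions()] (an
#'   unclassified data frame is accepted; class counts are then `NA`).
#' @param varmap named `"high"`/`"low"` vector (names = positions), e.g. from
#'   [read_varmap()]; positions not covered are counted as unscored.
#' @return object of class `"classification_summary"`: counts of disruptive,
#'   conservative, low-/high-variability substitutions, totals and ratios.
#' @export
score_variability <- function(records, varmap = NULL) {
  n <- nrow(records)
  if (!is.null(varmap)) {
    flag <- unname(varmap[as.character(records$position)])
    flag[is.na(flag)] <- "unscored"
    records$variability <- flag
  }
  n_low <- sum(records$variability == "low")
  n_high <- sum(records$variability == "high")
  n_dis <- if (all(is.na(records$class))) NA_integer_ else
    sum(records$class == "disruptive", na.rm = TRUE)
  n_con <- if (is.na(n_dis)) NA_integer_ else n - n_dis
  structure(list(
    n_substitutions = n,
    disruptive = n_dis,
    conservative = n_con,
    disruptive_fraction = if (is.na(n_dis) || n == 0) NA_real_ else n_dis / n,
    low_variability = n_low,
    high_variability = n_high,
    unscored = n - n_low - n_high,
    records = records
  ), class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("Substitutions: %d\n", x$n_substitutions))
  if (!is.na(x$disruptive)) {
    cat(sprintf("  disruptive: %d (%.1f%%)   conservative: %d\n",
                x$disruptive, 100 * x$disruptive_fraction, x$conservative))
  }
  cat(sprintf("  at low-variability sites: %d   high: %d   unscored: %d\n",
              x$low_variability, x$high_variability, x$unscored))
  invisible(x)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in the table
#' `rbind(c(a, b), c(c, d))`: with margins fixed, the first cell is
#' hypergeometric, and the p-value sums the probabilities of all tables whose
#' probability does not exceed that of the observed table (the standard
#' two-sided convention, matching [stats::fisher.test()]).
#'
#' @param a,b,c,d non-negative integer cell counts (rows = groups, columns =
#'   outcome classes, e.g. disruptive/conservative).
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(85, 95, 9, 60)   # disruptive excess, p << 0.001
#' fisher_exact_2x2(3, 0, 0, 3)      # 0.1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("both row sums must be positive", call. = FALSE)
  }
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  ## tolerance guards against floating-point ties (tables with equal prob)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
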