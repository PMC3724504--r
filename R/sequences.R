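#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

## for each base, the three alternative bases (column = original base)
.alt_bases <- local({
  m <- vapply(DNA_BASES, function(b) setdiff(DNA_BASES, b), character(3))
  colnames(m) <- DNA_BASES
  m
})

## split a sequence into an uppercase character vector of single bases
seq_chars <- function(seq) {
  if (is.character(seq) && length(seq) == 1L) {
    seq <- strsplit(seq, "", fixed = TRUE)[[1L]]
  }
  toupper(seq)
}

seq_string <- function(chars) paste(chars, collapse = "")

check_dna <- function(chars, what = "sequence") {
  if (length(chars) == 0L) {
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  }
  bad <- !(chars %in% DNA_BASES)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(unique(chars[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(chars)
}

#' Random point mutation of a nucleotide sequence
#'
#' Draws a Poisson number of substitution events with mean `expected_subs`,
#' picks that many distinct sites uniformly at random, and replaces the base at
#' each chosen site by one of the three alternative bases (uniformly). No
#' indels are ever introduced, so the returned sequence has the same length as
#' the input. This models one cycle of the discrete-time replacement simulator.
#'
#' @param seq a nucleotide sequence over A/C/G/T, either a single string or a
#'   character vector of single bases.
#' @param expected_subs expected number of substitutions (Poisson mean),
#'   a finite non-negative number. Units: substitutions per sequence.
#' @param seed optional integer seed for reproducibility; if `NULL` the current
#'   RNG state is used.
#' @return the mutated sequence, in the same form (string or character vector)
#'   as the input.
#' @examples
#' mutate_sequence("ACGTACGT", 2, seed = 1)
#' @export
mutate_sequence <- function(seq, expected_subs, seed = NULL) {
  as_string <- is.character(seq) && length(seq) == 1L && nchar(seq) > 1L
  s <- seq_chars(seq)
  check_dna(s)
  if (!is.numeric(expected_subs) || length(expected_subs) != 1L ||
      !is.finite(expected_subs) || expected_subs < 0) {
    stop("'expected_subs' must be a single finite non-negative number",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1L, expected_subs)
  n <- min(n, length(s))
  if (n > 0L) {
    sites <- sample.int(length(s), n)
    picks <- sample.int(3L, n, replace = TRUE)
    s[sites] <- .alt_bases[cbind(picks, match(s[sites], DNA_BASES))]
  }
  if (as_string) seq_string(s) else s
}

## Bulk evolution over a span of cycles: total events ~ Poisson(rate * cycles),
## applied one at a time (sites uniform with replacement across the span, so a
## site may be hit repeatedly -- the multiple hits that distance corrections
## account for). Distributionally identical to per-cycle Poisson mutation.
evolve_chars <- function(chars, rate, cycles) {
  if (cycles <= 0 || rate <= 0) return(chars)
  total <- stats::rpois(1L, rate * cycles)
  if (total == 0L) return(chars)
  sites <- sample.int(length(chars), total, replace = TRUE)
  picks <- sample.int(3L, total, replace = TRUE)
  for (k in seq_len(total)) {
    i <- sites[k]
    chars[i] <- .alt_bases[picks[k], chars[i]]
  }
  chars
}

#' Draw descendant birth cycles from a Beta distribution
#'
#' Birth times of descendant lineages are modelled as `n_cycles` times a
#' Beta(`alpha`, `beta`) variate, rounded to the nearest cycle and clamped to
#' `[1, n_cycles - 1]` so that every descendant has a non-empty independent
#' history. With `alpha = beta = 2` (the default used throughout) births
#' concentrate around the midpoint of the run.
#'
#' @param n number of descendants (non-negative integer).
#' @param alpha,beta positive Beta shape parameters.
#' @param n_cycles total number of simulation cycles (at least 2 for `n > 0`).
#' @param seed optional integer seed.
#' @return sorted integer vector of length `n`.
#' @examples
#' draw_birth_cycles(5, 2, 2, 5000, seed = 1)
#' @export
draw_birth_cycles <- function(n, alpha = 2, beta = 2, n_cycles = 5000,
                              seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a single non-negative integer", call. = FALSE)
  }
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  if (n == 0L) return(integer(0))
  if (n_cycles < 2L) stop("'n_cycles' must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- round(n_cycles * stats::rbeta(n, alpha, beta))
  sort(as.integer(pmin(pmax(b, 1L), n_cycles - 1L)))
}
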