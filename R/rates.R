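#' Lineage-specific distances from a three-taxon comparison
#'
#' Three-point decomposition of pairwise distances between two ingroup taxa
#' (1, 2) and an outgroup O: `K1 = (d12 + d1O - d2O)/2` is the distance from
#' taxon 1 to the internal node, `K2 = (d12 + d2O - d1O)/2` from taxon 2.
#' Under equal rates K1 = K2; their difference and ratio quantify
#' lineage-specific rate acceleration. Negative decompositions (possible with
#' noisy distances) are clamped to 0 and flagged.
#'
#' @param d12,d1O,d2O non-negative pairwise distances (substitutions/site).
#' @return list with `K1`, `K2`, `difference` (K1 - K2 before clamping),
#'   `ratio` (K1/K2, `NA` when K2 = 0), `clamped`.
#' @examples
#' lineage_rates(0.2, 0.35, 0.30)  # K1 = 0.125, K2 = 0.075
#' @export
lineage_rates <- function(d12, d1O, d2O) {
  if (any(c(d12, d1O, d2O) < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  k1 <- (d12 + d1O - d2O) / 2
  k2 <- (d12 + d2O - d1O) / 2
  ## snap floating-point dust so exact-zero decompositions report 0
  if (abs(k1) < 1e-12) k1 <- 0
  if (abs(k2) < 1e-12) k2 <- 0
  clamped <- k1 < 0 || k2 < 0
  diff <- k1 - k2
  k1 <- max(k1, 0)
  k2 <- max(k2, 0)
  list(K1 = k1, K2 = k2, difference = diff,
       ratio = if (k2 == 0) NA_real_ else k1 / k2,
       clamped = clamped)
}

#' Tajima's relative-rate test for three aligned sequences
#'
#' Tajima's (1993) 1D test of the molecular clock: among alignment columns
#' where all three sequences carry unambiguous bases, `m1` counts sites where
#' sequence 1 is the odd one out (sequence 2 equals the outgroup) and `m2`
#' sites where sequence 2 is unique. Under rate equality m1 and m2 are
#' exchangeable, and `chisq = (m1 - m2)^2 / (m1 + m2)` is asymptotically
#' chi-squared with 1 df. Sites where the outgroup is the odd one out, or all
#' three differ, carry no information about the ingroup rate contrast and are
#' ignored. Lineage distances K1/K2 are reported via JC distances and
#' [lineage_rates()].
#'
#' @param seq1,seq2,outgroup aligned sequences of equal length.
#' @param labels optional character vector of three names for reporting.
#' @return object of class `"rate_test"`: list with `m1`, `m2`, `chisq`,
#'   `p_value`, `K1`, `K2`, `difference`, `ratio`, `labels`. When
#'   `m1 + m2 = 0` the test is undefined and `p_value = 1` with
#'   `undefined = TRUE`.
#' @examples
#' a <- strsplit("ACGTACGTACGTACGTACGT", "")[[1]]
#' b <- a; b[1] <- "T"
#' tajima_rrt(b, a, a)
#' @export
tajima_rrt <- function(seq1, seq2, outgroup,
                       labels = c("seq1", "seq2", "outgroup")) {
  s1 <- seq_chars(seq1)
  s2 <- seq_chars(seq2)
  og <- seq_chars(outgroup)
  if (length(unique(c(length(s1), length(s2), length(og)))) != 1L) {
    stop("sequences must have equal aligned lengths", call. = FALSE)
  }
  ok <- s1 %in% DNA_BASES & s2 %in% DNA_BASES & og %in% DNA_BASES
  m1 <- sum(ok & s1 != s2 & s2 == og)
  m2 <- sum(ok & s1 != s2 & s1 == og)
  undefined <- (m1 + m2) == 0L
  if (undefined) {
    chisq <- 0
    p <- 1
  } else {
    chisq <- (m1 - m2)^2 / (m1 + m2)
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  }
  aln <- stats::setNames(c(seq_string(s1), seq_string(s2), seq_string(og)),
                         labels)
  kk <- tryCatch({
    dm <- jc_distance(aln)
    lineage_rates(dm[1, 2], dm[1, 3], dm[2, 3])
  }, error = function(e) list(K1 = NA_real_, K2 = NA_real_,
                              difference = NA_real_, ratio = NA_real_,
                              clamped = NA))
  structure(list(m1 = m1, m2 = m2, chisq = chisq, p_value = p,
                 K1 = kk$K1, K2 = kk$K2, difference = kk$difference,
                 ratio = kk$ratio, undefined = undefined, labels = labels),
            class = "rate_test")
}

#' @export
print.rate_test <- function(x, ...) {
  cat(sprintf("Tajima relative-rate test: %s vs %s (outgroup %s)\n",
              x$labels[1], x$labels[2], x$labels[3]))
  cat(sprintf("  unique sites m1 = %d, m2 = %d;  chi-square = %.3f, p = %.4g%s\n",
              x$m1, x$m2, x$chisq, x$p_value,
              if (x$undefined) " (undefined: no informative sites)" else ""))
  if (is.finite(x$K1)) {
    cat(sprintf("  K1 = %.4f  K2 = %.4f  K1-K2 = %.4f  K1/K2 = %s\n",
                x$K1, x$K2, x$difference,
                if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio)))
  }
  invisible(x)
}
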