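## standard genetic code, DNA codons
GENETIC_CODE_STD <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

translate_codon <- function(codon) unname(GENETIC_CODE_STD[codon])

split_codons <- function(seq) {
  s <- seq_chars(seq)
  check_dna(s, "coding sequence")
  if (length(s) %% 3L != 0L) {
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  }
  vapply(seq_len(length(s) / 3L),
         function(i) paste(s[(3 * i - 2):(3 * i)], collapse = ""), "")
}

## synonymous site count of one codon: per position, the fraction of the three
## alternative bases giving a synonymous change (changes to stops count as
## nonsynonymous)
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      if (translate_codon(paste(mut, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

## average synonymous/nonsynonymous differences between two codons over all
## equal-weighted mutational pathways; pathways through stop codons are
## excluded when at least one stop-free pathway exists
codon_path_diffs <- function(c1, c2) {
  chars1 <- strsplit(c1, "")[[1]]
  chars2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(chars1 != chars2)
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(diff_pos) else {
    idx <- permutations_of(k)
    lapply(seq_len(nrow(idx)), function(i) diff_pos[idx[i, ]])
  }
  path_counts <- function(order) {
    cur <- chars1
    sd <- nd <- 0
    via_stop <- FALSE
    for (pos in order) {
      aa_from <- translate_codon(paste(cur, collapse = ""))
      cur[pos] <- chars2[pos]
      codon_to <- paste(cur, collapse = "")
      aa_to <- translate_codon(codon_to)
      if (aa_to == "*" && codon_to != c2) via_stop <- TRUE
      if (aa_from == aa_to) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, via_stop = as.numeric(via_stop))
  }
  res <- vapply(perms, path_counts, c(sd = 0, nd = 0, via_stop = 0))
  keep <- res["via_stop", ] == 0
  if (!any(keep)) keep <- rep(TRUE, ncol(res))
  c(sd = mean(res["sd", keep]), nd = mean(res["nd", keep]))
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Unweighted-pathway dS/dN for a pair of aligned coding sequences.
#' Synonymous site counts per codon are the fractions of the three possible
#' changes at each position that preserve the amino acid (changes to stop
#' codons count as nonsynonymous); site totals are averaged between the two
#' sequences. Differences within a codon are resolved over all equal-weighted
#' minimal mutational pathways (pathways through intermediate stop codons are
#' dropped when avoidable). The proportions ps = Sd/S and pn = Nd/N are
#' corrected for multiple hits Jukes-Cantor style:
#' d = -(3/4) log(1 - (4/3) p).
#'
#' @param seq1,seq2 aligned coding sequences: equal lengths divisible by 3,
#'   no internal stop codons (a shared terminal stop codon is trimmed).
#' @return object of class `"ds_result"`: list with `dS`, `dN`, `S`, `N`
#'   (site counts), `Sd`, `Nd` (difference counts), `ps`, `pn`,
#'   `saturated_s`, `saturated_n`.
#' @examples
#' ng86_ds(strrep("TTT", 10), paste0(strrep("TTT", 9), "TTC"))
#' @export
ng86_ds <- function(seq1, seq2) {
  cod1 <- split_codons(seq1)
  cod2 <- split_codons(seq2)
  if (length(cod1) != length(cod2)) {
    stop("coding sequences must have equal lengths", call. = FALSE)
  }
  n <- length(cod1)
  if (n > 1L && translate_codon(cod1[n]) == "*" &&
      translate_codon(cod2[n]) == "*") {
    cod1 <- cod1[-n]
    cod2 <- cod2[-n]
    n <- n - 1L
  }
  if (any(translate_codon(cod1) == "*") || any(translate_codon(cod2) == "*")) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  s1 <- sum(vapply(cod1, codon_syn_sites, 0))
  s2 <- sum(vapply(cod2, codon_syn_sites, 0))
  S <- (s1 + s2) / 2
  N <- 3 * n - S
  diffs <- vapply(seq_len(n),
                  function(i) codon_path_diffs(cod1[i], cod2[i]),
                  c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else max(0, -0.75 * log(1 - 4 / 3 * p))
  structure(list(dS = jc(ps), dN = jc(pn), S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn,
                 saturated_s = ps >= 0.75, saturated_n = pn >= 0.75,
                 n_codons = n), class = "ds_result")
}

#' @export
print.ds_result <- function(x, ...) {
  cat(sprintf("NG86 divergence over %d codons\n", x$n_codons))
  cat(sprintf("  S = %.3f, Sd = %.3f, ps = %.4f, dS = %s%s\n",
              x$S, x$Sd, x$ps,
              if (x$saturated_s) "saturated" else sprintf("%.4f", x$dS), ""))
  cat(sprintf("  N = %.3f, Nd = %.3f, pn = %.4f, dN = %s\n",
              x$N, x$Nd, x$pn,
              if (x$saturated_n) "saturated" else sprintf("%.4f", x$dN)))
  invisible(x)
}

#' Time since divergence by linear extrapolation from a calibration pair
#'
#' Synonymous divergence accumulates approximately neutrally, so dS is used
#' as a linear clock: a calibration pair with known dS and known divergence
#' time anchors the rate, and `TSD = round(ds / ds_cal * t_cal)` dates any
#' other pair. The default anchor is the free-living progenitor (strain HS)
#' versus the grain-weevil symbiont SOPE: dS 0.046 (fusA) at 28,000 years.
#'
#' @param ds observed synonymous divergence (non-negative).
#' @param ds_cal,t_cal calibration divergence (> 0) and time in years (> 0).
#' @return estimated divergence time in years, rounded to the nearest
#'   integer.
#' @examples
#' tsd_extrapolate(0.428)                 # 260522 years
#' tsd_extrapolate(0.046)                 # the anchor itself: 28000
#' @export
tsd_extrapolate <- function(ds, ds_cal = 0.046, t_cal = 28000) {
  if (!is.numeric(ds) || any(ds < 0)) {
    stop("'ds' must be non-negative", call. = FALSE)
  }
  if (ds_cal <= 0 || t_cal <= 0) {
    stop("calibration dS and time must be positive", call. = FALSE)
  }
  round(ds / ds_cal * t_cal)
}
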