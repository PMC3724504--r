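## random DNA with target GC content (no seeding; callers manage the RNG)
random_dna <- function(length, gc_fraction = 0.5) {
  if (length < 1) stop("'length' must be at least 1", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("'gc_fraction' must lie in [0, 1]", call. = FALSE)
  }
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  sample(DNA_BASES, length, replace = TRUE, prob = p)
}

#' Generate a synthetic progenitor sequence
#'
#' Random nucleotide sequence with a target GC fraction, the synthetic
#' stand-in for a 16S rRNA progenitor (default length 1460 nt, GC 0.54,
#' resembling free-living enterobacterial 16S composition).
#'
#' @param length sequence length in nt.
#' @param gc_fraction target GC content in `[0, 1]`.
#' @param seed integer seed.
#' @return a single character string.
#' @examples
#' make_progenitor(60, 0.54, seed = 1)
#' @export
make_progenitor <- function(length = 1460, gc_fraction = 0.54, seed = 1L) {
  set.seed(seed)
  seq_string(random_dna(length, gc_fraction))
}

#' Generate a toy secondary-structure fixture
#'
#' Builds a well-formed nested dot-bracket annotation containing `n_hairpins`
#' stem-loop hairpins evenly spread along the sequence, plus the matching
#' positional variability map: stem (paired) positions are flagged
#' low-variability, loop and linker positions high-variability - the
#' constraint pattern real rRNA stems show.
#'
#' @param length total annotation length.
#' @param n_hairpins number of hairpins (0 gives an all-unpaired annotation).
#' @param stem_len,loop_len helix and loop lengths per hairpin.
#' @param seed integer seed (placement jitter).
#' @return list with `dotbracket` (string), `structure` (partner vector from
#'   [parse_dotbracket()]), and `varmap` (named `"high"`/`"low"` vector).
#' @export
make_structure_fixture <- function(length, n_hairpins, stem_len = 4,
                                   loop_len = 4, seed = 1L) {
  unit <- 2 * stem_len + loop_len
  if (n_hairpins * unit > length) {
    stop("hairpins do not fit in the requested length", call. = FALSE)
  }
  set.seed(seed)
  db <- rep(".", length)
  if (n_hairpins > 0) {
    slot <- length %/% n_hairpins
    for (h in seq_len(n_hairpins)) {
      slack <- slot - unit
      offset <- if (slack > 0) sample.int(slack, 1L) - 1L else 0L
      start <- (h - 1L) * slot + offset + 1L
      db[start:(start + stem_len - 1L)] <- "("
      db[(start + stem_len + loop_len):(start + unit - 1L)] <- ")"
    }
  }
  dotbracket <- paste(db, collapse = "")
  partner <- parse_dotbracket(dotbracket)
  varmap <- stats::setNames(ifelse(is.na(partner), "high", "low"),
                            seq_along(partner))
  list(dotbracket = dotbracket, structure = partner, varmap = varmap)
}

## single-base neighbors of a codon, with translation
codon_neighbors <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (alt in setdiff(DNA_BASES, chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Generate a codon-alignment pair with controlled divergence
#'
#' Builds a random stop-free coding sequence of `n_codons` codons, then
#' injects exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous single-base
#' codon changes (one change per codon, never creating a stop) to produce the
#' second sequence. Useful for exercising [ng86_ds()] with known ground
#' truth.
#'
#' @param n_codons number of codons.
#' @param n_syn,n_nonsyn numbers of synonymous / nonsynonymous changes;
#'   `n_syn + n_nonsyn` must not exceed `n_codons`.
#' @param seed integer seed.
#' @return list with `seq1`, `seq2` (strings), `syn_positions`,
#'   `nonsyn_positions` (codon indices).
#' @export
make_codon_pair <- function(n_codons, n_syn = 0, n_nonsyn = 0, seed = 1L) {
  if (n_syn + n_nonsyn > n_codons) {
    stop("requested changes exceed the number of codons", call. = FALSE)
  }
  set.seed(seed)
  sense <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  ## codons admitting a synonymous single-base neighbor
  has_syn <- vapply(sense, function(cd) {
    nb <- codon_neighbors(cd)
    any(GENETIC_CODE_STD[nb] == GENETIC_CODE_STD[cd])
  }, TRUE)
  cod1 <- character(n_codons)
  cod1[] <- sample(sense[has_syn], n_codons, replace = TRUE)
  cod2 <- cod1
  targets <- sample.int(n_codons, n_syn + n_nonsyn)
  syn_pos <- targets[seq_len(n_syn)]
  non_pos <- setdiff(targets, syn_pos)
  pick <- function(codon, synonymous) {
    nb <- codon_neighbors(codon)
    aa <- GENETIC_CODE_STD[codon]
    ok <- if (synonymous) GENETIC_CODE_STD[nb] == aa
          else GENETIC_CODE_STD[nb] != aa & GENETIC_CODE_STD[nb] != "*"
    cand <- nb[ok]
    if (length(cand) == 0L) stop("codon admits no suitable change", call. = FALSE)
    cand[sample.int(length(cand), 1L)]
  }
  for (i in syn_pos) cod2[i] <- pick(cod1[i], TRUE)
  for (i in non_pos) cod2[i] <- pick(cod1[i], FALSE)
  list(seq1 = paste(cod1, collapse = ""),
       seq2 = paste(cod2, collapse = ""),
       syn_positions = sort(syn_pos),
       nonsyn_positions = sort(non_pos))
}

#' Named presets of the replacement-simulation experiments
#'
#' The four canonical experiment configurations: a 1460-nt progenitor run for
#' 5000 cycles with 12 descendants born at Beta(2,2) times, under
#' \describe{
#'   \item{`slow_progenitor`}{progenitor rate 0.002, descendant rate 0.016
#'     (expected substitutions per sequence per cycle) - the calibrated
#'     baseline with an 8-fold descendant acceleration.}
#'   \item{`equal_rates`}{0.016 / 0.016 - progenitor sped up to match the
#'     descendants, seeding synapomorphies and raising bootstrap support.}
#'   \item{`fast_descendants`}{0.016 / 0.128 - a further 8-fold descendant
#'     acceleration, drowning signal in noise.}
#'   \item{`cospeciation`}{the `slow_progenitor` configuration with the
#'     earliest-born descendant splitting into "cospec1"/"cospec2" at cycle
#'     2500, mimicking a host-symbiont co-speciation.}
#' }
#'
#' @param preset preset name.
#' @param seed integer seed stored in the returned parameters.
#' @return a [sim_params()] object.
#' @export
replacement_preset <- function(preset = c("slow_progenitor", "equal_rates",
                                          "fast_descendants", "cospeciation"),
                               seed = 1L) {
  preset <- match.arg(preset)
  base <- list(n_cycles = 5000, n_descendants = 12, beta_alpha = 2,
               beta_beta = 2, seq_length = 1460, gc_fraction = 0.54,
               seed = seed)
  extra <- switch(preset,
    slow_progenitor = list(progenitor_rate = 0.002, descendant_rate = 0.016),
    equal_rates = list(progenitor_rate = 0.016, descendant_rate = 0.016),
    fast_descendants = list(progenitor_rate = 0.016, descendant_rate = 0.128),
    cospeciation = list(progenitor_rate = 0.002, descendant_rate = 0.016,
                        cospec_cycle = 2500, cospec_lineage = "earliest"))
  do.call(sim_params, c(base, extra))
}

#' Generate a full replacement dataset from a preset
#'
#' Runs [run_simulation()] under a [replacement_preset()] configuration and
#' optionally writes the FASTA alignment plus event log to disk.
#'
#' @param preset preset name (see [replacement_preset()]).
#' @param seed integer seed.
#' @param dir optional output directory; when given, files are written via
#'   [write_simulation()].
#' @return the `"replacement_sim"` object (with attribute `"files"` when
#'   written).
#' @export
make_replacement_dataset <- function(preset = "slow_progenitor", seed = 1L,
                                     dir = NULL) {
  sim <- run_simulation(replacement_preset(preset, seed = seed))
  if (!is.null(dir)) {
    files <- write_simulation(sim, dir, prefix = preset)
    attr(sim, "files") <- files
  }
  sim
}
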