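#' Parameters for the symbiont-replacement simulator
#'
#' Bundles and validates the configuration of [run_simulation()]: a progenitor
#' sequence evolving for `n_cycles` discrete cycles at `progenitor_rate`,
#' spawning `n_descendants` lineages at Beta-distributed birth cycles, each of
#' which thereafter evolves independently at `descendant_rate`. Optionally one
#' descendant splits into two lineages ("cospec1"/"cospec2") at `cospec_cycle`,
#' mimicking a host-symbiont co-speciation event.
#'
#' Rates are expected substitutions per *sequence* per cycle by default
#' (`rate_unit = "per_sequence"`); set `rate_unit = "per_site"` to have them
#' multiplied by the sequence length.
#'
#' @param n_cycles number of simulation cycles (default 5000).
#' @param progenitor_rate,descendant_rate non-negative finite substitution
#'   rates (see `rate_unit`).
#' @param n_descendants non-negative integer number of descendant lineages.
#' @param beta_alpha,beta_beta positive shape parameters of the Beta
#'   birth-time distribution (defaults 2 and 2).
#' @param cospec_cycle optional integer cycle at which one descendant splits
#'   into "cospec1" and "cospec2"; must lie in `(birth, n_cycles)`.
#' @param cospec_lineage which descendant splits: `"earliest"` (default, the
#'   earliest-born) or a 1-based index into the birth-order of descendants.
#' @param progenitor_seq the starting sequence (string or character vector
#'   over A/C/G/T); default is a synthetic 1460-nt sequence with GC 0.54
#'   generated from `seed`.
#' @param seq_length,gc_fraction used to generate the default progenitor.
#' @param rate_unit `"per_sequence"` (canonical) or `"per_site"`.
#' @param seed integer seed controlling every random draw of the run.
#' @return an object of class `"sim_params"` (a validated list).
#' @seealso [run_simulation()], [replacement_preset()]
#' @export
sim_params <- function(n_cycles = 5000,
                       progenitor_rate = 0.002,
                       descendant_rate = 0.016,
                       n_descendants = 12,
                       beta_alpha = 2,
                       beta_beta = 2,
                       cospec_cycle = NULL,
                       cospec_lineage = "earliest",
                       progenitor_seq = NULL,
                       seq_length = 1460,
                       gc_fraction = 0.54,
                       rate_unit = c("per_sequence", "per_site"),
                       seed = 1L) {
  rate_unit <- match.arg(rate_unit)
  if (!is.numeric(n_cycles) || n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  }
  for (r in c(progenitor_rate, descendant_rate)) {
    if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0) {
      stop("rates must be single finite non-negative numbers", call. = FALSE)
    }
  }
  if (n_descendants < 0 || n_descendants != round(n_descendants)) {
    stop("'n_descendants' must be a non-negative integer", call. = FALSE)
  }
  if (beta_alpha <= 0 || beta_beta <= 0) {
    stop("Beta shape parameters must be positive", call. = FALSE)
  }
  if (!is.null(cospec_cycle)) {
    if (n_descendants < 1) {
      stop("co-speciation requires at least one descendant", call. = FALSE)
    }
    if (cospec_cycle >= n_cycles || cospec_cycle < 1) {
      stop("'cospec_cycle' must lie in [1, n_cycles - 1]", call. = FALSE)
    }
    if (!identical(cospec_lineage, "earliest") &&
        (!is.numeric(cospec_lineage) || cospec_lineage < 1 ||
         cospec_lineage > n_descendants)) {
      stop("'cospec_lineage' must be \"earliest\" or a descendant index",
           call. = FALSE)
    }
  }
  if (!is.null(progenitor_seq)) {
    progenitor_seq <- seq_chars(progenitor_seq)
    check_dna(progenitor_seq, "progenitor_seq")
  }
  structure(list(
    n_cycles = as.integer(n_cycles),
    progenitor_rate = progenitor_rate,
    descendant_rate = descendant_rate,
    n_descendants = as.integer(n_descendants),
    beta_alpha = beta_alpha, beta_beta = beta_beta,
    cospec_cycle = if (is.null(cospec_cycle)) NULL else as.integer(cospec_cycle),
    cospec_lineage = cospec_lineage,
    progenitor_seq = progenitor_seq,
    seq_length = as.integer(seq_length),
    gc_fraction = gc_fraction,
    rate_unit = rate_unit,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Replacement-simulation parameters\n")
  cat(sprintf("  cycles: %d   descendants: %d   rates (prog/desc): %g / %g %s\n",
              x$n_cycles, x$n_descendants, x$progenitor_rate,
              x$descendant_rate, x$rate_unit))
  cat(sprintf("  birth times ~ %d * Beta(%g, %g)\n",
              x$n_cycles, x$beta_alpha, x$beta_beta))
  if (!is.null(x$cospec_cycle)) {
    cat(sprintf("  co-speciation of lineage '%s' at cycle %d\n",
                as.character(x$cospec_lineage), x$cospec_cycle))
  }
  len <- if (is.null(x$progenitor_seq)) x$seq_length else length(x$progenitor_seq)
  cat(sprintf("  progenitor length: %d nt   seed: %d\n", len, x$seed))
  invisible(x)
}

#' Run the discrete-time symbiont-replacement simulation
#'
#' A single progenitor sequence accumulates random point substitutions over
#' `n_cycles` cycles. At Beta-distributed birth cycles, descendant lineages are
#' initialized as exact copies of the progenitor's current sequence and
#' thereafter evolve independently at the (typically elevated) descendant
#' rate. An optional co-speciation event replaces one descendant by two
#' lineages, "cospec1" and "cospec2", that share its history up to the split
#' cycle. Substitution counts over any span of cycles are Poisson with mean
#' rate x cycles; sites are chosen uniformly and a hit replaces the base by
#' one of the three alternatives, so repeated hits (including reversions) can
#' occur. No indels are introduced.
#'
#' Output labels follow the convention `"prog"` for the progenitor,
#' `"d<birth cycle>"` for descendants, and `"cospec1"`/`"cospec2"` for the
#' co-speciated pair. The run is fully reproducible from `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `"replacement_sim"`: a list with elements
#'   `sequences` (named character vector of final sequences), `lineages`
#'   (data frame with label, birth_cycle, parent, rate), `params`, and `seed`.
#' @examples
#' sim <- run_simulation(sim_params(n_cycles = 200, n_descendants = 3,
#'                                  seq_length = 300, seed = 42))
#' sim
#' @export
run_simulation <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  set.seed(params$seed)
  prog <- params$progenitor_seq
  if (is.null(prog)) {
    prog <- random_dna(params$seq_length, params$gc_fraction)
  }
  L <- length(prog)
  scale <- if (params$rate_unit == "per_site") L else 1
  prate <- params$progenitor_rate * scale
  drate <- params$descendant_rate * scale

  births <- draw_birth_cycles(params$n_descendants, params$beta_alpha,
                              params$beta_beta, params$n_cycles)
  labels <- if (length(births)) make.unique(paste0("d", births), sep = "_") else character(0)

  cospec_idx <- NULL
  if (!is.null(params$cospec_cycle)) {
    cospec_idx <- if (identical(params$cospec_lineage, "earliest")) 1L
                  else as.integer(params$cospec_lineage)
    if (params$cospec_cycle <= births[cospec_idx]) {
      stop(sprintf(
        "co-speciation cycle %d is not after the birth cycle (%d) of lineage '%s'",
        params$cospec_cycle, births[cospec_idx], labels[cospec_idx]),
        call. = FALSE)
    }
  }

  ## progenitor trajectory: evolve segment-wise, snapshotting at each birth
  snapshots <- vector("list", length(births))
  cur <- prog
  t0 <- 0L
  for (i in seq_along(births)) {
    cur <- evolve_chars(cur, prate, births[i] - t0)
    snapshots[[i]] <- cur
    t0 <- births[i]
  }
  prog_final <- evolve_chars(cur, prate, params$n_cycles - t0)

  seqs <- list(prog = seq_string(prog_final))
  lineages <- data.frame(label = "prog", birth_cycle = 0L, parent = NA_character_,
                         rate = params$progenitor_rate, stringsAsFactors = FALSE)

  for (i in seq_along(births)) {
    b <- births[i]
    if (!is.null(cospec_idx) && i == cospec_idx) {
      stem <- evolve_chars(snapshots[[i]], drate, params$cospec_cycle - b)
      for (lab in c("cospec1", "cospec2")) {
        tip <- evolve_chars(stem, drate, params$n_cycles - params$cospec_cycle)
        seqs[[lab]] <- seq_string(tip)
        lineages <- rbind(lineages, data.frame(
          label = lab, birth_cycle = params$cospec_cycle, parent = labels[i],
          rate = params$descendant_rate, stringsAsFactors = FALSE))
      }
    } else {
      tip <- evolve_chars(snapshots[[i]], drate, params$n_cycles - b)
      seqs[[labels[i]]] <- seq_string(tip)
      lineages <- rbind(lineages, data.frame(
        label = labels[i], birth_cycle = b, parent = "prog",
        rate = params$descendant_rate, stringsAsFactors = FALSE))
    }
  }

  structure(list(
    sequences = unlist(seqs),
    lineages = lineages,
    params = params,
    seed = params$seed
  ), class = "replacement_sim")
}

#' @export
print.replacement_sim <- function(x, ...) {
  n <- length(x$sequences)
  cat(sprintf("Replacement simulation: %d lineages, %d nt, %d cycles (seed %d)\n",
              n, nchar(x$sequences[[1L]]), x$params$n_cycles, x$seed))
  cat("  labels:", paste(names(x$sequences), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.replacement_sim <- function(object, ...) {
  ds <- summarize_divergence(object)
  cat(sprintf(
    "Progenitor-descendant JC divergence: mean %.4f, variance %.3g (%d pairs)\n",
    ds$mean, ds$variance, ds$n_pairs))
  invisible(ds)
}

#' Write simulation output to disk
#'
#' Writes the final sequences as multi-FASTA, the lineage event log as TSV
#' (columns label, birth_cycle, parent, rate), and a YAML echo of the
#' parameters.
#'
#' @param sim a `"replacement_sim"` object.
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "replacement_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  tsv <- file.path(dir, paste0(prefix, "_events.tsv"))
  cfg <- file.path(dir, paste0(prefix, "_params.yaml"))
  write_fasta(sim$sequences, fa)
  utils::write.table(sim$lineages, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p <- sim$params
  p$progenitor_seq <- if (is.null(p$progenitor_seq)) NULL else seq_string(p$progenitor_seq)
  writeLines(yaml::as.yaml(unclass(p)), cfg)
  invisible(c(fasta = fa, events = tsv, params = cfg))
}
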