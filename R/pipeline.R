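#' Run a multi-stage analysis pipeline
#'
#' Executes a sequence of analysis stages described by a structured
#' configuration (an R list, or a YAML file path), writing every artifact and
#' a run manifest to the output directory. Stages run in order; any stage
#' error aborts the pipeline with a message naming the stage. Every stochastic
#' stage receives an explicit seed, derived deterministically from the global
#' `seed` and the stage index when not given, so a whole run is reproducible
#' from one master seed. Log messages go to standard error (via
#' [message()]); results go only to files.
#'
#' Supported stages and their parameters:
#' \describe{
#'   \item{simulate}{`preset` (see [replacement_preset()]) or raw
#'     [sim_params()] fields; writes FASTA, event-log TSV and a parameter
#'     echo.}
#'   \item{tree}{`fasta` input (defaults to the previous simulate stage's
#'     output), `n_reps` bootstrap replicates; writes Newick with supports
#'     and the distance matrix TSV.}
#'   \item{mbv}{`newick` input (defaults to the previous tree stage); writes
#'     the mean bootstrap value.}
#'   \item{shape}{`newick` input; writes comb-topology metrics.}
#'   \item{classify}{`ref_fasta`, `query_fasta`, `structure` (dot-bracket
#'     file), optional `varmap` TSV; writes substitution records and the
#'     classification summary.}
#'   \item{rrt}{`fasta` with exactly three aligned sequences
#'     (seq1, seq2, outgroup); writes the relative-rate test table.}
#'   \item{ds}{`fasta` with two aligned coding sequences; writes NG86
#'     dS/dN.}
#'   \item{tsd}{`ds` value(s), `ds_cal`, `t_cal`; writes extrapolated
#'     divergence times.}
#'   \item{calibrate}{`target_mean`, `target_var` and
#'     [calibrate_params()] settings; writes the accepted trajectory and best
#'     parameters.}
#'   \item{make_data}{`kind` in `progenitor`, `structure`, `codon_pair`,
#'     `replacement_dataset` plus the matching generator arguments.}
#' }
#'
#' @param config an R list with fields `seed`, `out_dir`, `stages` (list of
#'   stage blocks, each with a `stage` name and parameters), or the path of a
#'   YAML file with that shape.
#' @param quiet suppress progress messages.
#' @return invisibly, a named list of artifact paths per stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config needs an 'out_dir'", call. = FALSE)
  if (is.null(config$stages) || length(config$stages) == 0L) {
    stop("config needs a non-empty 'stages' list", call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  artifacts <- list()
  last <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    name <- st$stage
    if (is.null(name)) stop("stage block ", i, " lacks a 'stage' field",
                            call. = FALSE)
    st$seed <- as.integer(st$seed %||% (seed + i))
    say("[%d/%d] stage '%s' (seed %d)", i, length(config$stages), name, st$seed)
    handler <- switch(name,
      simulate = stage_simulate, tree = stage_tree, mbv = stage_mbv,
      shape = stage_shape, classify = stage_classify, rrt = stage_rrt,
      ds = stage_ds, tsd = stage_tsd, calibrate = stage_calibrate,
      make_data = stage_make_data,
      stop(sprintf("unknown pipeline stage '%s'", name), call. = FALSE))
    res <- tryCatch(handler(st, out_dir, last),
                    error = function(e) {
                      stop(sprintf("stage '%s' failed: %s", name,
                                   conditionMessage(e)), call. = FALSE)
                    })
    last <- res
    artifacts[[paste0(i, "_", name)]] <- res$files
  }

  manifest <- list(package = "combsim",
                   version = as.character(utils::packageVersion("combsim")),
                   seed = seed,
                   stages = config$stages,
                   artifacts = lapply(artifacts, as.list))
  manifest_path <- file.path(out_dir, "manifest.yaml")
  writeLines(yaml::as.yaml(manifest), manifest_path)
  say("wrote manifest: %s", manifest_path)
  invisible(artifacts)
}

stage_input <- function(st, field, last, last_field, what) {
  path <- st[[field]] %||% last$files[[last_field]]
  if (is.null(path) || !file.exists(path)) {
    stop(sprintf("missing %s input ('%s')", what, field %||% last_field),
         call. = FALSE)
  }
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_simulate <- function(st, out_dir, last) {
  if (!is.null(st$preset)) {
    sim <- run_simulation(replacement_preset(st$preset, seed = st$seed))
  } else {
    args <- st[setdiff(names(st), c("stage", "preset"))]
    sim <- run_simulation(do.call(sim_params, args))
  }
  files <- write_simulation(sim, out_dir,
                            prefix = st$prefix %||% st$preset %||% "sim")
  list(files = files, sim = sim)
}

stage_tree <- function(st, out_dir, last) {
  fasta <- stage_input(st, "fasta", last, "fasta", "alignment")
  aln <- read_fasta(fasta)
  tr <- bootstrap_tree(aln, n_reps = st$n_reps %||% 100, seed = st$seed)
  nwk <- file.path(out_dir, paste0(st$prefix %||% "tree", ".nwk"))
  write_newick(tr, nwk)
  dm <- jc_distance(aln)
  dtsv <- write_tsv(data.frame(label = rownames(dm), dm, check.names = FALSE),
                    file.path(out_dir, paste0(st$prefix %||% "tree", "_dist.tsv")))
  list(files = c(newick = nwk, distances = dtsv), tree = tr)
}

stage_mbv <- function(st, out_dir, last) {
  tr <- last$tree
  if (is.null(tr)) tr <- ape::read.tree(stage_input(st, "newick", last,
                                                    "newick", "tree"))
  out <- file.path(out_dir, "mbv.tsv")
  write_tsv(data.frame(mbv = mean_bootstrap_value(tr)), out)
  list(files = c(mbv = out), tree = tr)
}

stage_shape <- function(st, out_dir, last) {
  tr <- last$tree
  if (is.null(tr)) tr <- ape::read.tree(stage_input(st, "newick", last,
                                                    "newick", "tree"))
  m <- tree_shape_metrics(tr)
  out <- write_tsv(data.frame(mean_terminal = m$mean_terminal,
                              mean_internal = m$mean_internal,
                              ratio = m$ratio,
                              mean_support = m$mean_support),
                   file.path(out_dir, "shape.tsv"))
  list(files = c(shape = out), tree = tr)
}

stage_classify <- function(st, out_dir, last) {
  ref <- read_fasta(stage_input(st, "ref_fasta", last, "ref_fasta", "reference"))
  qry <- read_fasta(stage_input(st, "query_fasta", last, "query_fasta", "query"))
  struct <- read_structure(stage_input(st, "structure", last, "structure",
                                       "dot-bracket"))
  rec <- call_substitutions(ref[[1L]], qry[[1L]])
  rec <- classify_substitutions(rec, struct, qry[[1L]])
  varmap <- if (!is.null(st$varmap)) read_varmap(st$varmap) else NULL
  summ <- score_variability(rec, varmap)
  rec_path <- write_tsv(summ$records, file.path(out_dir, "substitutions.tsv"))
  sum_path <- write_tsv(data.frame(
    n_substitutions = summ$n_substitutions, disruptive = summ$disruptive,
    conservative = summ$conservative,
    disruptive_fraction = summ$disruptive_fraction,
    low_variability = summ$low_variability,
    high_variability = summ$high_variability),
    file.path(out_dir, "classification_summary.tsv"))
  list(files = c(records = rec_path, summary = sum_path), summary = summ)
}

stage_rrt <- function(st, out_dir, last) {
  seqs <- read_fasta(stage_input(st, "fasta", last, "fasta", "triple"))
  if (length(seqs) != 3L) stop("relative-rate test needs exactly 3 sequences",
                               call. = FALSE)
  rt <- tajima_rrt(seqs[[1L]], seqs[[2L]], seqs[[3L]], labels = names(seqs))
  out <- write_tsv(data.frame(
    lineage1 = names(seqs)[1], lineage2 = names(seqs)[2],
    outgroup = names(seqs)[3], K1 = rt$K1, K2 = rt$K2,
    difference = rt$difference, ratio = rt$ratio,
    m1 = rt$m1, m2 = rt$m2, chisq = rt$chisq, p_value = rt$p_value),
    file.path(out_dir, "rrt.tsv"))
  list(files = c(rrt = out), test = rt)
}

stage_ds <- function(st, out_dir, last) {
  seqs <- read_fasta(stage_input(st, "fasta", last, "fasta", "codon pair"))
  if (length(seqs) != 2L) stop("dS needs exactly 2 coding sequences",
                               call. = FALSE)
  res <- ng86_ds(seqs[[1L]], seqs[[2L]])
  out <- write_tsv(data.frame(dS = res$dS, dN = res$dN, S = res$S, N = res$N,
                              Sd = res$Sd, Nd = res$Nd),
                   file.path(out_dir, "ds.tsv"))
  list(files = c(ds = out), ds = res)
}

stage_tsd <- function(st, out_dir, last) {
  ds <- st$ds %||% last$ds$dS
  if (is.null(ds)) stop("missing 'ds' value", call. = FALSE)
  years <- tsd_extrapolate(unlist(ds), ds_cal = st$ds_cal %||% 0.046,
                           t_cal = st$t_cal %||% 28000)
  out <- write_tsv(data.frame(ds = unlist(ds), tsd_years = years),
                   file.path(out_dir, "tsd.tsv"))
  list(files = c(tsd = out))
}

stage_calibrate <- function(st, out_dir, last) {
  fit <- calibrate_params(
    list(mean = st$target_mean, variance = st$target_var),
    base_params = sim_params(seed = st$seed),
    fix_ratio = st$fix_ratio %||% 8,
    iterations = st$iterations %||% 40,
    replicates = st$replicates %||% 10,
    seed = st$seed)
  traj <- write_tsv(fit$trajectory, file.path(out_dir, "calibration_trajectory.tsv"))
  best <- write_tsv(data.frame(t(coef(fit)), objective = fit$objective),
                    file.path(out_dir, "calibration_best.tsv"))
  list(files = c(trajectory = traj, best = best), fit = fit)
}

stage_make_data <- function(st, out_dir, last) {
  kind <- st$kind %||% "replacement_dataset"
  switch(kind,
    progenitor = {
      fa <- file.path(out_dir, "progenitor.fasta")
      write_fasta(c(prog = make_progenitor(st$length %||% 1460,
                                           st$gc_fraction %||% 0.54,
                                           seed = st$seed)), fa)
      list(files = c(fasta = fa))
    },
    structure = {
      fx <- make_structure_fixture(st$length %||% 100,
                                   st$n_hairpins %||% 3, seed = st$seed)
      dbn <- file.path(out_dir, "structure.dbn")
      writeLines(fx$dotbracket, dbn)
      vm <- write_tsv(data.frame(position = as.integer(names(fx$varmap)),
                                 flag = unname(fx$varmap)),
                      file.path(out_dir, "varmap.tsv"))
      list(files = c(structure = dbn, varmap = vm))
    },
    codon_pair = {
      cp <- make_codon_pair(st$n_codons %||% 50, st$n_syn %||% 5,
                            st$n_nonsyn %||% 5, seed = st$seed)
      fa <- file.path(out_dir, "codon_pair.fasta")
      write_fasta(c(seq1 = cp$seq1, seq2 = cp$seq2), fa)
      list(files = c(fasta = fa))
    },
    replacement_dataset = {
      sim <- make_replacement_dataset(st$preset %||% "slow_progenitor",
                                      seed = st$seed, dir = out_dir)
      list(files = attr(sim, "files"), sim = sim)
    },
    stop(sprintf("unknown data kind '%s'", kind), call. = FALSE))
}
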