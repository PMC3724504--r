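#' Jukes-Cantor distance matrix from an alignment
#'
#' Computes pairwise distances using only columns where both sequences carry
#' an unambiguous A/C/G/T (pairwise deletion of gap and ambiguity columns).
#' The proportion of differing sites p is corrected for multiple hits as
#' d = -(3/4) log(1 - (4/3) p); `model = "p"` returns the raw p-distance.
#'
#' @param alignment an alignment (DNAbin matrix, named character vector of
#'   equal-length strings, or character matrix).
#' @param model `"JC"` (default) or `"p"`.
#' @return a symmetric numeric matrix with zero diagonal and the sequence
#'   labels as dimnames.
#' @section Errors: a pair sharing no comparable columns is an error, as is a
#'   pair with p >= 0.75 under `model = "JC"` (JC saturation).
#' @examples
#' aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAA")
#' jc_distance(aln)
#' @export
jc_distance <- function(alignment, model = c("JC", "p")) {
  model <- match.arg(model)
  aln <- as_alignment(alignment)
  p <- as.matrix(ape::dist.dna(aln, model = "raw", pairwise.deletion = TRUE))
  bad <- which(!is.finite(p) & upper.tri(p), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("sequences '%s' and '%s' share no comparable columns",
                 rownames(p)[bad[1, 1]], colnames(p)[bad[1, 2]]),
         call. = FALSE)
  }
  if (model == "p") return(p)
  sat <- which(p >= 0.75 & upper.tri(p), arr.ind = TRUE)
  if (nrow(sat) > 0L) {
    stop(sprintf(
      "saturated pair '%s' vs '%s': p-distance %.3f >= 0.75, JC undefined",
      rownames(p)[sat[1, 1]], colnames(p)[sat[1, 2]], p[sat[1, , drop = FALSE]]),
      call. = FALSE)
  }
  d <- -0.75 * log(1 - 4 / 3 * p)
  diag(d) <- 0
  d
}

check_distance_matrix <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || is.null(rownames(dm))) {
    stop("distance matrix must be square with labels", call. = FALSE)
  }
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(dm))) stop("distance matrix must be finite", call. = FALSE)
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(dm < 0)) stop("distances must be non-negative", call. = FALSE)
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]); negative branch
#' lengths, an artefact of the algorithm on noisy matrices, are clamped to 0.
#' Two taxa yield the degenerate two-edge tree whose total length is their
#' distance.
#'
#' @param dm symmetric distance matrix with labels (e.g. from
#'   [jc_distance()]).
#' @return an unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(dm) {
  dm <- check_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = c(dm[1, 2] / 2, dm[1, 2] / 2),
               tip.label = rownames(dm), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(dm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Builds the point-estimate NJ tree from JC distances, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree per
#' replicate, and annotates every internal edge of the point tree with the
#' percentage of replicates containing the corresponding bipartition. Support
#' values are stored in `tree$node.label` (the basal node of the unrooted
#' tree, whose split is trivial, gets `NA`).
#'
#' If the alignment has no variable sites the supports are undefined: all node
#' labels are `NA` and the attribute `"degenerate"` is set.
#'
#' @param alignment alignment accepted by [jc_distance()].
#' @param n_reps number of bootstrap replicates (default 100).
#' @param seed integer seed; the run is reproducible.
#' @param model distance model passed to [jc_distance()].
#' @return a `phylo` tree with numeric `node.label` supports in `[0, 100]`.
#' @examples
#' sim <- run_simulation(sim_params(n_cycles = 500, n_descendants = 4,
#'                                  seq_length = 400, seed = 7))
#' tr <- bootstrap_tree(sim$sequences, n_reps = 25, seed = 7)
#' @export
bootstrap_tree <- function(alignment, n_reps = 100, seed = NULL,
                           model = "JC") {
  if (!is.numeric(n_reps) || n_reps < 1) {
    stop("'n_reps' must be a positive integer", call. = FALSE)
  }
  aln <- as_alignment(alignment)
  tree <- nj_tree(jc_distance(aln, model = model))
  nint <- tree$Nnode
  chars <- alignment_chars(aln)
  variable <- any(apply(chars, 2, function(col) {
    b <- col[col %in% DNA_BASES]
    length(unique(b)) > 1L
  }))
  if (!variable) {
    tree$node.label <- rep(NA_real_, nint)
    attr(tree, "degenerate") <- TRUE
    warning("alignment has no variable sites; bootstrap supports undefined",
            call. = FALSE)
    return(tree)
  }
  if (!is.null(seed)) set.seed(seed)
  ncol_aln <- ncol(aln)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol_aln, replace = TRUE)
    reps[[b]] <- nj_tree(jc_distance(aln[, idx, drop = FALSE], model = model))
  }
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- counts / n_reps * 100
  support[1L] <- NA_real_  # basal node: trivial split
  tree$node.label <- support
  tree
}

#' Mean bootstrap value (MBV) of a tree
#'
#' Arithmetic mean of the bootstrap supports over all internal edges of the
#' tree, the single-number summary of overall tree resolution. Supports are
#' taken from `tree$node.label`; non-numeric and `NA` labels (e.g. the trivial
#' basal split of an unrooted tree) are excluded.
#'
#' @param tree a `phylo` tree with support node labels (e.g. from
#'   [bootstrap_tree()] or read from Newick).
#' @return mean support, a number in `[0, 100]`.
#' @export
mean_bootstrap_value <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) {
    stop("tree carries no support values", call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(tree$node.label))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) {
    stop("tree has no supported internal edges; MBV undefined", call. = FALSE)
  }
  mean(vals)
}

#' Comb-topology branch-length metrics
#'
#' Summarizes the signature of replacement radiations: long terminal branches
#' over very short internal branches. Computes mean terminal and mean internal
#' branch lengths, their ratio, and (when present) the mean of the internal
#' support values.
#'
#' @param tree a `phylo` tree with branch lengths.
#' @return an object of class `"comb_metrics"`: list with
#'   `mean_terminal`, `mean_internal`, `ratio` (terminal/internal; `Inf` when
#'   the internal mean is 0, `NaN` for a tree with no internal edges),
#'   `n_terminal`, `n_internal` and `mean_support` (or `NA`).
#' @export
tree_shape_metrics <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree carries no branch lengths", call. = FALSE)
  }
  term <- tree$edge[, 2] <= length(tree$tip.label)
  mt <- mean(tree$edge.length[term])
  mi <- if (any(!term)) mean(tree$edge.length[!term]) else NaN
  ratio <- if (is.nan(mi)) NaN else if (mi == 0) Inf else mt / mi
  ms <- NA_real_
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    if (any(is.finite(v))) ms <- mean(v[is.finite(v)])
  }
  structure(list(mean_terminal = mt, mean_internal = mi, ratio = ratio,
                 n_terminal = sum(term), n_internal = sum(!term),
                 mean_support = ms), class = "comb_metrics")
}

#' @export
print.comb_metrics <- function(x, ...) {
  cat("Tree shape metrics\n")
  cat(sprintf("  terminal branches: n = %d, mean length %.5f\n",
              x$n_terminal, x$mean_terminal))
  cat(sprintf("  internal branches: n = %d, mean length %.5f\n",
              x$n_internal, x$mean_internal))
  cat(sprintf("  terminal/internal ratio: %s\n", format(x$ratio, digits = 4)))
  if (is.finite(x$mean_support)) {
    cat(sprintf("  mean internal support: %.1f%%\n", x$mean_support))
  }
  invisible(x)
}

#' Bootstrap support of a given bipartition
#'
#' Looks up the support annotated on the internal edge separating `tips` from
#' the remaining taxa, e.g. the cospec1/cospec2 pair in the co-speciation
#' experiment.
#'
#' @param tree a supported `phylo` tree from [bootstrap_tree()].
#' @param tips character vector of tip labels on one side of the bipartition.
#' @return support percentage, or `NA` if the bipartition is not an edge of
#'   the tree.
#' @export
bipartition_support <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(tips %in% tree$tip.label)) {
    stop("unknown tip labels", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  target <- sort(match(tips, tree$tip.label))
  all_tips <- seq_len(ntip)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    clade <- sort(clade_tips(tree, node))
    if (identical(clade, target) ||
        identical(sort(setdiff(all_tips, clade)), target)) {
      lab <- tree$node.label[node - ntip]
      return(suppressWarnings(as.numeric(lab)))
    }
  }
  NA_real_
}

## tip indices descending from an internal node
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1L]
    todo <- todo[-1L]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= ntip])
    todo <- c(todo, kids[kids > ntip])
  }
  tips
}

#' Write a supported tree as Newick
#'
#' Supports are written as internal-node labels (the convention read by most
#' tree viewers); `NA` supports become empty labels.
#'
#' @param tree a `phylo` tree.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label
    lab <- ifelse(is.na(suppressWarnings(as.numeric(lab))), "",
                  format(suppressWarnings(as.numeric(lab)), trim = TRUE))
    tree$node.label <- lab
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}
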