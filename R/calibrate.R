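#' Summarize progenitor-descendant divergence of a simulation
#'
#' Mean and (population) variance of the JC-corrected distances between the
#' progenitor ("prog") and each descendant lineage; these two numbers are the
#' summary statistics that simulation parameters are calibrated against.
#'
#' @param result a `"replacement_sim"` object, or any named sequence set
#'   containing `"prog"` and at least one other sequence.
#' @param model `"JC"` (default) or `"p"` (raw p-distance).
#' @return an object of class `"divergence_summary"`: list with `mean`,
#'   `variance`, `n_pairs`, `distances`.
#' @export
summarize_divergence <- function(result, model = "JC") {
  seqs <- if (inherits(result, "replacement_sim")) result$sequences else unlist(result)
  if (!("prog" %in% names(seqs)) || length(seqs) < 2L) {
    stop("need a 'prog' sequence and at least one descendant", call. = FALSE)
  }
  dm <- jc_distance(seqs, model = model)
  d <- dm["prog", setdiff(rownames(dm), "prog")]
  structure(list(
    mean = mean(d),
    variance = mean((d - mean(d))^2),
    n_pairs = length(d),
    distances = d
  ), class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat(sprintf(
    "Divergence summary: mean %.5f, variance %.3g over %d prog-descendant pairs\n",
    x$mean, x$variance, x$n_pairs))
  invisible(x)
}

divergence_target <- function(mean, variance, n_pairs = 1L) {
  if (variance < 0) stop("variance must be non-negative", call. = FALSE)
  structure(list(mean = mean, variance = variance, n_pairs = n_pairs),
            class = "divergence_summary")
}

#' Calibration objective: distance between simulated and target divergence
#'
#' Runs `replicates` seeded simulations under `candidate`, averages their
#' divergence summaries, and returns the squared relative mismatch
#' `((mean - target$mean)/target$mean)^2 + ((var - target$variance)/target$variance)^2`
#' (a term whose target is zero uses the absolute instead of the relative
#' difference). Replicates where every progenitor-descendant pair is
#' JC-saturated are dropped; if all replicates saturate the objective is
#' `Inf` with attribute `"saturated"`.
#'
#' @param candidate a [sim_params()] object (its `seed` is overridden).
#' @param target a `"divergence_summary"` (observed mean/variance).
#' @param replicates number of simulation replicates per evaluation.
#' @param seed integer seed for the replicate seeds (common-random-numbers:
#'   calling with the same seed makes the objective deterministic in
#'   `candidate`).
#' @return non-negative number (possibly `Inf`).
#' @export
sim_objective <- function(candidate, target, replicates = 10, seed = 1L) {
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  means <- vars <- rep(NA_real_, replicates)
  for (r in seq_len(replicates)) {
    p <- candidate
    p$seed <- rep_seeds[r]
    s <- tryCatch(summarize_divergence(run_simulation(p)),
                  error = function(e) NULL)
    if (!is.null(s)) {
      means[r] <- s$mean
      vars[r] <- s$variance
    }
  }
  ok <- is.finite(means)
  if (!any(ok)) {
    return(structure(Inf, saturated = TRUE))
  }
  m <- mean(means[ok])
  v <- mean(vars[ok])
  term <- function(x, tgt) if (tgt == 0) abs(x - tgt) else ((x - tgt) / tgt)^2
  term(m, target$mean) + term(v, target$variance)
}

#' Calibrate simulation parameters to an observed divergence summary
#'
#' Stochastic hill-climbing over the free simulation parameters so that the
#' simulated progenitor-descendant divergence (mean and variance of
#' JC distances) matches an observed summary. Proposals are log-normal
#' multiplicative steps whose scale shrinks geometrically; a step is accepted
#' only if it lowers the objective, so the accepted trajectory is
#' non-increasing. The Monte Carlo objective is evaluated with common random
#' numbers, making the search deterministic given `seed`.
#'
#' With only two target statistics the progenitor and descendant rates are
#' confounded, so by default the ratio descendant/progenitor is fixed
#' (`fix_ratio = 8`) and the single free rate is the progenitor's; the Beta
#' birth-time shapes may be freed via `free`.
#'
#' @param target a `"divergence_summary"` or a list with `mean`, `variance`.
#' @param base_params [sim_params()] object giving everything not searched
#'   over (cycles, descendant count, sequence length, ...).
#' @param free character vector of parameters to optimize, subset of
#'   `c("progenitor_rate", "descendant_rate", "beta_alpha", "beta_beta")`.
#'   When `fix_ratio` is non-`NULL`, `descendant_rate` must not be free.
#' @param fix_ratio fixed descendant/progenitor rate ratio (default 8);
#'   `NULL` to decouple the rates.
#' @param bounds named list of `c(lower, upper)` bounds for each free
#'   parameter (defaults supplied).
#' @param iterations number of proposal steps.
#' @param proposal_scale initial standard deviation of the log-normal step.
#' @param cooling geometric decay factor of the proposal scale per iteration.
#' @param replicates simulation replicates per objective evaluation.
#' @param seed integer seed governing the whole search.
#' @return an object of class `"sim_calibration"`: list with `best_params`
#'   (a [sim_params()] object), `objective`, `trajectory` (data frame of
#'   accepted steps), `replicates`, `target`, and `converged` (`FALSE` with a
#'   warning when no proposal improved on the initial point).
#' @seealso [sim_objective()], [summarize_divergence()]
#' @examples
#' \donttest{
#' tgt <- list(mean = 0.03, variance = 1e-4)
#' fit <- calibrate_params(tgt, base_params = sim_params(n_cycles = 500,
#'                         n_descendants = 6, seq_length = 400),
#'                         iterations = 10, replicates = 3, seed = 1)
#' coef(fit)
#' }
#' @export
calibrate_params <- function(target,
                             base_params = sim_params(),
                             free = "progenitor_rate",
                             fix_ratio = 8,
                             bounds = NULL,
                             iterations = 40,
                             proposal_scale = 0.4,
                             cooling = 0.95,
                             replicates = 10,
                             seed = 1L) {
  if (!all(free %in% c("progenitor_rate", "descendant_rate",
                       "beta_alpha", "beta_beta"))) {
    stop("unknown free parameter", call. = FALSE)
  }
  if (length(free) == 0L) stop("need at least one free parameter", call. = FALSE)
  if (!is.null(fix_ratio) && "descendant_rate" %in% free) {
    stop("'descendant_rate' cannot be free when 'fix_ratio' is set",
         call. = FALSE)
  }
  if (is.null(fix_ratio) &&
      all(c("progenitor_rate", "descendant_rate") %in% free)) {
    warning(paste("progenitor and descendant rates are confounded by a",
                  "mean/variance target; consider fixing their ratio"),
            call. = FALSE)
  }
  default_bounds <- list(progenitor_rate = c(1e-5, 1),
                         descendant_rate = c(1e-5, 1),
                         beta_alpha = c(0.1, 20),
                         beta_beta = c(0.1, 20))
  bounds <- utils::modifyList(default_bounds, as.list(bounds %||% list()))
  target <- if (inherits(target, "divergence_summary")) target
            else divergence_target(target$mean, target$variance)

  apply_free <- function(params, theta) {
    for (nm in names(theta)) params[[nm]] <- theta[[nm]]
    if (!is.null(fix_ratio)) {
      params$descendant_rate <- fix_ratio * params$progenitor_rate
    }
    params
  }

  set.seed(seed)
  eval_seed <- sample.int(.Machine$integer.max - 1L, 1L)

  ## degenerate target: zero divergence is attained only at zero rates
  if (target$mean == 0 && target$variance == 0 &&
      setequal(intersect(free, c("progenitor_rate", "descendant_rate")), free)) {
    theta <- stats::setNames(vapply(free, function(nm) bounds[[nm]][1], 0), free)
  } else {
    theta <- stats::setNames(
      vapply(free, function(nm) sqrt(prod(bounds[[nm]])), 0), free)
  }
  cur_par <- apply_free(base_params, theta)
  cur_obj <- sim_objective(cur_par, target, replicates, seed = eval_seed)

  traj <- data.frame(iteration = 0L, objective = as.numeric(cur_obj),
                     t(unlist(theta)))
  scale <- proposal_scale
  improved <- FALSE
  for (it in seq_len(iterations)) {
    prop <- theta
    for (nm in free) {
      prop[[nm]] <- theta[[nm]] * exp(stats::rnorm(1L, 0, scale))
      prop[[nm]] <- min(max(prop[[nm]], bounds[[nm]][1]), bounds[[nm]][2])
    }
    cand <- apply_free(base_params, prop)
    obj <- sim_objective(cand, target, replicates, seed = eval_seed)
    if (is.finite(obj) && obj < cur_obj) {
      theta <- prop
      cur_par <- cand
      cur_obj <- obj
      improved <- TRUE
      traj <- rbind(traj, data.frame(iteration = it,
                                     objective = as.numeric(obj),
                                     t(unlist(theta))))
    }
    scale <- scale * cooling
  }
  if (!improved) {
    warning("no proposal improved on the initial point; returning the start",
            call. = FALSE)
  }
  structure(list(best_params = cur_par,
                 objective = as.numeric(cur_obj),
                 trajectory = traj,
                 replicates = replicates,
                 target = target,
                 free = free,
                 fix_ratio = fix_ratio,
                 converged = improved,
                 seed = seed), class = "sim_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_calibration <- function(x, ...) {
  cat("Calibrated replacement-simulation parameters\n")
  cat(sprintf("  target: mean %.5f, variance %.3g\n",
              x$target$mean, x$target$variance))
  cat(sprintf("  objective: %.4g after %d accepted steps (%d replicates/eval)\n",
              x$objective, nrow(x$trajectory) - 1L, x$replicates))
  print(coef(x))
  invisible(x)
}

#' @export
coef.sim_calibration <- function(object, ...) {
  p <- object$best_params
  out <- c(progenitor_rate = p$progenitor_rate,
           descendant_rate = p$descendant_rate,
           beta_alpha = p$beta_alpha,
           beta_beta = p$beta_beta)
  out
}

#' @export
plot.sim_calibration <- function(x, ...) {
  tr <- x$trajectory
  plot(tr$iteration, tr$objective, type = "s", xlab = "iteration",
       ylab = "objective (accepted)", log = if (all(tr$objective > 0)) "y" else "",
       main = "Calibration trajectory", ...)
  graphics::points(tr$iteration, tr$objective, pch = 16)
  invisible(x)
}
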