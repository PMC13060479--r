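# Multichain driver and the fitted-ensemble S3 class.

#' Generate a Pareto-optimal parameter ensemble
#'
#' The package's main fitting function. Runs \code{n_chains} independent
#' Pareto simulated-annealing chains (\code{\link{anneal_chain}}) from
#' diverse starting points, merges their archives, and performs a final full
#' re-rank on the combined set (\code{\link{merge_archives}}). No cutoff or
#' capacity pruning is applied after the merge: the value of the method is
#' the full cloud of near-optimal parameter sets, from which a rank-filtered
#' ensemble (default rank <= 1) is drawn for downstream analysis.
#'
#' Each chain owns an independent RNG stream seeded with
#' \code{seed + chain - 1}; chains are exchangeable, so results are
#' identical to serial execution regardless of scheduling, and a fixed seed
#' reproduces the result bit for bit.
#'
#' @param problem A \code{\link{poets_problem}}.
#' @param schedule A \code{\link{poets_schedule}}.
#' @param n_chains Number of independent chains (default 8).
#' @param starts Optional list of in-bounds, feasible starting vectors (one
#'   per chain); otherwise starts are drawn uniformly within the bounds.
#' @param seed Base integer seed.
#' @param rank_filter Ensemble selection rule recorded with the result:
#'   members with rank <= \code{rank_filter} form the working ensemble
#'   (default 1).
#' @param neighbor Proposal function (see \code{\link{gaussian_neighbor}}).
#' @param monitor Optional per-proposal callback (see
#'   \code{\link{anneal_chain}}).
#' @param trace_hv Record per-level rank-0 hypervolume in the traces against
#'   \code{problem$ref_point} (requires one).
#' @return An object of class \code{"poets"}: a list with the merged
#'   \code{archive}, per-chain \code{traces}, the \code{schedule},
#'   \code{problem}, \code{seed}, \code{starts}, per-chain status, total
#'   \code{n_evals} and \code{wall_time} (seconds).
#' @examples
#' \donttest{
#' fit <- poets(problem_binh_korn(),
#'              poets_schedule(Tmin = 0.05, n_iter = 20, n_max = 500),
#'              n_chains = 2, seed = 1)
#' print(fit)
#' }
#' @export
poets <- function(problem, schedule = poets_schedule(), n_chains = 8L,
                  starts = NULL, seed = 1L, rank_filter = 1L,
                  neighbor = gaussian_neighbor, monitor = NULL,
                  trace_hv = FALSE) {
  stopifnot(inherits(problem, "poets_problem"),
            inherits(schedule, "poets_schedule"))
  n_chains <- as.integer(n_chains)
  if (is.na(n_chains) || n_chains < 1L) {
    stop("n_chains must be >= 1", call. = FALSE)
  }
  if (!is.null(starts)) {
    if (!is.list(starts) || length(starts) != n_chains) {
      stop("starts must be a list with one vector per chain", call. = FALSE)
    }
  }
  hv_ref <- if (isTRUE(trace_hv)) {
    if (is.null(problem$ref_point)) {
      stop("trace_hv requires a problem ref_point", call. = FALSE)
    }
    problem$ref_point
  } else NULL

  t0 <- proc.time()[["elapsed"]]
  d <- length(problem$lower)
  chains <- vector("list", n_chains)
  errors <- rep(NA_character_, n_chains)
  used_starts <- vector("list", n_chains)
  for (i in seq_len(n_chains)) {
    set.seed(seed + i - 1L)
    x0 <- if (!is.null(starts)) as.numeric(starts[[i]]) else
      draw_feasible_start(problem, d)
    used_starts[[i]] <- x0
    chains[[i]] <- tryCatch(
      anneal_chain(problem, x0, schedule, neighbor = neighbor,
                   chain_id = i, monitor = monitor, hv_ref = hv_ref),
      error = function(e) {
        errors[i] <<- conditionMessage(e)
        NULL
      })
  }
  ok <- !vapply(chains, is.null, logical(1))
  if (!any(ok)) {
    stop("all chains failed; first error: ", errors[!ok][1L], call. = FALSE)
  }
  if (any(!ok)) {
    warning(sum(!ok), " chain(s) failed: ",
            paste(errors[!ok], collapse = "; "), call. = FALSE)
  }
  merged <- merge_archives(lapply(chains[ok], `[[`, "archive"))
  traces <- lapply(chains, function(ch) if (is.null(ch)) NULL else ch$trace)
  n_evals <- sum(vapply(chains[ok], `[[`, integer(1), "evals"))
  structure(list(archive = merged,
                 traces = traces,
                 schedule = schedule,
                 problem = problem,
                 n_chains = n_chains,
                 seed = as.integer(seed),
                 starts = used_starts,
                 chain_ok = ok,
                 chain_errors = errors,
                 rank_filter = as.integer(rank_filter),
                 n_evals = n_evals,
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "poets")
}

draw_feasible_start <- function(problem, d, max_tries = 10000L) {
  for (k in seq_len(max_tries)) {
    x <- problem$lower + runif(d) * (problem$upper - problem$lower)
    ok <- tryCatch(isTRUE(problem$feasible(x)), error = function(e) FALSE)
    if (ok) return(x)
  }
  stop("could not draw a feasible starting point within ", max_tries,
       " tries", call. = FALSE)
}

#' Rank-filtered ensemble parameter matrix
#'
#' @param object A fitted \code{\link{poets}} object.
#' @param rank_filter Maximum rank to include (default the object's recorded
#'   filter).
#' @return Numeric matrix, members x parameters, on the search scale.
#' @export
ensemble_parameters <- function(object, rank_filter = object$rank_filter) {
  stopifnot(inherits(object, "poets"))
  object$archive$params[object$archive$rank <= rank_filter, , drop = FALSE]
}

#' @export
print.poets <- function(x, ...) {
  a <- x$archive
  cat("Pareto-optimal ensemble (POETs)\n")
  cat("  problem: ", x$problem$name, " (", ncol(a$params), " parameter(s), ",
      ncol(a$objectives), " objective(s))\n", sep = "")
  cat("  chains: ", sum(x$chain_ok), "/", x$n_chains, " completed, seed ",
      x$seed, ", ", x$n_evals, " evaluations (",
      sprintf("%.1f", x$wall_time), " s)\n", sep = "")
  cat("  merged archive: ", archive_size(a), " record(s); Pareto front: ",
      sum(a$rank == 0L), "; ensemble (rank <= ", x$rank_filter, "): ",
      sum(a$rank <= x$rank_filter), "\n", sep = "")
  invisible(x)
}

#' @export
summary.poets <- function(object, rank_filter = object$rank_filter, ...) {
  a <- object$archive
  P <- ensemble_parameters(object, rank_filter)
  qs <- t(apply(P, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  colnames(qs) <- c("q2.5", "median", "q97.5")
  structure(list(problem = object$problem$name,
                 n_chains = object$n_chains,
                 n_evals = object$n_evals,
                 archive_size = archive_size(a),
                 front_size = sum(a$rank == 0L),
                 rank_filter = rank_filter,
                 ensemble_size = nrow(P),
                 rank_hist = rank_histogram(a),
                 param_quantiles = qs,
                 objective_range = apply(a$objectives, 2, range)),
            class = "summary.poets")
}

#' @export
print.summary.poets <- function(x, ...) {
  cat("POETs ensemble summary -- problem '", x$problem, "'\n", sep = "")
  cat("  archive ", x$archive_size, " record(s) from ", x$n_chains,
      " chain(s), ", x$n_evals, " evaluations\n", sep = "")
  cat("  Pareto front ", x$front_size, " record(s); ensemble (rank <= ",
      x$rank_filter, ") ", x$ensemble_size, " member(s)\n", sep = "")
  cat("  rank histogram:\n")
  print(x$rank_hist)
  cat("  ensemble parameter quantiles (search scale):\n")
  print(round(x$param_quantiles, 4))
  invisible(x)
}

#' Ensemble central parameter estimate
#'
#' The componentwise median of the rank-filtered ensemble on the search
#' scale: a robust single representative of the parameter cloud (the cloud
#' itself is available via \code{\link{ensemble_parameters}}).
#'
#' @param object A fitted \code{\link{poets}} object.
#' @param rank_filter Maximum rank to include.
#' @param ... Unused.
#' @return Named numeric vector of ensemble medians.
#' @export
coef.poets <- function(object, rank_filter = object$rank_filter, ...) {
  apply(ensemble_parameters(object, rank_filter), 2, median)
}

#' Ensemble prediction bands
#'
#' Propagates the rank-filtered ensemble through the problem's
#' \code{simulate} component and returns an empirical-quantile prediction
#' band per simulated observable. When the ensemble is larger than
#' \code{max_members}, an evenly spaced (deterministic) subset is simulated.
#'
#' @param object A fitted \code{\link{poets}} object whose problem defines
#'   \code{simulate}.
#' @param times Prediction time grid.
#' @param level Band level (default 0.95).
#' @param rank_filter Maximum rank to include.
#' @param max_members Cap on simulated members (default 500).
#' @param ... Unused.
#' @return A named list of \code{\link{prediction_band}} objects, one per
#'   observable, with attribute \code{"n_members"}.
#' @export
predict.poets <- function(object, times, level = 0.95,
                          rank_filter = object$rank_filter,
                          max_members = 500L, ...) {
  if (is.null(object$problem$simulate)) {
    stop("the fitted problem has no simulate component", call. = FALSE)
  }
  P <- ensemble_parameters(object, rank_filter)
  if (nrow(P) < 2L) {
    stop("ensemble has fewer than 2 members; increase rank_filter",
         call. = FALSE)
  }
  if (nrow(P) > max_members) {
    P <- P[unique(round(seq(1L, nrow(P), length.out = max_members))), ,
           drop = FALSE]
  }
  sims <- lapply(seq_len(nrow(P)), function(i) {
    object$problem$simulate(P[i, ], times)
  })
  obs_names <- colnames(sims[[1L]])
  if (is.null(obs_names)) obs_names <- paste0("y_", seq_len(ncol(sims[[1L]])))
  bands <- lapply(seq_along(obs_names), function(j) {
    traj <- do.call(rbind, lapply(sims, function(s) s[, j]))
    prediction_band(traj, times = times, level = level)
  })
  names(bands) <- obs_names
  attr(bands, "n_members") <- nrow(P)
  bands
}

#' Plot the objective-space archive
#'
#' Scatter of the first two objectives, with the Pareto front (rank 0)
#' highlighted.
#'
#' @param x A fitted \code{\link{poets}} object.
#' @param objectives Indices of the two objectives to show (default 1:2).
#' @param ... Passed to \code{plot}.
#' @export
plot.poets <- function(x, objectives = c(1L, 2L), ...) {
  F <- x$archive$objectives
  stopifnot(ncol(F) >= 2L)
  j <- objectives[1:2]
  on <- colnames(F)
  if (is.null(on)) on <- paste0("f_", seq_len(ncol(F)))
  front <- x$archive$rank == 0L
  plot(F[, j[1]], F[, j[2]], col = adjustcolor("grey50", 0.5), pch = 16,
       cex = 0.5, xlab = on[j[1]], ylab = on[j[2]], ...)
  points(F[front, j[1]], F[front, j[2]], col = "black", pch = 16, cex = 0.6)
  legend("topright", pch = 16, col = c("grey50", "black"),
         legend = c("archive", "Pareto front"), bty = "n")
  invisible(x)
}
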