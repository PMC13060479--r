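# Single-chain Pareto simulated annealing: geometric cooling, rank-energy
# Metropolis acceptance, pop-on-reject archive management.

#' Annealing schedule
#'
#' Bundles the simulated-annealing hyperparameters. Defaults follow the
#' settings used for the package's calibration studies: start temperature 1,
#' geometric cooling at rate 0.90, 50 candidates per level, rank cutoff 8,
#' capacity 5000, and a Gaussian neighbor step of 5% of each bound width.
#' The default stopping temperature of 1e-11 gives 241 temperature levels
#' (12,050 evaluations per chain), so a default 8-chain run spends roughly
#' 100,000 evaluations, matching the evaluation budgets of the validation
#' studies; temperatures below about 0.01 act as a quench phase in which only
#' non-worsening moves are accepted and the front is refined in place.
#'
#' @param T0 Initial temperature (> 0).
#' @param cooling_rate Geometric cooling factor, in (0, 1).
#' @param Tmin Stopping temperature (> 0, < \code{T0}); annealing stops once
#'   the temperature falls below it.
#' @param n_iter Candidate proposals per temperature level (>= 1).
#' @param rank_cutoff Archive rank cutoff (>= 1); see
#'   \code{\link{prune_by_cutoff}}.
#' @param n_max Archive capacity (>= 1); see \code{\link{enforce_capacity}}.
#' @param step_scale Neighbor standard deviation as a fraction of each
#'   parameter's bound width; scalar or per-dimension vector, >= 0.
#' @param max_evals Optional cap on objective evaluations per chain, for
#'   budget-matched runs (default unlimited).
#' @param acceptance Rank energy form: \code{"difference"} (default) accepts
#'   with probability min(1, exp(-(rank_cand - rank_inc)/T)), so any
#'   non-worsening move is certain; \code{"absolute"} uses exp(-rank_cand/T).
#' @return An object of class \code{"poets_schedule"}.
#' @export
poets_schedule <- function(T0 = 1, cooling_rate = 0.90, Tmin = 1e-11,
                           n_iter = 50L, rank_cutoff = 8L, n_max = 5000L,
                           step_scale = 0.05, max_evals = Inf,
                           acceptance = c("difference", "absolute")) {
  acceptance <- match.arg(acceptance)
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0) || T0 <= 0) {
    stop("T0 must be a positive number", call. = FALSE)
  }
  if (!is.numeric(cooling_rate) || length(cooling_rate) != 1L ||
      !is.finite(cooling_rate) || cooling_rate <= 0 || cooling_rate >= 1) {
    stop("cooling_rate must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(Tmin) || length(Tmin) != 1L || !is.finite(Tmin) ||
      Tmin <= 0 || Tmin >= T0) {
    stop("Tmin must satisfy 0 < Tmin < T0", call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  if (is.na(n_iter) || n_iter < 1L) stop("n_iter must be >= 1", call. = FALSE)
  rank_cutoff <- as.integer(rank_cutoff)
  if (is.na(rank_cutoff) || rank_cutoff < 1L) {
    stop("rank_cutoff must be >= 1", call. = FALSE)
  }
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("n_max must be >= 1", call. = FALSE)
  if (!is.numeric(step_scale) || any(!is.finite(step_scale)) ||
      any(step_scale < 0)) {
    stop("step_scale must be non-negative", call. = FALSE)
  }
  if (!(is.numeric(max_evals) && length(max_evals) == 1L &&
        (is.infinite(max_evals) || max_evals >= 1))) {
    stop("max_evals must be >= 1 (or Inf)", call. = FALSE)
  }
  structure(list(T0 = T0, cooling_rate = cooling_rate, Tmin = Tmin,
                 n_iter = n_iter, rank_cutoff = rank_cutoff, n_max = n_max,
                 step_scale = step_scale, max_evals = max_evals,
                 acceptance = acceptance),
            class = "poets_schedule")
}

#' @export
print.poets_schedule <- function(x, ...) {
  n_levels <- floor(log(x$Tmin / x$T0) / log(x$cooling_rate)) + 1L
  cat("Annealing schedule: T0 = ", x$T0, ", cooling_rate = ", x$cooling_rate,
      ", Tmin = ", x$Tmin, " (", n_levels, " levels)\n",
      "  n_iter = ", x$n_iter, "/level, rank_cutoff = ", x$rank_cutoff,
      ", n_max = ", x$n_max, ", acceptance = ", x$acceptance, "\n", sep = "")
  invisible(x)
}

#' Metropolis acceptance probability with rank energy
#'
#' The dominance-count rank plays the role of the energy: a candidate is
#' accepted with probability min(1, exp(-(rank_cand - rank_inc)/T)) (the
#' default difference form; improving or equal-rank moves are always
#' accepted), or exp(-rank_cand/T) under the absolute form.
#'
#' @param rank_candidate,rank_incumbent Non-negative dominance-count ranks,
#'   both read from the post-insertion rank state.
#' @param temperature Current temperature (> 0).
#' @param acceptance \code{"difference"} (default) or \code{"absolute"}.
#' @return Acceptance probability in [0, 1] (vectorized over ranks).
#' @examples
#' acceptance_probability(1, 0, 1)  # exp(-1)
#' acceptance_probability(0, 3, 1)  # 1
#' @export
acceptance_probability <- function(rank_candidate, rank_incumbent = 0,
                                   temperature,
                                   acceptance = c("difference", "absolute")) {
  acceptance <- match.arg(acceptance)
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive", call. = FALSE)
  }
  if (any(rank_candidate < 0) || any(rank_incumbent < 0)) {
    stop("ranks must be non-negative", call. = FALSE)
  }
  energy <- if (acceptance == "difference") {
    rank_candidate - rank_incumbent
  } else {
    rank_candidate
  }
  pmin(1, exp(-energy / temperature))
}

# Reflect values into [lower, upper] (period-2w fold), preserving in-bounds
# values exactly.
reflect_into_bounds <- function(x, lower, upper) {
  w <- upper - lower
  y <- (x - lower) %% (2 * w)
  out_high <- y > w
  y[out_high] <- 2 * w[out_high] - y[out_high]
  lower + y
}

#' Default Gaussian neighbor proposal
#'
#' Perturbs each component with independent Gaussian noise whose standard
#' deviation is \code{step_scale} times the bound width, then reflects the
#' result at the bounds so proposals always stay within
#' \code{[lower, upper]}. Any function with this signature that returns an
#' in-bounds vector can replace it in \code{\link{anneal_chain}} /
#' \code{\link{poets}}; proposals draw from R's global RNG stream.
#'
#' @param x Current parameter vector, within bounds.
#' @param lower,upper Bound vectors with \code{lower < upper} componentwise.
#' @param step_scale Scalar or per-dimension fraction of the bound width
#'   (default 0.05); 0 returns \code{x} unchanged.
#' @return An in-bounds proposal vector.
#' @export
gaussian_neighbor <- function(x, lower, upper, step_scale = 0.05) {
  if (any(upper <= lower)) stop("bounds require lower < upper", call. = FALSE)
  if (any(x < lower) || any(x > upper)) {
    stop("x must lie within the bounds", call. = FALSE)
  }
  sd <- rep_len(step_scale, length(x)) * (upper - lower)
  reflect_into_bounds(x + rnorm(length(x), 0, sd), lower, upper)
}

# Evaluate a candidate under a problem's feasibility predicate and objective
# map. Returns NULL (=> rejected move, no archive change) on infeasibility,
# evaluation error, wrong length, or non-finite objectives.
evaluate_candidate <- function(problem, x, m_expected = NULL) {
  feas <- tryCatch(isTRUE(problem$feasible(x)), error = function(e) FALSE)
  if (!feas) return(NULL)
  f <- tryCatch(as.numeric(problem$evaluate(x)), error = function(e) NULL)
  if (is.null(f) || anyNA(f) || !all(is.finite(f))) return(NULL)
  if (!is.null(m_expected) && length(f) != m_expected) return(NULL)
  f
}

#' Run one Pareto simulated-annealing chain
#'
#' The chain is seeded with the single evaluated solution \code{(x0, f(x0))}
#' at temperature \code{T0}. At each temperature level, \code{n_iter}
#' candidates are proposed from the incumbent (the most recently accepted
#' solution) via the neighbor function, inserted into the archive with an
#' incremental O(nm) rank update, and accepted with the rank-energy
#' Metropolis probability. On acceptance the archive is pruned at the rank
#' cutoff and capped at \code{n_max}; on rejection the candidate is popped
#' immediately and the rank state restored from the touched-index set
#' (pop-on-reject), so the archive never holds more than \code{n_max + 1}
#' records at any instant. Infeasible or failed evaluations consume a
#' proposal but never enter the archive. The temperature is then multiplied
#' by \code{cooling_rate} until it falls below \code{Tmin}.
#'
#' Uses R's global RNG stream; seed it (or use \code{\link{poets}}, which
#' derives one stream per chain) for reproducible runs.
#'
#' @param problem A \code{\link{poets_problem}}.
#' @param x0 Initial parameter vector, in-bounds and feasible; an evaluation
#'   failure at \code{x0} is a startup error.
#' @param schedule A \code{\link{poets_schedule}}.
#' @param neighbor Proposal function with the \code{\link{gaussian_neighbor}}
#'   signature.
#' @param chain_id Integer provenance tag stored with each record.
#' @param monitor Optional callback invoked after every proposal with a list
#'   (chain, level, temperature, evals, proposed, inserted, accepted,
#'   size_after_insert, archive = list(params, objectives, rank)); intended
#'   for instrumentation and tests.
#' @param hv_ref Optional reference point; when given, the per-level trace
#'   includes the rank-0 hypervolume.
#' @return A list with elements \code{archive} (a ranked
#'   \code{\link{poets_archive}}, max rank below the cutoff, size <=
#'   \code{n_max}), \code{trace} (one data.frame row per completed
#'   temperature level: level, temperature, archive size, rank-0 count,
#'   accepted count, cumulative evaluations, hypervolume), and \code{evals}.
#' @export
anneal_chain <- function(problem, x0, schedule = poets_schedule(),
                         neighbor = gaussian_neighbor, chain_id = 1L,
                         monitor = NULL, hv_ref = NULL) {
  stopifnot(inherits(problem, "poets_problem"),
            inherits(schedule, "poets_schedule"))
  x0 <- as.numeric(x0)
  lower <- problem$lower
  upper <- problem$upper
  if (length(x0) != length(lower)) {
    stop("x0 has wrong length for the problem", call. = FALSE)
  }
  if (any(x0 < lower) || any(x0 > upper)) {
    stop("x0 must lie within the problem bounds", call. = FALSE)
  }
  f0 <- evaluate_candidate(problem, x0)
  if (is.null(f0)) {
    stop("startup error: objective evaluation failed or infeasible at x0",
         call. = FALSE)
  }
  m <- length(f0)
  d <- length(x0)

  # Preallocated growable buffers; the live archive is the first n rows.
  cap <- 1024L
  P <- matrix(NA_real_, cap, d)
  Fm <- matrix(NA_real_, cap, m)
  rk <- integer(cap)
  insv <- integer(cap)
  n <- 1L
  P[1L, ] <- x0
  Fm[1L, ] <- f0
  rk[1L] <- 0L
  insv[1L] <- 1L
  ins_counter <- 1L

  grow <- function() {
    cap2 <- 2L * cap
    P2 <- matrix(NA_real_, cap2, d); P2[seq_len(n), ] <- P[seq_len(n), ]
    F2 <- matrix(NA_real_, cap2, m); F2[seq_len(n), ] <- Fm[seq_len(n), ]
    rk2 <- integer(cap2); rk2[seq_len(n)] <- rk[seq_len(n)]
    iv2 <- integer(cap2); iv2[seq_len(n)] <- insv[seq_len(n)]
    P <<- P2; Fm <<- F2; rk <<- rk2; insv <<- iv2; cap <<- cap2
  }

  compact <- function(keep) {
    k <- length(keep)
    P[seq_len(k), ] <<- P[keep, , drop = FALSE]
    Fm[seq_len(k), ] <<- Fm[keep, , drop = FALSE]
    rk[seq_len(k)] <<- rk[keep]
    insv[seq_len(k)] <<- insv[keep]
    n <<- k
  }

  snapshot <- function() {
    idx <- seq_len(n)
    list(params = P[idx, , drop = FALSE],
         objectives = Fm[idx, , drop = FALSE],
         rank = rk[idx])
  }

  inc_x <- x0
  inc_f <- f0
  inc_idx <- 1L   # incumbent's row in the archive; NA if pruned out

  temp <- schedule$T0
  evals <- 1L
  level <- 0L
  trace <- list()
  step_scale <- schedule$step_scale

  while (temp >= schedule$Tmin && evals < schedule$max_evals) {
    level <- level + 1L
    accepted_this_level <- 0L
    for (it in seq_len(schedule$n_iter)) {
      if (evals >= schedule$max_evals) break
      xc <- neighbor(inc_x, lower, upper, step_scale)
      fc <- evaluate_candidate(problem, xc, m_expected = m)
      evals <- evals + 1L
      if (is.null(fc)) {
        # infeasible or failed evaluation: rejection without archive change
        if (!is.null(monitor)) {
          monitor(list(chain = chain_id, level = level, temperature = temp,
                       evals = evals, proposed = xc, inserted = FALSE,
                       accepted = FALSE, size_after_insert = n,
                       archive = snapshot()))
        }
        next
      }
      if (n + 1L > cap) grow()
      scan <- cpp_insert_scan(Fm, n, fc)
      touched <- scan$touched
      cand_rank <- scan$candidate_rank
      if (length(touched)) rk[touched] <- rk[touched] + 1L
      n <- n + 1L
      P[n, ] <- xc
      Fm[n, ] <- fc
      rk[n] <- cand_rank
      ins_counter <- ins_counter + 1L
      insv[n] <- ins_counter
      size_after_insert <- n

      inc_rank <- if (!is.na(inc_idx)) rk[inc_idx] else
        cpp_count_dominators(Fm, n, inc_f)
      p_acc <- acceptance_probability(cand_rank, inc_rank, temp,
                                      schedule$acceptance)
      accept <- runif(1) < p_acc

      if (accept) {
        accepted_this_level <- accepted_this_level + 1L
        inc_x <- xc
        inc_f <- fc
        inc_idx <- n
        # prune at the rank cutoff; survivor ranks are unchanged under strict
        # dominance (every dominator of a survivor has strictly lower rank
        # and therefore also survives), so they are carried over
        keep <- prune_keep_idx(rk[seq_len(n)], schedule$rank_cutoff)
        if (length(keep) < n) {
          inc_idx <- match(inc_idx, keep)
          compact(keep)
        }
        # capacity cap: same carried-rank argument applies
        if (n > schedule$n_max) {
          keep <- capacity_keep_idx(rk[seq_len(n)], insv[seq_len(n)],
                                    schedule$n_max)
          inc_idx <- match(inc_idx, keep)
          compact(keep)
        }
      } else {
        # pop-on-reject: drop the candidate row and restore the rank state
        if (length(touched)) rk[touched] <- rk[touched] - 1L
        n <- n - 1L
        ins_counter <- ins_counter - 1L
      }

      if (!is.null(monitor)) {
        monitor(list(chain = chain_id, level = level, temperature = temp,
                     evals = evals, proposed = xc, inserted = TRUE,
                     accepted = accept, size_after_insert = size_after_insert,
                     archive = snapshot()))
      }
    }
    idx <- seq_len(n)
    hv <- if (is.null(hv_ref)) NA_real_ else
      hypervolume(Fm[idx, , drop = FALSE][rk[idx] == 0L, , drop = FALSE],
                  hv_ref)
    trace[[level]] <- data.frame(level = level, temperature = temp,
                                 archive_size = n,
                                 rank0_count = sum(rk[idx] == 0L),
                                 accepted = accepted_this_level,
                                 evaluations = evals,
                                 hypervolume = hv)
    temp <- temp * schedule$cooling_rate
  }

  idx <- seq_len(n)
  archive <- poets_archive(P[idx, , drop = FALSE], Fm[idx, , drop = FALSE],
                           n_max = schedule$n_max,
                           rank_cutoff = schedule$rank_cutoff,
                           chain_id = chain_id,
                           insertion = insv[idx],
                           rank = rk[idx])
  colnames(archive$params) <- problem$par_names
  colnames(archive$objectives) <- problem$obj_names
  list(archive = archive,
       trace = do.call(rbind, trace),
       evals = evals)
}
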