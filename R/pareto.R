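# Strict Pareto dominance, dominance-count ranking, and archive maintenance.
# Minimization convention throughout: lower objective values are preferred;
# maximization objectives must be negated by the caller.

#' Strict Pareto dominance test
#'
#' Tests whether objective vector \code{fj} strictly dominates \code{fi}:
#' \code{fj} is no worse in every objective and strictly better in at least
#' one. Identical vectors do not dominate each other (strict dominance), which
#' is what keeps duplicated solutions at rank 0 in an archive. The scan exits
#' early at the first objective where \code{fj} is worse than \code{fi}.
#'
#' @param fj,fi Numeric vectors of equal length, all entries finite. Lower
#'   values are preferred.
#' @return A single logical.
#' @examples
#' strictly_dominates(c(1, 1), c(2, 2))  # TRUE
#' strictly_dominates(c(1, 2), c(1, 2))  # FALSE: identical
#' strictly_dominates(c(1, 3), c(2, 2))  # FALSE: incomparable
#' @export
strictly_dominates <- function(fj, fi) {
  if (length(fj) != length(fi)) {
    stop("objective vectors differ in length (", length(fj), " vs ",
         length(fi), ")", call. = FALSE)
  }
  if (!all(is.finite(fj)) || !all(is.finite(fi))) {
    stop("objective vectors must be finite", call. = FALSE)
  }
  cpp_strictly_dominates(as.numeric(fj), as.numeric(fi))
}

as_objective_matrix <- function(objectives) {
  if (inherits(objectives, "poets_archive")) objectives <- objectives$objectives
  F <- as.matrix(objectives)
  storage.mode(F) <- "double"
  if (nrow(F) > 0 && !all(is.finite(F))) {
    stop("objective matrix contains non-finite values", call. = FALSE)
  }
  F
}

#' Dominance-count Pareto ranks
#'
#' The rank of a solution is the number of archive members that strictly
#' dominate it; rank-0 solutions form the Pareto front. Computed by an
#' O(n^2 m) pairwise scan with early exit; the result is independent of record
#' order. \code{weak = TRUE} switches to weak dominance (only \code{<=}
#' required), a deliberately retained diagnostic mode under which duplicated
#' solutions dominate each other and inflate each other's ranks.
#'
#' @param objectives A numeric matrix (rows = solutions, columns = objectives)
#'   or a \code{\link{poets_archive}}.
#' @param weak Use weak dominance (diagnostic mode). Default \code{FALSE}.
#' @return Integer vector of ranks, one per row (empty for an empty archive).
#' @examples
#' pareto_ranks(rbind(c(1, 1), c(2, 2), c(3, 0)))  # 0 1 0
#' @export
pareto_ranks <- function(objectives, weak = FALSE) {
  F <- as_objective_matrix(objectives)
  if (nrow(F) == 0L) return(integer(0))
  cpp_rank_all(F, weak)
}

#' Incremental rank update for one candidate
#'
#' Updates dominance-count ranks for a candidate appended to an archive with
#' known ranks, using a single O(nm) pass that tests dominance in both
#' directions: each existing rank is incremented iff the candidate strictly
#' dominates that record, and the candidate's rank is the number of existing
#' records that strictly dominate it. The returned \code{touched} index set
#' (the incremented records) allows an O(k) revert via
#' \code{\link{rank_revert}} when the candidate is rejected.
#'
#' Incoming ranks are trusted, not re-checked (caller contract).
#'
#' @param objectives Objective matrix or \code{\link{poets_archive}} of the
#'   existing records.
#' @param ranks Integer vector of their current ranks, consistent with
#'   \code{\link{pareto_ranks}}.
#' @param candidate Numeric objective vector of the candidate.
#' @return A list with \code{ranks} (updated ranks of the existing records),
#'   \code{candidate_rank}, and \code{touched} (1-based indices whose ranks
#'   were incremented).
#' @examples
#' rank_insert(rbind(c(1, 1), c(2, 2)), c(0L, 1L), c(0, 0))
#' @export
rank_insert <- function(objectives, ranks, candidate) {
  F <- as_objective_matrix(objectives)
  candidate <- as.numeric(candidate)
  if (nrow(F) > 0 && length(candidate) != ncol(F)) {
    stop("candidate objective dimension (", length(candidate),
         ") does not match archive (", ncol(F), ")", call. = FALSE)
  }
  if (!all(is.finite(candidate))) {
    stop("candidate objectives must be finite", call. = FALSE)
  }
  if (length(ranks) != nrow(F)) {
    stop("ranks length does not match archive size", call. = FALSE)
  }
  scan <- cpp_insert_scan(F, nrow(F), candidate)
  ranks <- as.integer(ranks)
  if (length(scan$touched)) {
    ranks[scan$touched] <- ranks[scan$touched] + 1L
  }
  list(ranks = ranks, candidate_rank = scan$candidate_rank,
       touched = as.integer(scan$touched))
}

#' Revert an incremental rank update
#'
#' Decrements the ranks at the touched indices returned by
#' \code{\link{rank_insert}}, restoring the pre-insertion rank vector exactly
#' (the pop-on-reject restore step).
#'
#' @param ranks Integer rank vector after the insertion (excluding the
#'   candidate's own rank).
#' @param touched Indices incremented by the insertion.
#' @return The restored integer rank vector.
#' @export
rank_revert <- function(ranks, touched) {
  ranks <- as.integer(ranks)
  if (length(touched)) ranks[touched] <- ranks[touched] - 1L
  ranks
}

#' Construct a Pareto archive
#'
#' An archive is the algorithm's central object: an ordered collection of
#' parameter vectors with their evaluated objective vectors and current
#' dominance-count ranks, plus the capacity \code{n_max} and rank cutoff
#' \code{rank_cutoff} used by \code{\link{prune_by_cutoff}} and
#' \code{\link{enforce_capacity}}.
#'
#' @param params Numeric matrix of parameter vectors (rows = records).
#' @param objectives Numeric matrix of objective vectors (rows = records,
#'   finite, lower is better).
#' @param n_max Capacity cap (positive integer).
#' @param rank_cutoff Rank cutoff (positive integer); records whose rank
#'   reaches it are pruned.
#' @param chain_id Integer chain provenance per record (recycled).
#' @param insertion Integer insertion indices per record (default sequential);
#'   used for the capacity tie-break.
#' @param rank Optional precomputed ranks; computed with
#'   \code{\link{pareto_ranks}} when \code{NULL}.
#' @return An object of class \code{"poets_archive"}.
#' @export
poets_archive <- function(params, objectives, n_max = 5000L, rank_cutoff = 8L,
                          chain_id = 1L, insertion = NULL, rank = NULL) {
  params <- as.matrix(params)
  storage.mode(params) <- "double"
  F <- as_objective_matrix(objectives)
  n <- nrow(F)
  if (nrow(params) != n) {
    stop("params and objectives must have the same number of rows",
         call. = FALSE)
  }
  n_max <- as.integer(n_max)
  rank_cutoff <- as.integer(rank_cutoff)
  if (is.na(n_max) || n_max < 1L) stop("n_max must be >= 1", call. = FALSE)
  if (is.na(rank_cutoff) || rank_cutoff < 1L) {
    stop("rank_cutoff must be >= 1", call. = FALSE)
  }
  if (is.null(insertion)) insertion <- seq_len(n)
  if (is.null(rank)) rank <- pareto_ranks(F)
  rownames(params) <- NULL
  rownames(F) <- NULL
  structure(list(params = params,
                 objectives = F,
                 rank = as.integer(rank),
                 chain_id = rep_len(as.integer(chain_id), n),
                 insertion = as.integer(insertion),
                 n_max = n_max,
                 rank_cutoff = rank_cutoff),
            class = "poets_archive")
}

archive_size <- function(archive) nrow(archive$objectives)

archive_subset <- function(archive, idx, rerank = TRUE) {
  out <- archive
  out$params <- archive$params[idx, , drop = FALSE]
  out$objectives <- archive$objectives[idx, , drop = FALSE]
  out$chain_id <- archive$chain_id[idx]
  out$insertion <- archive$insertion[idx]
  out$rank <- if (rerank) pareto_ranks(out$objectives) else archive$rank[idx]
  out
}

#' @export
print.poets_archive <- function(x, ...) {
  n <- archive_size(x)
  cat("Pareto archive: ", n, " record(s), ",
      ncol(x$objectives), " objective(s), ",
      ncol(x$params), " parameter(s)\n", sep = "")
  if (n > 0) {
    cat("  rank 0 (front): ", sum(x$rank == 0L), " record(s); max rank ",
        max(x$rank), "\n", sep = "")
  }
  cat("  n_max = ", x$n_max, ", rank_cutoff = ", x$rank_cutoff, "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.poets_archive <- function(x, ...) {
  d <- ncol(x$params)
  m <- ncol(x$objectives)
  pn <- colnames(x$params)
  if (is.null(pn)) pn <- paste0("p_", seq_len(d))
  on <- colnames(x$objectives)
  if (is.null(on)) on <- paste0("f_", seq_len(m))
  out <- data.frame(chain_id = x$chain_id,
                    insertion_index = x$insertion,
                    rank = x$rank)
  for (j in seq_len(d)) out[[pn[j]]] <- x$params[, j]
  for (j in seq_len(m)) out[[on[j]]] <- x$objectives[, j]
  out
}

# Indices surviving the rank cutoff. A rank-0 record always exists, so the
# result is never empty for a non-empty archive.
prune_keep_idx <- function(rank, rank_cutoff) which(rank < rank_cutoff)

# Indices surviving the capacity cap: the n_max lowest-rank records, ties at
# equal rank broken in favour of the most recently inserted. Survivors keep
# their original archive order.
capacity_keep_idx <- function(rank, insertion, n_max) {
  ord <- order(rank, -insertion)
  sort(ord[seq_len(n_max)])
}

#' Remove records at or above the rank cutoff
#'
#' Drops every record whose rank meets or exceeds the archive's
#' \code{rank_cutoff} and re-ranks the survivors from scratch with
#' \code{\link{pareto_ranks}}. At least one record always survives, since a
#' rank-0 record exists in any non-empty archive.
#'
#' @param archive A ranked \code{\link{poets_archive}}.
#' @return The pruned, re-ranked archive.
#' @export
prune_by_cutoff <- function(archive) {
  stopifnot(inherits(archive, "poets_archive"))
  keep <- prune_keep_idx(archive$rank, archive$rank_cutoff)
  if (length(keep) == archive_size(archive)) {
    archive$rank <- pareto_ranks(archive$objectives)  # no-op re-rank
    return(archive)
  }
  archive_subset(archive, keep, rerank = TRUE)
}

#' Enforce the archive capacity cap
#'
#' If the archive exceeds its capacity \code{n_max}, only the \code{n_max}
#' lowest-rank records are retained (ties at equal rank keep the most recently
#' inserted record) and the survivors are re-ranked from scratch. Otherwise
#' the archive is returned unchanged.
#'
#' @param archive A ranked \code{\link{poets_archive}}.
#' @return The capped archive.
#' @export
enforce_capacity <- function(archive) {
  stopifnot(inherits(archive, "poets_archive"))
  if (archive$n_max < 1L) stop("n_max must be >= 1", call. = FALSE)
  if (archive_size(archive) <= archive$n_max) return(archive)
  keep <- capacity_keep_idx(archive$rank, archive$insertion, archive$n_max)
  archive_subset(archive, keep, rerank = TRUE)
}

#' Rank histogram of an archive
#'
#' Counts records per dominance rank; a compact density summary of the
#' solution cloud around the front.
#'
#' @param archive A ranked \code{\link{poets_archive}} or an integer rank
#'   vector.
#' @return Named integer vector mapping rank to count; the \code{"0"} key is
#'   always present for a non-empty archive.
#' @export
rank_histogram <- function(archive) {
  rank <- if (inherits(archive, "poets_archive")) archive$rank else
    as.integer(archive)
  if (length(rank) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(factor(rank, levels = sort(unique(c(0L, rank)))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Merge archives from independent chains
#'
#' Concatenates the archives (chain provenance preserved, duplicates across
#' chains retained — under strict dominance duplicates do not dominate each
#' other) and performs a full re-rank of the combined set. No cutoff or
#' capacity pruning is applied at merge: the full solution cloud is retained.
#'
#' @param archives A list of \code{\link{poets_archive}} objects with
#'   identical objective dimension.
#' @return A single re-ranked \code{\link{poets_archive}}.
#' @export
merge_archives <- function(archives) {
  if (inherits(archives, "poets_archive")) archives <- list(archives)
  stopifnot(length(archives) >= 1L,
            all(vapply(archives, inherits, logical(1), "poets_archive")))
  m <- vapply(archives, function(a) ncol(a$objectives), integer(1))
  if (length(unique(m)) != 1L) {
    stop("archives have differing objective dimensions", call. = FALSE)
  }
  d <- vapply(archives, function(a) ncol(a$params), integer(1))
  if (length(unique(d)) != 1L) {
    stop("archives have differing parameter dimensions", call. = FALSE)
  }
  params <- do.call(rbind, lapply(archives, `[[`, "params"))
  F <- do.call(rbind, lapply(archives, `[[`, "objectives"))
  poets_archive(params, F,
                n_max = archives[[1L]]$n_max,
                rank_cutoff = archives[[1L]]$rank_cutoff,
                chain_id = unlist(lapply(archives, `[[`, "chain_id")),
                insertion = unlist(lapply(archives, `[[`, "insertion")),
                rank = NULL)
}
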