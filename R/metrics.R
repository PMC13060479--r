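# Front quality indicators: hypervolume and inverted generational distance.

# 2-D hypervolume by sort-and-sweep; all points assumed <= ref componentwise.
hv_2d <- function(F, ref) {
  o <- order(F[, 1], F[, 2])
  F <- F[o, , drop = FALSE]
  hv <- 0
  best2 <- ref[2]
  for (i in seq_len(nrow(F))) {
    f2 <- F[i, 2]
    if (f2 < best2) {
      hv <- hv + (ref[1] - F[i, 1]) * (best2 - f2)
      best2 <- f2
    }
  }
  as.numeric(hv)
}

# 3-D hypervolume by slicing along the third objective: the volume is the
# integral over f3 of the 2-D hypervolume of the points already introduced.
hv_3d <- function(F, ref) {
  o <- order(F[, 3])
  F <- F[o, , drop = FALSE]
  n <- nrow(F)
  hv <- 0
  for (i in seq_len(n)) {
    z_next <- if (i < n) F[i + 1L, 3] else ref[3]
    depth <- z_next - F[i, 3]
    if (depth > 0) {
      hv <- hv + depth * hv_2d(F[seq_len(i), 1:2, drop = FALSE], ref[1:2])
    }
  }
  hv
}

# Monte Carlo hypervolume for m > 3: fraction of uniform samples in
# [min corner, ref] dominated by some front point, times the box volume.
hv_mc <- function(F, ref, n_samples) {
  m <- ncol(F)
  lo <- apply(F, 2, min)
  vol_box <- prod(ref - lo)
  if (vol_box <= 0) return(0)
  S <- matrix(runif(n_samples * m), n_samples, m)
  S <- sweep(sweep(S, 2, ref - lo, "*"), 2, lo, "+")
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(F))) {
    todo <- which(!dominated)
    if (!length(todo)) break
    hit <- rep(TRUE, length(todo))
    for (k in seq_len(m)) hit <- hit & (F[i, k] <= S[todo, k])
    dominated[todo[hit]] <- TRUE
  }
  mean(dominated) * vol_box
}

#' Hypervolume of a front
#'
#' Lebesgue measure of the region of objective space dominated by the front
#' and bounded above by the reference point: the volume covered by the union
#' of boxes [point, ref_point]. Larger is better. Exact sort-and-sweep for
#' two objectives and recursive slicing for three; Monte Carlo fallback for
#' higher dimensions. Points not dominated by the reference point (i.e. with
#' some objective beyond it) contribute nothing and are clipped out with a
#' warning.
#'
#' @param front Numeric objective matrix (rows = points) or a
#'   \code{\link{poets_archive}} (its rank-0 records are used).
#' @param ref_point Finite numeric reference point, one value per objective.
#' @param n_samples Monte Carlo sample count for m > 3.
#' @return A non-negative scalar; 0 for an empty front.
#' @examples
#' hypervolume(rbind(c(0, 0)), c(1, 1))            # 1
#' hypervolume(rbind(c(0, 1), c(1, 0)), c(2, 2))   # 3
#' @export
hypervolume <- function(front, ref_point, n_samples = 100000L) {
  if (inherits(front, "poets_archive")) {
    front <- front$objectives[front$rank == 0L, , drop = FALSE]
  }
  F <- as.matrix(front)
  storage.mode(F) <- "double"
  ref_point <- as.numeric(ref_point)
  if (any(!is.finite(ref_point))) {
    stop("ref_point must be finite", call. = FALSE)
  }
  if (nrow(F) == 0L) return(0)
  if (ncol(F) != length(ref_point)) {
    stop("ref_point dimension does not match the front", call. = FALSE)
  }
  inside <- rowSums(sweep(F, 2, ref_point, "<=")) == ncol(F)
  if (!all(inside)) {
    warning(sum(!inside), " front point(s) beyond the reference point were ",
            "clipped out", call. = FALSE)
    F <- F[inside, , drop = FALSE]
    if (nrow(F) == 0L) return(0)
  }
  m <- ncol(F)
  out <- if (m == 1L) ref_point[1] - min(F[, 1])
  else if (m == 2L) hv_2d(F, ref_point)
  else if (m == 3L) hv_3d(F, ref_point)
  else hv_mc(F, ref_point, n_samples)
  unname(as.numeric(out))
}

#' Inverted generational distance
#'
#' Mean, over the reference-front points, of the Euclidean distance to the
#' nearest point of the computed front. Lower indicates a closer
#' approximation of the true front; 0 iff every reference point coincides
#' with a front point. Distances are taken on the raw objective scale by
#' default; \code{normalize = TRUE} rescales both fronts by the reference
#' front's per-objective range first.
#'
#' @param front Computed front: objective matrix or
#'   \code{\link{poets_archive}} (rank-0 records used). Must be non-empty.
#' @param reference Reference (true/dense) front matrix, mutually
#'   non-dominated, same number of objectives.
#' @param normalize Rescale objectives by the reference ranges.
#' @return A non-negative scalar.
#' @export
igd <- function(front, reference, normalize = FALSE) {
  if (inherits(front, "poets_archive")) {
    front <- front$objectives[front$rank == 0L, , drop = FALSE]
  }
  F <- as.matrix(front); storage.mode(F) <- "double"
  R <- as.matrix(reference); storage.mode(R) <- "double"
  if (nrow(F) == 0L) stop("front is empty", call. = FALSE)
  if (nrow(R) == 0L) stop("reference front is empty", call. = FALSE)
  if (ncol(F) != ncol(R)) {
    stop("front and reference have differing objective dimensions",
         call. = FALSE)
  }
  if (normalize) {
    rng <- apply(R, 2, function(v) diff(range(v)))
    rng[rng == 0] <- 1
    F <- sweep(F, 2, rng, "/")
    R <- sweep(R, 2, rng, "/")
  }
  # squared cross-distances via the expansion |r - f|^2 = |r|^2 + |f|^2 - 2 r.f
  d2 <- outer(rowSums(R^2), rowSums(F^2), "+") - 2 * tcrossprod(R, F)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}
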