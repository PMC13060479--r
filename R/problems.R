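# Problem definitions: the objective bundle the annealer consumes, plus the
# built-in analytic benchmarks.

#' Define an optimization problem
#'
#' A problem bundles the vector objective map (minimization convention), box
#' bounds, an optional feasibility predicate (constraint handling is by
#' rejection, keeping dominance-count ranks meaningful), and labelling
#' metadata. For models searched in log space, set \code{scale = "log10"}:
#' \code{evaluate} then receives log10-space vectors and must exponentiate
#' internally.
#'
#' @param name Problem name.
#' @param evaluate Function mapping a parameter vector to a numeric objective
#'   vector (lower is better). Errors or non-finite values are converted to
#'   rejected moves by the annealer.
#' @param lower,upper Numeric bound vectors, \code{lower < upper}.
#' @param feasible Optional predicate returning \code{TRUE} for feasible
#'   vectors (default: always feasible).
#' @param par_names,obj_names Optional names for parameters and objectives.
#' @param scale \code{"linear"} or \code{"log10"} (the scale the search and
#'   downstream correlation analyses operate on).
#' @param simulate Optional function \code{(x, times)} returning a matrix of
#'   model trajectories (columns = observables); enables
#'   \code{\link{predict.poets}}.
#' @param ref_point Optional default hypervolume reference point.
#' @return An object of class \code{"poets_problem"}.
#' @export
poets_problem <- function(name, evaluate, lower, upper, feasible = NULL,
                          par_names = NULL, obj_names = NULL,
                          scale = c("linear", "log10"), simulate = NULL,
                          ref_point = NULL) {
  scale <- match.arg(scale)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(!is.finite(c(lower, upper))) ||
      any(upper <= lower)) {
    stop("bounds must be finite with lower < upper componentwise",
         call. = FALSE)
  }
  if (is.null(feasible)) feasible <- function(x) TRUE
  if (is.null(par_names)) par_names <- paste0("p_", seq_along(lower))
  structure(list(name = name, evaluate = evaluate, lower = lower,
                 upper = upper, feasible = feasible, par_names = par_names,
                 obj_names = obj_names, scale = scale, simulate = simulate,
                 ref_point = ref_point),
            class = "poets_problem")
}

#' @export
print.poets_problem <- function(x, ...) {
  cat("Problem '", x$name, "': ", length(x$lower), " parameter(s)",
      if (!is.null(x$obj_names)) paste0(", objectives: ",
                                        paste(x$obj_names, collapse = ", ")),
      " [", x$scale, " scale]\n", sep = "")
  invisible(x)
}

#' Binh-Korn benchmark objectives
#'
#' The constrained two-objective Binh-Korn benchmark:
#' f1 = 4x^2 + 4y^2, f2 = (x-5)^2 + (y-5)^2, subject to
#' (x-5)^2 + y^2 <= 25 and (x-8)^2 + (y+3)^2 >= 7.7, with x in [0,5],
#' y in [0,3].
#'
#' @param x A length-2 numeric vector.
#' @return A list with \code{objectives} (length-2 vector) and
#'   \code{feasible} (logical).
#' @examples
#' binh_korn(c(0, 0))  # f = (0, 50), feasible
#' @export
binh_korn <- function(x) {
  f1 <- 4 * x[1]^2 + 4 * x[2]^2
  f2 <- (x[1] - 5)^2 + (x[2] - 5)^2
  g1 <- (x[1] - 5)^2 + x[2]^2 <= 25
  g2 <- (x[1] - 8)^2 + (x[2] + 3)^2 >= 7.7
  list(objectives = c(f1 = f1, f2 = f2), feasible = g1 && g2)
}

#' @rdname binh_korn
#' @export
problem_binh_korn <- function() {
  poets_problem(
    name = "binh_korn",
    evaluate = function(x) binh_korn(x)$objectives,
    lower = c(0, 0), upper = c(5, 3),
    feasible = function(x) binh_korn(x)$feasible,
    par_names = c("x", "y"), obj_names = c("f1", "f2"),
    ref_point = c(140, 50))
}

#' Dense Binh-Korn Pareto front
#'
#' The Pareto-optimal set lies along x = y for x in [0, 3] and along y = 3
#' for x in [3, 5]; this returns the corresponding objective-space front,
#' densely sampled and mutually non-dominated.
#'
#' @param n Number of front points.
#' @return An n x 2 objective matrix, ordered by increasing f1.
#' @export
binh_korn_front <- function(n = 10000L) {
  n1 <- ceiling(n * 0.6)
  t1 <- seq(0, 3, length.out = n1)
  t2 <- seq(3, 5, length.out = n - n1 + 1L)[-1L]
  F1 <- cbind(8 * t1^2, 2 * (t1 - 5)^2)
  F2 <- cbind(4 * t2^2 + 36, (t2 - 5)^2 + 4)
  out <- rbind(F1, F2)
  colnames(out) <- c("f1", "f2")
  out
}

#' Fonseca-Fleming benchmark objectives
#'
#' The unconstrained two-objective Fonseca-Fleming benchmark in three
#' dimensions: f1 = 1 - exp(-sum (x_k - 1/sqrt(3))^2),
#' f2 = 1 - exp(-sum (x_k + 1/sqrt(3))^2), x_k in [-4, 4].
#'
#' @param x A length-3 numeric vector.
#' @return A length-2 objective vector with values in [0, 1).
#' @export
fonseca_fleming <- function(x) {
  a <- 1 / sqrt(3)
  c(f1 = 1 - exp(-sum((x - a)^2)),
    f2 = 1 - exp(-sum((x + a)^2)))
}

#' @rdname fonseca_fleming
#' @export
problem_fonseca_fleming <- function() {
  poets_problem(
    name = "fonseca_fleming",
    evaluate = fonseca_fleming,
    lower = rep(-4, 3), upper = rep(4, 3),
    par_names = c("x1", "x2", "x3"), obj_names = c("f1", "f2"),
    ref_point = c(1, 1))
}

#' Analytic Fonseca-Fleming Pareto front
#'
#' The Pareto set is x1 = x2 = x3 = t for t in [-1/sqrt(3), 1/sqrt(3)];
#' this returns the corresponding objective-space front.
#'
#' @param n Number of front points.
#' @return An n x 2 objective matrix.
#' @export
fonseca_fleming_front <- function(n = 1000L) {
  a <- 1 / sqrt(3)
  t <- seq(-a, a, length.out = n)
  out <- cbind(1 - exp(-3 * (t - a)^2), 1 - exp(-3 * (t + a)^2))
  colnames(out) <- c("f1", "f2")
  out
}

# Registry used by the command-line interface.
problem_registry <- function(name, observations = NULL) {
  switch(name,
         binh_korn = problem_binh_korn(),
         fonseca_fleming = problem_fonseca_fleming(),
         cellfree = {
           if (is.null(observations)) {
             stop("the cellfree problem requires time-course observations",
                  call. = FALSE)
           }
           problem_cellfree(observations)
         },
         stop("unknown problem '", name, "'; available: binh_korn, ",
              "fonseca_fleming, cellfree", call. = FALSE))
}
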