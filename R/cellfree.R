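# Two-state cell-free gene expression model (transcription/translation of a
# reporter driven by sigma70 at a constitutive promoter), its synthetic-data
# generator, and the SD-weighted least-squares objectives.

#' Hill-type promoter activity
#'
#' u = sigma70^n / (K^n + sigma70^n): the fraction of promoters engaged by
#' the sigma factor at concentration \code{sigma70}, with dissociation
#' constant \code{K} and Hill coefficient \code{hill_n}.
#'
#' @param sigma70 Sigma-factor concentration (nM, >= 0).
#' @param K Promoter dissociation constant (nM, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @return Activity in [0, 1]; 0.5 exactly when \code{sigma70 == K}.
#' @export
promoter_activity <- function(sigma70, K, hill_n) {
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  if (any(hill_n <= 0)) stop("hill_n must be positive", call. = FALSE)
  if (any(sigma70 < 0)) stop("sigma70 must be non-negative", call. = FALSE)
  sigma70^hill_n / (K^hill_n + sigma70^hill_n)
}

#' Translational capacity decay
#'
#' w(t) = exp(-ln 2 * t / tau_half): the exponentially decaying capacity of
#' the cell-free extract to translate, with half-life \code{tau_half} (hours),
#' so that w(t + tau_half) = w(t) / 2.
#'
#' @param t Time (h, >= 0).
#' @param tau_half Capacity half-life (h, > 0).
#' @return Value in (0, 1]; w(0) = 1.
#' @export
capacity_decay <- function(t, tau_half) {
  if (any(tau_half <= 0)) stop("tau_half must be positive", call. = FALSE)
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-log(2) * t / tau_half)
}

#' Cell-free model parameters
#'
#' The five estimated parameters (maximum transcription rate \code{alpha},
#' effective translation rate constant \code{kappa}, mRNA degradation rate
#' \code{delta_m}, promoter dissociation constant \code{K}, and translation
#' capacity half-life \code{tau_half}) plus the fixed constants
#' (\code{sigma70} = 35 nM, Hill coefficient \code{hill_n} = 1.5, protein
#' degradation rate \code{delta_p} = 0.005 per hour). The defaults for the
#' estimated parameters are package defaults chosen as realistic for a
#' sigma70-driven reporter circuit in a cell-free extract; they serve as the
#' ground truth in the synthetic recovery studies.
#'
#' @param alpha Maximum transcription rate (nM/h).
#' @param kappa Translation rate constant (1/h).
#' @param delta_m mRNA degradation rate (1/h).
#' @param K Promoter dissociation constant (nM).
#' @param tau_half Translation capacity half-life (h).
#' @param sigma70 Sigma-factor concentration (nM), fixed.
#' @param hill_n Hill coefficient, fixed.
#' @param delta_p Protein degradation rate (1/h), fixed.
#' @return A named list of class \code{"cellfree_params"}.
#' @export
cellfree_params <- function(alpha = 100, kappa = 2, delta_m = 0.5, K = 70,
                            tau_half = 4, sigma70 = 35, hill_n = 1.5,
                            delta_p = 0.005) {
  p <- list(alpha = alpha, kappa = kappa, delta_m = delta_m, K = K,
            tau_half = tau_half, sigma70 = sigma70, hill_n = hill_n,
            delta_p = delta_p)
  if (any(unlist(p) <= 0)) {
    stop("all cell-free parameters must be positive", call. = FALSE)
  }
  structure(p, class = "cellfree_params")
}

cellfree_free_names <- c("alpha", "kappa", "delta_m", "K", "tau_half")

#' Simulate the cell-free gene expression model
#'
#' Integrates the two-ODE model
#' dm/dt = alpha * u(sigma70) - delta_m * m and
#' dp/dt = kappa * m * w(t) - delta_p * p,
#' from m(0) = p(0) = 0, where u is the Hill promoter activity
#' (\code{\link{promoter_activity}}) and w the translational capacity decay
#' (\code{\link{capacity_decay}}). Solved with \code{deSolve::lsoda} at tight
#' tolerances, so the mRNA trajectory matches its closed form
#' (alpha*u/delta_m)(1 - exp(-delta_m t)) to relative error below 1e-6.
#'
#' @param params A \code{\link{cellfree_params}} object.
#' @param times Strictly increasing times (h) starting at 0.
#' @return A data.frame with columns \code{time}, \code{mRNA}, \code{protein}
#'   (nM, non-negative).
#' @export
simulate_cellfree <- function(params, times) {
  stopifnot(inherits(params, "cellfree_params"))
  times <- as.numeric(times)
  if (length(times) < 1L || times[1] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing and start at 0", call. = FALSE)
  }
  u <- promoter_activity(params$sigma70, params$K, params$hill_n)
  lambda <- log(2) / params$tau_half
  deriv <- function(t, y, parms) {
    list(c(params$alpha * u - params$delta_m * y[1],
           params$kappa * y[1] * exp(-lambda * t) - params$delta_p * y[2]))
  }
  sol <- deSolve::lsoda(c(m = 0, p = 0), times, deriv, parms = NULL,
                        rtol = 1e-9, atol = 1e-9)
  if (attr(sol, "istate")[1L] < 0 || nrow(sol) < length(times)) {
    stop("ODE solver failed for the cell-free model", call. = FALSE)
  }
  data.frame(time = times,
             mRNA = pmax(sol[, "m"], 0),
             protein = pmax(sol[, "p"], 0))
}

#' Standard-deviation-weighted sum of squared errors
#'
#' sum_i ((sim_i - obs_i) / sd_i)^2: the per-species objective used to fit
#' time-course data, weighting each residual by the reported measurement SD.
#'
#' @param sim,obs Numeric vectors of equal length.
#' @param sd Positive weights of the same length.
#' @return A non-negative scalar.
#' @export
weighted_sse <- function(sim, obs, sd) {
  if (length(sim) != length(obs) || length(obs) != length(sd)) {
    stop("sim, obs and sd must have equal lengths", call. = FALSE)
  }
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  sum(((sim - obs) / sd)^2)
}

#' Generate synthetic time-course observations
#'
#' Simulates the cell-free model at the true parameters, draws
#' \code{n_reps} noisy replicates per time point under the multiplicative
#' Gaussian noise model x' = x * (1 + eps), eps ~ N(0, cv^2) (negative draws
#' clipped at 0), and reports the per-point replicate mean and SD for each
#' species. SDs are floored at \code{sd_floor_frac} times the species'
#' maximum noise-free value so that SD-weighted objectives stay finite at
#' points where the truth (hence the SD) is 0, e.g. t = 0. Draws come from
#' R's global RNG; set a seed for a reproducible table.
#'
#' @param params_true The generating \code{\link{cellfree_params}}.
#' @param times Observation times (h), default the 0, 2, 4, 8, 16 h grid.
#' @param cv Noise coefficient of variation (default 0.15).
#' @param n_reps Replicates per time point (default 3).
#' @param sd_floor_frac SD floor as a fraction of the species maximum
#'   (default 0.01).
#' @return A data.frame of class \code{"poets_observations"} with columns
#'   \code{time}, \code{species} ("mRNA"/"protein"), \code{mean}, \code{sd},
#'   \code{n_reps}; the noise-free truth is attached as attribute
#'   \code{"truth"}.
#' @export
make_synthetic_observations <- function(params_true = cellfree_params(),
                                        times = c(0, 2, 4, 8, 16),
                                        cv = 0.15, n_reps = 3L,
                                        sd_floor_frac = 0.01) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  n_reps <- as.integer(n_reps)
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  truth <- simulate_cellfree(params_true, times)
  one_species <- function(values, label) {
    reps <- matrix(rep(values, each = n_reps) *
                     (1 + rnorm(n_reps * length(values), 0, cv)),
                   nrow = n_reps)
    reps <- pmax(reps, 0)
    floor_sd <- sd_floor_frac * max(values)
    data.frame(time = truth$time,
               species = label,
               mean = colMeans(reps),
               sd = pmax(apply(reps, 2, sd), floor_sd),
               n_reps = n_reps)
  }
  out <- rbind(one_species(truth$mRNA, "mRNA"),
               one_species(truth$protein, "protein"))
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  class(out) <- c("poets_observations", "data.frame")
  out
}

#' Read and write time-course observation tables
#'
#' CSV with columns \code{time, species, mean, sd, n_reps}, header row, '.'
#' decimal separator.
#'
#' @param observations A \code{poets_observations} data.frame.
#' @param path File path.
#' @return \code{read_observations} returns the observation data.frame;
#'   \code{write_observations} returns \code{path} invisibly.
#' @export
write_observations <- function(observations, path) {
  write_csv_full(as.data.frame(observations)[, c("time", "species", "mean",
                                                 "sd", "n_reps")], path)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "species", "mean", "sd", "n_reps")
  if (!all(need %in% names(out))) {
    stop("observation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("poets_observations", "data.frame")
  out
}

#' Cell-free parameter estimation problem
#'
#' Builds the two-objective estimation problem for the cell-free model from a
#' time-course observation table: objectives are the SD-weighted sums of
#' squared errors for the mRNA and protein time courses. The search operates
#' in log10 parameter space over the five estimated parameters, with bounds
#' of +/- \code{half_width} decades around \code{center} (package-default
#' bounds; the scale of plausible rate constants spans orders of magnitude).
#'
#' @param observations A \code{poets_observations} table (see
#'   \code{\link{make_synthetic_observations}} /
#'   \code{\link{read_observations}}) holding both species on a common grid.
#' @param center A \code{\link{cellfree_params}} giving the bound midpoints
#'   and the fixed constants.
#' @param half_width Log10 half-width of the box bounds (default 1.5
#'   decades).
#' @return A \code{\link{poets_problem}} with \code{scale = "log10"} and a
#'   \code{simulate} component for prediction bands.
#' @export
problem_cellfree <- function(observations, center = cellfree_params(),
                             half_width = 1.5) {
  stopifnot(inherits(observations, "data.frame"))
  obs_m <- observations[observations$species == "mRNA", , drop = FALSE]
  obs_p <- observations[observations$species == "protein", , drop = FALSE]
  if (nrow(obs_m) == 0L || nrow(obs_p) == 0L) {
    stop("observations must include both mRNA and protein", call. = FALSE)
  }
  if (!isTRUE(all.equal(obs_m$time, obs_p$time))) {
    stop("mRNA and protein observations must share a time grid",
         call. = FALSE)
  }
  times <- obs_m$time
  center_free <- log10(unlist(center[cellfree_free_names]))
  from_log <- function(xlog) {
    th <- as.list(10^xlog)
    names(th) <- cellfree_free_names
    cellfree_params(alpha = th$alpha, kappa = th$kappa,
                    delta_m = th$delta_m, K = th$K, tau_half = th$tau_half,
                    sigma70 = center$sigma70, hill_n = center$hill_n,
                    delta_p = center$delta_p)
  }
  poets_problem(
    name = "cellfree",
    evaluate = function(xlog) {
      sim <- simulate_cellfree(from_log(xlog), times)
      c(eps_mRNA = weighted_sse(sim$mRNA, obs_m$mean, obs_m$sd),
        eps_protein = weighted_sse(sim$protein, obs_p$mean, obs_p$sd))
    },
    lower = center_free - half_width,
    upper = center_free + half_width,
    par_names = paste0("log10_", cellfree_free_names),
    obj_names = c("eps_mRNA", "eps_protein"),
    scale = "log10",
    simulate = function(xlog, times) {
      sim <- simulate_cellfree(from_log(xlog), times)
      cbind(mRNA = sim$mRNA, protein = sim$protein)
    })
}
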