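# Independent oracles and fixture generators. The oracles deliberately avoid
# the package's ranking/hypervolume code paths: ranks by a direct double-loop
# dominance count in R, hypervolume by uniform Monte Carlo sampling.

# Brute-force dominance-count ranks, O(n^2 m), pure R.
oracle_ranks <- function(F, weak = FALSE) {
  n <- nrow(F)
  m <- ncol(F)
  r <- integer(n)
  for (i in seq_len(n)) {
    fi <- matrix(F[i, ], n, m, byrow = TRUE)
    le <- rowSums(F <= fi) == m
    lt <- rowSums(F < fi) > 0
    dom <- if (weak) le else (le & lt)
    dom[i] <- FALSE
    r[i] <- sum(dom)
  }
  r
}

# Random objective matrix; mixing continuous and small-integer-grid values
# forces exact ties and duplicated rows, exercising strictness.
random_objectives <- function(n, m, discrete = FALSE) {
  if (discrete) {
    matrix(as.numeric(sample(0:4, n * m, replace = TRUE)), n, m)
  } else {
    matrix(runif(n * m), n, m)
  }
}

# Random mutually non-dominated front (minimization) by filtering a cloud.
random_front <- function(n, m) {
  X <- matrix(runif(3 * n * m), ncol = m)
  keep <- oracle_ranks(X) == 0
  F <- X[keep, , drop = FALSE]
  F[seq_len(min(n, nrow(F))), , drop = FALSE]
}

# Monte Carlo hypervolume oracle: fraction of uniform samples in
# [min corner, ref] dominated by at least one front point.
oracle_hypervolume_mc <- function(F, ref, n_samples = 1e5) {
  m <- ncol(F)
  lo <- apply(F, 2, min)
  box <- prod(ref - lo)
  S <- matrix(runif(n_samples * m), n_samples, m)
  S <- sweep(sweep(S, 2, ref - lo, "*"), 2, lo, "+")
  dominated <- rep(FALSE, n_samples)
  for (i in seq_len(nrow(F))) {
    dominated <- dominated | (rowSums(S >= matrix(F[i, ], n_samples, m,
                                                  byrow = TRUE)) == m)
  }
  list(estimate = mean(dominated) * box,
       se = sd(dominated) / sqrt(n_samples) * box)
}

# Small archive around random params for a given objective matrix.
archive_from_objectives <- function(F, ...) {
  poets_archive(matrix(runif(nrow(F) * 2), ncol = 2), F, ...)
}

# A quick schedule for tests that only need algorithmic behavior, not
# convergence depth.
short_schedule <- function(...) {
  defaults <- list(Tmin = 1e-2, n_iter = 20L, n_max = 400L)
  args <- utils::modifyList(defaults, list(...))
  do.call(poets_schedule, args)
}

log_truth_cellfree <- function(params = cellfree_params()) {
  log10(unlist(params[c("alpha", "kappa", "delta_m", "K", "tau_half")]))
}
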