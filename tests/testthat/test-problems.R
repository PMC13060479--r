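test_that("Binh-Korn objectives and constraints match the definition", {
  r <- binh_korn(c(0, 0))
  expect_equal(unname(r$objectives), c(0, 50))
  expect_true(r$feasible)   # (0-5)^2 + 0 = 25 <= 25; 64 + 9 = 73 >= 7.7
  r <- binh_korn(c(5, 3))
  expect_equal(unname(r$objectives), c(136, 4))
  expect_true(r$feasible)
  expect_false(binh_korn(c(0, 3))$feasible)  # 25 + 9 = 34 > 25
  p <- problem_binh_korn()
  expect_equal(p$lower, c(0, 0))
  expect_equal(p$upper, c(5, 3))
})

test_that("the dense Binh-Korn front is feasible and non-dominated", {
  F <- binh_korn_front(400)
  expect_equal(nrow(F), 400L)
  # f1 increasing, f2 decreasing along the parametrization => non-dominated
  expect_true(all(diff(F[, 1]) > 0))
  expect_true(all(diff(F[, 2]) < 0))
  expect_identical(oracle_ranks(F), rep(0L, nrow(F)))
  # objective-space points correspond to feasible parameter-space points
  t1 <- seq(0, 3, length.out = 10)
  for (t in t1) expect_true(binh_korn(c(t, t))$feasible)
  for (t in seq(3, 5, length.out = 10)) {
    expect_true(binh_korn(c(t, 3))$feasible)
  }
  # oracle: a dense feasible grid contains nothing dominating the front
  xs <- seq(0, 5, length.out = 60)
  ys <- seq(0, 3, length.out = 40)
  grid <- expand.grid(x = xs, y = ys)
  vals <- t(apply(grid, 1, function(r) {
    b <- binh_korn(as.numeric(r))
    if (b$feasible) b$objectives else c(NA, NA)
  }))
  vals <- vals[stats::complete.cases(vals), ]
  Fsub <- F[seq(1, nrow(F), by = 40), , drop = FALSE]
  for (i in seq_len(nrow(Fsub))) {
    dominating <- vals[, 1] <= Fsub[i, 1] & vals[, 2] <= Fsub[i, 2] &
      (vals[, 1] < Fsub[i, 1] | vals[, 2] < Fsub[i, 2])
    expect_false(any(dominating))
  }
})

test_that("Fonseca-Fleming matches analytic values and its symmetry", {
  a <- 1 / sqrt(3)
  f <- fonseca_fleming(c(a, a, a))
  expect_equal(unname(f), c(0, 1 - exp(-4)))
  f0 <- fonseca_fleming(c(0, 0, 0))
  expect_equal(unname(f0), rep(1 - exp(-1), 2))
  set.seed(15)
  for (i in 1:10) {
    x <- runif(3, -4, 4)
    expect_equal(fonseca_fleming(x)[["f1"]], fonseca_fleming(-x)[["f2"]])
  }
  F <- fonseca_fleming_front(200)
  expect_identical(oracle_ranks(F), rep(0L, 200L))
  expect_true(all(F >= 0 & F < 1))
})

test_that("promoter activity is a Hill function with the right midpoint", {
  expect_equal(promoter_activity(35, 35, 1.5), 0.5)
  expect_equal(promoter_activity(70, 70, 3.7), 0.5)
  expect_equal(promoter_activity(0, 35, 1.5), 0)
  expect_equal(promoter_activity(1e6, 35, 1.5), 1, tolerance = 1e-4)
  expect_error(promoter_activity(35, 0, 1.5), "K")
})

test_that("capacity decay halves every half-life", {
  expect_equal(capacity_decay(0, 4), 1)
  expect_equal(capacity_decay(4, 4), 0.5)
  expect_equal(capacity_decay(8, 4), 0.25)
  t <- c(0.3, 1.7, 9)
  expect_equal(capacity_decay(t + 2.5, 2.5), capacity_decay(t, 2.5) / 2)
  expect_error(capacity_decay(1, 0), "tau_half")
  expect_error(capacity_decay(-1, 2), "t must")
})

test_that("weighted SSE matches its definition and scaling", {
  expect_equal(weighted_sse(c(1, 2), c(1, 2), c(1, 1)), 0)
  expect_equal(weighted_sse(3, 1, 2), 1)  # residual equal to the SD
  sim <- c(1, 4, 2); obs <- c(2, 2, 0); sd <- c(0.5, 1, 2)
  expect_equal(weighted_sse(sim, obs, 2 * sd), weighted_sse(sim, obs, sd) / 4)
  expect_error(weighted_sse(1, 1, 0), "sd")
  expect_error(weighted_sse(c(1, 2), 1, 1), "length")
})

test_that("the mRNA trajectory matches its closed form", {
  p <- cellfree_params()
  times <- c(0, 2, 4, 8, 16)
  sim <- simulate_cellfree(p, times)
  u <- promoter_activity(p$sigma70, p$K, p$hill_n)
  closed <- (p$alpha * u / p$delta_m) * (1 - exp(-p$delta_m * times))
  expect_equal(sim$mRNA[-1] / closed[-1], rep(1, 4), tolerance = 1e-6)
  expect_equal(sim$mRNA[1], 0)
  # zero transcription silences both species
  p0 <- cellfree_params(alpha = 1e-300)
  sim0 <- simulate_cellfree(p0, times)
  expect_equal(sim0$mRNA, rep(0, 5), tolerance = 1e-12)
  expect_equal(sim0$protein, rep(0, 5), tolerance = 1e-12)
  expect_error(simulate_cellfree(p, c(1, 2)), "start at 0")
})

test_that("the protein trajectory matches a quadrature oracle", {
  # p(t) = integral of kappa * m(s) * w(s) * exp(-delta_p (t - s)) ds with
  # m(s) known in closed form; independent of the ODE solver
  p <- cellfree_params(alpha = 80, kappa = 1.3, delta_m = 0.7, K = 50,
                       tau_half = 3)
  times <- c(0, 2, 4, 8, 16)
  sim <- simulate_cellfree(p, times)
  u <- promoter_activity(p$sigma70, p$K, p$hill_n)
  m_ss <- p$alpha * u / p$delta_m
  lam <- log(2) / p$tau_half
  for (i in 2:5) {
    t_i <- times[i]
    oracle <- stats::integrate(function(s) {
      p$kappa * m_ss * (1 - exp(-p$delta_m * s)) * exp(-lam * s) *
        exp(-p$delta_p * (t_i - s))
    }, 0, t_i, rel.tol = 1e-10)$value
    expect_equal(sim$protein[i], oracle, tolerance = 1e-5)
  }
})

test_that("synthetic observations implement the multiplicative noise model", {
  p <- cellfree_params()
  set.seed(30)
  obs <- make_synthetic_observations(p, cv = 0, n_reps = 3)
  truth <- attr(obs, "truth")
  # cv = 0: means equal truth and SDs sit at the floor
  expect_equal(obs$mean, c(truth$mRNA, truth$protein))
  expect_equal(obs$sd[obs$species == "mRNA"],
               rep(0.01 * max(truth$mRNA), 5))
  expect_equal(obs$sd[obs$species == "protein"],
               rep(0.01 * max(truth$protein), 5))

  # determinism for a fixed seed
  set.seed(31); o1 <- make_synthetic_observations(p)
  set.seed(31); o2 <- make_synthetic_observations(p)
  expect_identical(o1, o2)

  # at large replicate counts the empirical CV approaches 15%
  set.seed(32)
  big <- make_synthetic_observations(p, n_reps = 4000)
  late <- big$species == "protein" & big$time > 0
  expect_equal(big$sd[late] / big$mean[late], rep(0.15, 4),
               tolerance = 0.02)
  expect_error(make_synthetic_observations(p, n_reps = 1), "n_reps")
  expect_error(make_synthetic_observations(p, cv = -1), "cv")
})

test_that("the cell-free objective vanishes at truth on noise-free data", {
  p <- cellfree_params()
  set.seed(33)
  obs <- make_synthetic_observations(p, cv = 0)
  problem <- problem_cellfree(obs)
  eps <- problem$evaluate(log_truth_cellfree(p))
  expect_equal(unname(eps), c(0, 0), tolerance = 1e-8)
  # log10 bounds are +/- 1.5 decades around the center
  expect_equal(problem$upper - problem$lower, rep(3, 5))
  expect_identical(problem$scale, "log10")
  # evaluate exponentiates internally: simulate at bound corners stays finite
  expect_true(all(is.finite(problem$evaluate(problem$lower))))
})

test_that("observation tables round-trip through CSV", {
  set.seed(34)
  obs <- make_synthetic_observations()
  path <- tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$mean, obs$mean)
  expect_equal(back$sd, obs$sd)
  expect_identical(back$species, obs$species)
})
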