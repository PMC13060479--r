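test_that("strict dominance follows the componentwise definition", {
  expect_true(strictly_dominates(c(1, 1), c(2, 2)))
  expect_false(strictly_dominates(c(1, 2), c(1, 2)))  # identical points
  expect_false(strictly_dominates(c(1, 3), c(2, 2)))  # incomparable
  expect_false(strictly_dominates(c(2, 2), c(1, 3)))
  expect_true(strictly_dominates(c(1, 2), c(1, 3)))   # weak tie + one strict
  expect_error(strictly_dominates(c(1, 2), c(1, 2, 3)), "length")
  expect_error(strictly_dominates(c(1, NA), c(1, 2)), "finite")
  expect_error(strictly_dominates(c(1, Inf), c(1, 2)), "finite")
})

test_that("pareto_ranks counts dominators and ignores record order", {
  expect_identical(pareto_ranks(matrix(c(3, 3), 1)), 0L)
  expect_identical(pareto_ranks(rbind(c(1, 1), c(2, 2), c(3, 0))),
                   c(0L, 1L, 0L))
  expect_identical(pareto_ranks(matrix(numeric(0), 0, 2)), integer(0))
  set.seed(11)
  for (rep in 1:20) {
    F <- random_objectives(sample(2:60, 1), sample(2:4, 1),
                           discrete = rep %% 2 == 0)
    expect_identical(pareto_ranks(F), oracle_ranks(F))
    perm <- sample(nrow(F))
    expect_identical(pareto_ranks(F[perm, , drop = FALSE]),
                     pareto_ranks(F)[perm])
  }
})

test_that("duplicated solutions share rank 0 under strict dominance but not weak", {
  for (k in c(2L, 5L, 9L)) {
    F <- matrix(rep(c(1, 2, 3), each = k), nrow = k)
    expect_identical(pareto_ranks(F), rep(0L, k))
    expect_identical(pareto_ranks(F, weak = TRUE), rep(k - 1L, k))
  }
})

test_that("rank_insert performs the two-direction incremental update", {
  empty <- matrix(numeric(0), 0, 2)
  res <- rank_insert(empty, integer(0), c(1, 1))
  expect_identical(res$candidate_rank, 0L)
  expect_identical(res$touched, integer(0))

  res <- rank_insert(rbind(c(1, 1), c(2, 2)), c(0L, 1L), c(0, 0))
  expect_identical(res$ranks, c(1L, 2L))
  expect_identical(res$candidate_rank, 0L)
  expect_identical(sort(res$touched), c(1L, 2L))

  expect_error(rank_insert(rbind(c(1, 1)), 0L, c(1, 2, 3)), "dimension")
})

test_that("sequential rank_insert matches the brute-force oracle", {
  set.seed(7)
  F <- random_objectives(120, 3)
  ranks <- integer(0)
  acc <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(F))) {
    res <- rank_insert(acc, ranks, F[i, ])
    ranks <- c(res$ranks, res$candidate_rank)
    acc <- rbind(acc, F[i, , drop = FALSE])
  }
  expect_identical(ranks, oracle_ranks(F))
})

test_that("rank_revert restores the pre-insertion rank vector exactly", {
  set.seed(21)
  for (rep in 1:25) {
    F <- random_objectives(sample(2:40, 1), 2, discrete = rep %% 2 == 0)
    ranks <- pareto_ranks(F)
    cand <- runif(2)
    res <- rank_insert(F, ranks, cand)
    expect_identical(rank_revert(res$ranks, res$touched), ranks)
  }
})

test_that("prune_by_cutoff removes high ranks and keeps at least one record", {
  F <- rbind(c(5, 5), c(4, 4), c(3, 3), c(2, 2), c(1, 1), c(0, 0))
  a <- archive_from_objectives(F, rank_cutoff = 5L)
  expect_identical(a$rank, c(5L, 4L, 3L, 2L, 1L, 0L))
  pruned <- prune_by_cutoff(a)
  expect_equal(nrow(pruned$objectives), 5L)
  expect_true(all(pruned$rank < 5L))
  expect_identical(pruned$rank, pareto_ranks(pruned$objectives))

  # no removal: archive unchanged (re-rank is a no-op)
  b <- archive_from_objectives(rbind(c(1, 2), c(2, 1)), rank_cutoff = 8L)
  expect_identical(prune_by_cutoff(b)$objectives, b$objectives)
  expect_identical(prune_by_cutoff(b)$rank, b$rank)
})

test_that("pruning preserves survivor ranks (carried-rank equivalence)", {
  # the annealer carries survivor ranks instead of re-ranking; this asserts
  # the transitivity argument that makes the full re-rank a no-op
  set.seed(31)
  for (rep in 1:30) {
    F <- random_objectives(sample(5:80, 1), sample(2:3, 1),
                           discrete = rep %% 3 == 0)
    a <- archive_from_objectives(F, rank_cutoff = sample(1:4, 1))
    keep <- a$rank < a$rank_cutoff
    expect_identical(pareto_ranks(F[keep, , drop = FALSE]), a$rank[keep])
  }
})

test_that("enforce_capacity keeps the n_max lowest ranks, newest on ties", {
  F <- rbind(c(0, 11), c(1, 10), c(2, 9), c(3, 8))
  a <- archive_from_objectives(F, n_max = 10L)
  expect_identical(enforce_capacity(a)$objectives, a$objectives)

  # ranks 0..11 via a dominated chain; drop the two highest
  Fc <- cbind(as.numeric(0:11), as.numeric(0:11))
  b <- archive_from_objectives(Fc, n_max = 10L)
  capped <- enforce_capacity(b)
  expect_equal(nrow(capped$objectives), 10L)
  expect_equal(capped$objectives, Fc[1:10, ])
  expect_identical(capped$rank, pareto_ranks(capped$objectives))

  # equal-rank tie at the boundary: the most recently inserted survives
  Ft <- rbind(c(0, 3), c(3, 0), c(1, 2), c(2, 1))  # all rank 0
  tie <- poets_archive(matrix(0, 4, 1), Ft, n_max = 3L, rank_cutoff = 8L,
                       insertion = 1:4)
  kept <- enforce_capacity(tie)
  expect_equal(nrow(kept$objectives), 3L)
  expect_identical(kept$insertion, 2:4)  # oldest tie member dropped
})

test_that("capacity truncation also preserves survivor ranks", {
  set.seed(41)
  for (rep in 1:30) {
    F <- random_objectives(sample(10:80, 1), 2, discrete = rep %% 3 == 0)
    n_max <- sample(3:9, 1)
    a <- archive_from_objectives(F, n_max = n_max)
    keep <- sort(order(a$rank, -a$insertion)[seq_len(n_max)])
    expect_identical(pareto_ranks(F[keep, , drop = FALSE]), a$rank[keep])
  }
})

test_that("rank_histogram counts every record and always keys rank 0", {
  a <- archive_from_objectives(rbind(c(1, 2), c(2, 1), c(0.5, 0.5)))
  h <- rank_histogram(a)
  expect_identical(sum(h), 3L)
  expect_true("0" %in% names(h))
  h2 <- rank_histogram(c(0L, 0L, 1L, 3L))
  expect_identical(h2, setNames(c(2L, 1L, 1L), c("0", "1", "3")))
  set.seed(5)
  F <- random_objectives(100, 2)
  expect_identical(sum(rank_histogram(archive_from_objectives(F))), 100L)
})

test_that("merge_archives concatenates, re-ranks, and retains duplicates", {
  set.seed(9)
  F1 <- random_objectives(30, 2)
  F2 <- random_objectives(20, 2)
  a1 <- archive_from_objectives(F1, chain_id = 1L)
  a2 <- archive_from_objectives(F2, chain_id = 2L)

  merged <- merge_archives(list(a1, a2))
  expect_identical(merged$rank, oracle_ranks(rbind(F1, F2)))
  expect_identical(merged$chain_id, rep(c(1L, 2L), c(30L, 20L)))

  # merging one archive is just a re-rank
  expect_identical(merge_archives(list(a1))$rank, a1$rank)

  # self-merge: duplicates do not dominate each other, so the front (rank 0)
  # is exactly duplicated; dominated records see every dominator twice, and
  # the ranks match the dominance-count oracle on the doubled set
  self <- merge_archives(list(a1, a1))
  expect_identical(self$rank, oracle_ranks(rbind(F1, F1)))
  expect_identical(self$rank == 0L, rep(a1$rank == 0L, 2))
  expect_identical(self$rank, c(2L * a1$rank, 2L * a1$rank))

  a3 <- archive_from_objectives(random_objectives(5, 3))
  expect_error(merge_archives(list(a1, a3)), "dimension")
})
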