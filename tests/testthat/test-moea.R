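test_that("binary recombination follows the stated per-bit law", {
  set.seed(1)
  len <- 10
  # identical parents: both branches return the common bit, so the
  # offspring deviates from it with probability at most 1 - keep_prob
  b <- rbinom(len, 1, 0.5)
  n <- 2000
  ndev <- sum(replicate(n, sum(binary_recombine(b, b, b) != b)))
  expect_lt(ndev / (n * len), 0.1 + 3 * sqrt(0.1 * 0.9 / (n * len)))

  # agreeing advisors that contradict the base: the base bit is kept with
  # probability keep_prob = 0.9 exactly
  z0 <- rep(0L, len)
  ones <- rep(1L, len)
  adopt <- replicate(n, sum(binary_recombine(z0, ones, ones)))
  pa <- mean(adopt) / len
  expect_lt(abs(pa - 0.1), 3 * sqrt(0.1 * 0.9 / (n * len)))

  # all-zero parents: expected popcount <= 0.1 * len (binomial bound)
  z <- rep(0L, len)
  pops <- replicate(2000, sum(binary_recombine(z, z, z)))
  expect_lt(mean(pops), 0.1 * len + 3 * sqrt(0.1 * 0.9 * len / 2000))

  # disagreement branch: flip probability flip_prob
  b2 <- rep(0L, len)
  b3 <- rep(1L, len)
  flips <- replicate(2000, sum(binary_recombine(z, b2, b3, flip_prob = 0.45)))
  pf <- mean(flips) / len
  expect_lt(abs(pf - 0.45), 3 * sqrt(0.45 * 0.55 / (2000 * len)))

  # output length always matches
  expect_length(binary_recombine(z, b2, b3), len)
  expect_error(binary_recombine(c(0L, 1L), z, z), "length")
})

test_that("real recombination implements DE/rand/1 with reflection", {
  lo <- rep(-3, 2)
  hi <- rep(3, 2)
  set.seed(2)
  # r2 == r3: mutant equals r1; with CR = 1 the offspring is exactly r1
  r1 <- c(1, -2)
  expect_equal(real_recombine(r1, c(0.5, 0.5), c(0.5, 0.5),
                              de_f = 0.7, de_cr = 1, lo = lo, hi = hi), r1)
  # direct formula
  expect_equal(real_recombine(c(1, 1), c(2, 0), c(0, 0),
                              de_f = 0.5, de_cr = 1,
                              lo = c(0, 0), hi = c(10, 10)), c(2, 1))
  # reflection keeps every output inside the box
  for (i in 1:200) {
    out <- real_recombine(runif(4, -3, 3), runif(4, -3, 3), runif(4, -3, 3),
                          de_f = 2.5, de_cr = 0.9,
                          lo = rep(-3, 4), hi = rep(3, 4))
    expect_true(all(out >= -3 & out <= 3))
  }
})

test_that("rank_and_truncate agrees with brute-force dominance depth", {
  ds <- s1_dataset(seed = 3)
  for (rep in 1:3) {
    sols <- random_solutions(ds, 2, 40, seed = 10 + rep)
    rt <- rank_and_truncate(sols, 25)
    expect_length(rt$pop, 25)
    expect_length(rt$leftovers, 15)

    err <- vapply(sols, function(s) s$err, 0)
    l0 <- vapply(sols, function(s) s$l0, 0)
    oracle <- brute_ranks(err, l0)
    cpp <- ssinfer:::cpp_dominance_ranks(err, as.integer(l0))
    expect_equal(cpp, oracle)

    # survivors are closed under rank: no leftover outranks a survivor
    worst_kept <- max(oracle[match(
      vapply(rt$pop, function(s) s$err, 0), err)])
    best_left <- min(oracle[match(
      vapply(rt$leftovers, function(s) s$err, 0), err)])
    expect_lte(worst_kept, best_left + 0L)

    # within the survivor list ranks are non-decreasing, and l0 ascends
    # within each rank
    kept_ranks <- oracle[match(vapply(rt$pop, function(s) s$err, 0), err)]
    expect_true(all(diff(kept_ranks) >= 0))
    kept_l0 <- vapply(rt$pop, function(s) s$l0, 0)
    for (r in unique(kept_ranks)) {
      expect_true(all(diff(kept_l0[kept_ranks == r]) >= 0))
    }
  }
})

test_that("archive updating follows the replacement rules", {
  mk <- function(bx, err) mixed_solution(bx, c(rep(0, 10), 1, 1), 1, err = err)
  arc <- list(mk(c(1, rep(0, 9)), 5), mk(c(1, rep(0, 9)), 7),
              mk(c(0, 1, rep(0, 8)), 2))
  # candidate with a bitstring present: replaces the worst holder only if
  # better
  cand <- mk(c(1, rep(0, 9)), 6)
  out <- update_archive(arc, cand)
  expect_equal(sort(vapply(out, function(s) s$err, 0)), c(2, 5, 6))
  # worse candidate with a novel bitstring leaves the archive unchanged
  worse <- mk(c(0, 0, 1, rep(0, 7)), 99)
  out2 <- update_archive(arc, worse)
  expect_equal(vapply(out2, function(s) s$err, 0),
               vapply(arc, function(s) s$err, 0))
  # novel better candidate evicts the worst among duplicated bitstrings
  nov <- mk(c(0, 0, 1, rep(0, 7)), 1)
  out3 <- update_archive(arc, nov)
  expect_equal(sort(vapply(out3, function(s) s$err, 0)), c(1, 2, 5))
  expect_length(out3, 3)
})

test_that("run_equation is seed-deterministic and returns a clean front", {
  ds <- s1_dataset(seed = 1)
  cfg <- ea_config(pop_size = 30, iterations = 120, n_runs = 1)
  f1 <- run_equation(ds, 2, cfg, seed = 5)
  f2 <- run_equation(ds, 2, cfg, seed = 5)
  expect_identical(f1, f2)
  f3 <- run_equation(ds, 2, cfg, seed = 6)
  expect_false(identical(f1, f3))

  # front members are mutually nondominated (oracle check) and caches match
  err <- vapply(f1$solutions, function(s) s$err, 0)
  l0 <- vapply(f1$solutions, function(s) s$l0, 0)
  expect_true(all(brute_nondominated(err, l0)))
  for (s in f1$solutions) {
    expect_equal(s$err, fitting_error(s, ds))
    expect_equal(s$l0, sum(s$bx))
  }
})

test_that("merged fronts never lose the best error at any connection count", {
  ds <- s1_dataset(seed = 2)
  cfg <- ea_config(pop_size = 30, iterations = 150, n_runs = 1)
  fronts <- lapply(1:3, function(r) run_equation(ds, 2, cfg, seed = r))
  merged <- merge_runs(fronts)
  # idempotence
  expect_identical(merge_runs(list(merged, merged)), merged)
  merr <- vapply(merged$solutions, function(s) s$err, 0)
  ml0 <- vapply(merged$solutions, function(s) s$l0, 0)
  for (f in fronts) {
    for (s in f$solutions) {
      at <- which(ml0 == s$l0)
      better <- c(merr[at], merr[ml0 < s$l0])
      if (length(better)) expect_lte(min(better), s$err)
    }
  }
  expect_error(merge_runs(list(merged, run_equation(ds, 1, cfg, seed = 1))),
               "same equation")
})

test_that("the EA recovers the sparse truth of an easy equation", {
  # S1 equation 5 has two connections (g54, h55); analytic slopes make the
  # truth an exact optimum, so a modest budget suffices
  dsa <- s1_dataset(seed = 1, slopes = "analytic")
  f <- merge_runs(lapply(1:2, function(r) {
    run_equation(dsa, 5, ea_config(pop_size = 60, iterations = 400), seed = r)
  }))
  l0s <- vapply(f$solutions, function(s) s$l0, 0)
  expect_true(2 %in% l0s)
  best2 <- f$solutions[[which(l0s == 2)]]
  expect_identical(best2$bx, s1_true_mask(5))
  d <- decode(best2)
  expect_equal(d$g[4], 2, tolerance = 0.05)
  expect_equal(d$h[5], 2, tolerance = 0.05)
})
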