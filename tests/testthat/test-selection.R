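front_from <- function(err, l0, eq = 1, N = 5) {
  sols <- lapply(seq_along(err), function(k) {
    bx <- integer(2 * N)
    if (l0[k] > 0) bx[seq_len(l0[k])] <- 1L
    mixed_solution(bx, c(seq_len(2 * N) * 0.1, 1, 1), eq, err = err[k])
  })
  structure(list(solutions = sols, eq_index = eq), class = "ss_front")
}

test_that("normalization divides by the front maxima", {
  sf <- normalize_front(front_from(c(4, 1, 0.2), c(0, 1, 2)))
  expect_equal(sf$score1, c(1, 0.25, 0.05))
  expect_equal(sf$score2, c(0, 0.5, 1))
  # ordering of members is preserved
  expect_equal(order(sf$err), order(sf$score1))
  # single member: scores are 1 (or 0 where the maximum is 0)
  s1f <- normalize_front(front_from(2, 3))
  expect_equal(s1f$score1, 1)
  expect_equal(s1f$score2, 1)
  s0 <- normalize_front(front_from(0, 0))
  expect_equal(s0$score1, 0)
  expect_equal(s0$score2, 0)
  expect_error(normalize_front(structure(list(solutions = list()),
                                         class = "ss_front")), "empty")
})

test_that("aggregation scores follow their closed forms", {
  expect_equal(las_score(0.3, 0.8, 1), 0.3)
  expect_equal(las_score(0.3, 0.8, 0), 0.8)
  expect_equal(las_score(0.2, 0.6, 0.5), 0.4)
  expect_error(las_score(0.2, 0.6, 1.2), "lam")

  expect_equal(ap_score(0.3, 0.8, 1), 0.3)
  expect_equal(ap_score(0.04, 0.25, 0.5), 0.1)
  expect_equal(ap_score(0, 0.7, 0.6), 0)
  expect_equal(ap_score(0, 0.7, 0), 0.7)   # x^0 = 1 even at x = 0
  expect_error(ap_score(0.2, 0.6, -0.1), "lam")
})

test_that("per-weight selection matches exhaustive argmin over candidates", {
  set.seed(12)
  for (rep in 1:20) {
    M <- sample(3:8, 1)
    err <- sort(runif(M, 0.01, 5), decreasing = TRUE)
    l0 <- sort(sample(0:10, M))
    sf <- normalize_front(front_from(err, l0))
    lam <- runif(1)
    k <- select_equation_result(sf, lam)
    # oracle: argmin of the product over the selectable (nonempty) members
    cand <- which(sf$l0 > 0)
    ap <- sf$score1[cand]^lam * sf$score2[cand]^(1 - lam)
    expect_equal(sf$err[k], sf$err[cand[which.min(ap)]])
  }
  # endpoints: lam 0 gives the sparsest selectable, lam 1 the best fit
  sf <- normalize_front(front_from(c(9, 4, 1, 0.1), c(0, 1, 3, 6)))
  expect_equal(select_equation_result(sf, 0), 2)
  expect_equal(select_equation_result(sf, 1), 4)
})

test_that("the empty topology is an anchor, not a selectable result", {
  sf <- normalize_front(front_from(c(10, 0.5, 0.2), c(0, 2, 4)))
  for (lam in seq(0, 1, by = 0.25)) {
    expect_gt(sf$l0[select_equation_result(sf, lam)], 0)
  }
})

test_that("the weight sweep spans the grid and groups distinct networks", {
  fronts <- list(front_from(c(9, 2, 0.4, 0.1), c(0, 1, 2, 4), eq = 1, N = 2),
                 front_from(c(7, 1, 0.02), c(0, 2, 3), eq = 2, N = 2))
  sw <- sweep_lambda(fronts, grid_size = 101)
  expect_equal(nrow(sw$grid), 101)
  expect_equal(sw$grid$lambda[c(1, 101)], c(0, 1))
  # sum vectors stay within [0, N]
  expect_true(all(sw$grid$sum1 >= 0 & sw$grid$sum1 <= 2))
  expect_true(all(sw$grid$sum2 >= 0 & sw$grid$sum2 <= 2))
  # far fewer distinct networks than grid points
  expect_lte(length(sw$nets), 15)
  # selected l0 is non-decreasing in lambda for each equation
  for (i in 1:2) {
    l0path <- vapply(seq_len(101), function(a) {
      fronts[[i]]$solutions[[sw$selections[a, i]]]$l0
    }, 0)
    expect_true(all(diff(l0path) >= 0))
  }
})

test_that("knee selection finds the corner and is order-invariant", {
  # constructed toy: the middle point is the knee
  pts <- rbind(c(0, 1), c(0.05, 0.1), c(1, 0))
  kn <- knee_select(pts)
  expect_equal(kn$index, 2)
  expect_equal(unname(kn$point), c(0.05, 0.1))

  # invariance to row order
  perm <- c(3, 1, 2)
  kn2 <- knee_select(pts[perm, ])
  expect_equal(unname(kn2$point), c(0.05, 0.1))

  # the chosen point is always on the nondominated subset
  pts3 <- rbind(c(0.1, 1), c(0.2, 2), c(0.5, 0.5), c(1, 0.1))
  kn3 <- knee_select(pts3)
  others <- pts3[-kn3$index, , drop = FALSE]
  expect_false(any(apply(others, 1, function(p) dominates(p, kn3$point))))

  # two points: the better fit wins; fewer than two is an error
  expect_equal(knee_select(rbind(c(0.1, 2), c(1, 1)))$index, 1)
  expect_error(knee_select(rbind(c(1, 1))), "at least 2")
})

test_that("knee selection prefers the saturation corner of an L-chain", {
  # fit collapses by orders of magnitude at the third point, then saturates:
  # the knee must sit at the collapse, not on the flat tail
  pts <- rbind(c(2, 1), c(0.5, 2), c(0.001, 3), c(0.0008, 4), c(0.0007, 5))
  expect_equal(knee_select(pts)$index, 3)
})

test_that("asp assembles the knee network deterministically", {
  fronts <- list(front_from(c(9, 2, 0.001, 0.0008), c(0, 1, 2, 4), eq = 1, N = 2),
                 front_from(c(7, 1, 0.002), c(0, 2, 3), eq = 2, N = 2))
  inf1 <- asp(fronts)
  inf2 <- asp(fronts)
  expect_identical(inf1$model, inf2$model)
  expect_identical(inf1$lambda_interval, inf2$lambda_interval)
  # the assembled model decodes exactly from the selected solutions
  for (i in 1:2) {
    d <- decode(inf1$solutions[[i]])
    expect_equal(inf1$model$G[i, ], d$g)
    expect_equal(inf1$model$H[i, ], d$h)
    expect_equal(inf1$model$alpha[i], d$alpha)
  }
  # constant multipliers fold into the assembled rates
  cm <- cbind(cg = c(2, 3), ch = c(1, 4))
  inf3 <- asp(fronts, const_mult = cm)
  expect_equal(inf3$model$alpha,
               vapply(1:2, function(i) decode(inf3$solutions[[i]])$alpha, 0) *
                 cm[, 1])
})
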