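test_that("confusion counts structural positives over the 2N^2 entries", {
  m <- s1_model()
  cc <- confusion(m, m)
  expect_equal(cc[c("tp", "fp", "tn", "fn")],
               list(tp = 13, fp = 0, tn = 37, fn = 0))
  expect_equal(cc$sign_tp, 13)

  empty <- s_system(rep(1, 5), rep(1, 5), matrix(0, 5, 5), matrix(0, 5, 5))
  cc0 <- confusion(m, empty)
  expect_equal(cc0[c("tp", "fp", "tn", "fn")],
               list(tp = 0, fp = 0, tn = 37, fn = 13))

  # counts always partition the 2 N^2 entries
  set.seed(3)
  for (rep in 1:5) {
    G <- matrix(rbinom(25, 1, 0.3) * rnorm(25), 5, 5)
    H <- matrix(rbinom(25, 1, 0.3) * rnorm(25), 5, 5)
    inf <- s_system(rep(1, 5), rep(1, 5), G, H)
    cci <- confusion(m, inf)
    expect_equal(cci$tp + cci$fp + cci$tn + cci$fn, 50)
  }

  # only the dependent part of the truth is scored
  cc2 <- confusion(s2_model(), empty)
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 50)
  expect_error(confusion(m, s_system(1, 1, matrix(1, 1, 1), matrix(1, 1, 1))),
               "dimension")
})

test_that("confusion is invariant under joint component relabeling", {
  m <- s1_model()
  set.seed(9)
  G <- matrix(rbinom(25, 1, 0.4) * rnorm(25), 5, 5)
  H <- matrix(rbinom(25, 1, 0.4) * rnorm(25), 5, 5)
  inf <- s_system(rep(1, 5), rep(1, 5), G, H)
  perm <- sample(5)
  rel <- function(mm) s_system(mm$alpha[perm], mm$beta[perm],
                               mm$G[perm, perm], mm$H[perm, perm])
  expect_equal(confusion(m, inf), confusion(rel(m), rel(inf)))
})

test_that("tpr_fpr computes the two rates with 0/0 = 0", {
  expect_equal(tpr_fpr(list(tp = 13, fp = 0, tn = 37, fn = 0)),
               c(tpr = 1, fpr = 0))
  expect_equal(tpr_fpr(list(tp = 10, fp = 2, tn = 35, fn = 3)),
               c(tpr = 10 / 13, fpr = 2 / 37))
  expect_equal(tpr_fpr(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               c(tpr = 0, fpr = 0))
})

test_that("roc_curve sorts by FPR and collapses duplicates", {
  ds <- s1_dataset(seed = 1)
  cfg <- ea_config(pop_size = 30, iterations = 150, n_runs = 1)
  fronts <- lapply(1:5, function(eq) run_equation(ds, eq, cfg, seed = eq))
  sw <- sweep_lambda(fronts, const_mult = ds$const_mult)
  roc <- roc_curve(sw, s1_model())
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_false(any(duplicated(roc[, c("fpr", "tpr")])))
})

test_that("dynamics discrepancy is zero at equality and symmetric", {
  m <- s1_model()
  x0s <- list(rep(1, 5), c(0.7, 1.2, 0.9, 1.1, 0.8))
  times <- seq(0, 0.2, length.out = 8)
  expect_equal(dynamics_discrepancy(m, m, x0s, times), rep(0, 5))

  m2 <- s_system(m$alpha * 1.1, m$beta, m$G, m$H)
  d12 <- dynamics_discrepancy(m, m2, x0s, times)
  d21 <- dynamics_discrepancy(m2, m, x0s, times)
  expect_equal(d12, d21)
  expect_true(all(d12 > 0))
})

test_that("the published S2 reconstruction reproduces the true dynamics", {
  # the reconstructed fermentation network (rates on the inferred scale,
  # folded with the known independent-variable multipliers) tracks the true
  # model closely relative to the signal range
  truth <- s2_model()
  G <- matrix(0, 5, 5)
  H <- matrix(0, 5, 5)
  G[1, 2] <- -0.0495
  G[2, 1] <- 0.5822; G[2, 5] <- 0.1835
  G[3, 2] <- 0.2768
  G[4, 3] <- 0.5777; G[4, 5] <- 0.0599
  G[5, 3] <- 0.3766; G[5, 4] <- 0.1770; G[5, 5] <- 0.0581
  H[1, 1] <- 0.5970; H[1, 5] <- 0.0427
  H[2, 2] <- 0.5368; H[2, 5] <- -0.0732
  H[3, 3] <- 0.3901; H[3, 5] <- 0.2565
  H[4, 3] <- -0.0779; H[4, 4] <- 0.3684
  H[5, 1] <- 0.2863; H[5, 2] <- 0.2728; H[5, 4] <- -0.0541; H[5, 5] <- 0.2691
  alpha <- c(0.9009, 1.1871, 0.5014, 0.1935, 0.8562)
  beta <- c(1.4985, 0.3927, 0.2515, 1.9370, 1.5422)
  cm <- const_multipliers(truth)
  recon <- s_system(alpha * cm[, 1], beta * cm[, 2], G, H)

  set.seed(21)
  x0s <- lapply(1:3, function(i) runif(5, 0.2, 2))
  times <- seq(0, 0.5, length.out = 15)
  rmse <- dynamics_discrepancy(truth, recon, x0s, times)
  rng <- apply(do.call(rbind, lapply(x0s, function(x0) {
    apply(ss_simulate(truth, x0, times)$values, 2, function(v) diff(range(v)))
  })), 2, max)
  expect_true(all(rmse / rng <= 0.15))
})
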