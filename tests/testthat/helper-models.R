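# Shared fixtures, built in code.

# one-component linear decay/production model dX/dt = a - b X
linear_model <- function(a = 2, b = 4) {
  s_system(alpha = a, beta = b, G = matrix(0, 1, 1), H = matrix(1, 1, 1))
}

# a model whose RHS is identically zero (production == degradation)
null_model <- function(n = 3) {
  G <- matrix(rnorm(n * n), n, n)
  s_system(alpha = rep(2, n), beta = rep(2, n), G = G, H = G)
}

# encode the true parameters of one S1 equation as a mixed solution
s1_true_solution <- function(eq) {
  m <- s1_model()
  bx <- as.integer(c(m$G[eq, ] != 0, m$H[eq, ] != 0))
  rx <- c(m$G[eq, ], m$H[eq, ], m$alpha[eq], m$beta[eq])
  mixed_solution(bx, rx, eq)
}

s1_true_mask <- function(eq) {
  m <- s1_model()
  as.integer(c(m$G[eq, ] != 0, m$H[eq, ] != 0))
}

# small noise-free S1 dataset at the benchmark protocol
s1_dataset <- function(seed = 1, slopes = "five_point") {
  generate_dataset(s1_model(), n_conditions = 4, n_times = 15,
                   t_span = c(0, 0.2), init_range = c(0.5, 1.5),
                   seed = seed, slopes = slopes)
}

# random evaluated solutions for one equation of a dataset
random_solutions <- function(ds, eq, n, seed = 1) {
  set.seed(seed)
  N <- ncol(ds$trajectories[[1]]$values)
  lapply(seq_len(n), function(i) {
    sol <- mixed_solution(rbinom(2 * N, 1, 0.5),
                          c(runif(2 * N, -3, 3), runif(2, 0, 10)), eq)
    sol$err <- fitting_error(sol, ds)
    sol
  })
}

# brute-force O(n^2) nondominated filter on (err, l0) pairs
brute_nondominated <- function(err, l0) {
  n <- length(err)
  vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) {
      j != i && dominates(c(err[j], l0[j]), c(err[i], l0[i]))
    }, TRUE))
  }, TRUE)
}

# brute-force dominance depth (rank 0 = nondominated)
brute_ranks <- function(err, l0) {
  n <- length(err)
  rank <- rep(NA_integer_, n)
  left <- rep(TRUE, n)
  r <- 0L
  while (any(left)) {
    idx <- which(left)
    nd <- vapply(idx, function(i) {
      !any(vapply(idx, function(j) {
        j != i && dominates(c(err[j], l0[j]), c(err[i], l0[i]))
      }, TRUE))
    }, TRUE)
    rank[idx[nd]] <- r
    left[idx[nd]] <- FALSE
    r <- r + 1L
  }
  rank
}
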