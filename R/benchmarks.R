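#' The five-component artificial benchmark network (S1)
#'
#' A fully dependent five-gene S-System widely used to benchmark network
#' inference: 13 of the 50 kinetic orders are nonzero. Rate constants are
#' `alpha = (5, 10, 10, 8, 10)` and `beta = (10, 10, 10, 10, 10)`.
#'
#' @return An [s_system()] with `N = 5` and no independent variables.
#' @export
s1_model <- function() {
  G <- matrix(0, 5, 5)
  H <- matrix(0, 5, 5)
  G[1, 3] <- 1.0;  G[1, 5] <- -1.0; H[1, 1] <- 2.0
  G[2, 1] <- 2.0;                   H[2, 2] <- 2.0
  G[3, 2] <- -1.0;                  H[3, 2] <- -1.0; H[3, 3] <- 2.0
  G[4, 3] <- 2.0;  G[4, 5] <- -1.0; H[4, 4] <- 2.0
  G[5, 4] <- 2.0;                   H[5, 5] <- 2.0
  s_system(alpha = c(5, 10, 10, 8, 10), beta = c(10, 10, 10, 10, 10),
           G = G, H = H)
}

#' The yeast fermentation pathway benchmark (S2)
#'
#' Five dependent metabolites -- glucose (X1), glucose-6-phosphate (X2),
#' fructose-1,6-diphosphate (X3), phosphoenolpyruvate (X4) and ATP (X5) --
#' driven by eight independent variables held at their steady-state activities:
#' glucose uptake (X6 = 47.5), hexokinase (X7 = 24.1), phosphofructokinase
#' (X8 = 53.9), glyceraldehyde-3-phosphate dehydrogenase (X9 = 91.4), pyruvate
#' kinase (X10 = 18.1), polysaccharide storage (X11 = 82.9), glycerol
#' production (X12 = 92.4) and ATPase (X13 = 1.0), all in mM/min.
#'
#' Variables written without an explicit exponent in the published rate laws
#' carry kinetic order 1; the full adopted parameterisation is recorded in the
#' shipped model file `system.file("extdata", "s2_model.txt", package =
#' "ssinfer")`, against which this constructor is golden-file tested.
#'
#' @return An [s_system()] with `N = 5` dependent and 8 independent variables.
#' @export
s2_model <- function() {
  G <- matrix(0, 5, 13)
  H <- matrix(0, 5, 13)
  # production terms
  G[1, 2] <- -0.0492; G[1, 6] <- 1
  G[2, 1] <- 0.5582;  G[2, 5] <- 0.0465; G[2, 7] <- 1
  G[3, 2] <- 0.4407;  G[3, 5] <- -0.2665; G[3, 8] <- 1
  G[4, 3] <- 0.5285;  G[4, 5] <- 0.0994; G[4, 9] <- 1
  G[5, 3] <- 0.2605;  G[5, 4] <- 0.152;  G[5, 5] <- 0.0739
  G[5, 9] <- 0.5;     G[5, 10] <- 0.5
  # degradation terms
  H[1, 1] <- 0.5582;  H[1, 5] <- 0.0456; H[1, 7] <- 1
  H[2, 2] <- 0.5097;  H[2, 5] <- -0.2218; H[2, 8] <- 0.8322; H[2, 11] <- 0.1678
  H[3, 3] <- 0.4506;  H[3, 4] <- 0.0441; H[3, 5] <- 0.092
  H[3, 9] <- 0.8547;  H[3, 12] <- 0.1453
  H[4, 3] <- -0.0075; H[4, 4] <- 0.304;  H[4, 5] <- 0.0484; H[4, 10] <- 1
  H[5, 1] <- 0.1962;  H[5, 2] <- 0.1791; H[5, 5] <- 0.2354
  H[5, 7] <- 0.3514;  H[5, 8] <- 0.2925; H[5, 11] <- 0.0589; H[5, 13] <- 0.297
  s_system(alpha = c(1.0006, 1.6497, 0.4536, 0.2365, 1.406),
           beta = c(1.6497, 0.5793, 0.2456, 2.0892, 2.9437),
           G = G, H = H,
           fixed_vars = c(47.5, 24.1, 53.9, 91.4, 18.1, 82.9, 92.4, 1.0))
}

#' Known constant multipliers of the independent-variable terms
#'
#' For a model with independent variables, the factor
#' \eqn{\prod_{j>N} X_j^{g_{ij}}} (and likewise for `H`) is a known constant
#' per equation. During decoupled inference, which searches only over the `N`
#' dependent variables, these factors multiply the production and degradation
#' terms so that the searched rate constants stay on the scale of the printed
#' model. For fully dependent systems both multipliers are 1.
#'
#' @param model An [s_system()].
#' @return `N x 2` matrix with columns `cg` (production) and `ch`
#'   (degradation).
#' @export
const_multipliers <- function(model) {
  N <- model$n_dep
  nf <- length(model$fixed_vars)
  if (nf == 0) return(cbind(cg = rep(1, N), ch = rep(1, N)))
  lf <- log(model$fixed_vars)
  idx <- N + seq_len(nf)
  cbind(cg = exp(drop(model$G[, idx, drop = FALSE] %*% lf)),
        ch = exp(drop(model$H[, idx, drop = FALSE] %*% lf)))
}

#' Generate a synthetic multi-condition time-course dataset
#'
#' Draws initial concentrations uniformly per component, simulates the model
#' at a uniform time grid for each condition, and estimates slopes. The
#' benchmark protocols are 15 time points over `[0, 0.2]` from 4 conditions
#' with initial concentrations in `U[0.5, 1.5]` for the artificial network,
#' and 15 points over `[0, 0.5]` from 10 conditions in `U[0.2, 2]` for the
#' fermentation pathway; the spans are chosen so the five-point stencil
#' resolves the fastest relaxation modes (see the methods vignette).
#'
#' @param model Generating [s_system()].
#' @param n_conditions Number of initial conditions.
#' @param n_times Number of uniformly spaced time points (at least 5).
#' @param t_span Length-2 interval of time.
#' @param init_range Length-2 positive interval for the uniform initial
#'   concentrations.
#' @param seed Integer seed; the dataset is bit-reproducible given it.
#' @param slopes `"five_point"` (estimated from the sampled trajectories, the
#'   realistic setting) or `"analytic"` (exact model right-hand sides, useful
#'   for oracle tests).
#' @return An `ss_dataset`: trajectories, per-trajectory slope matrices,
#'   `noise_rate`, `seed`, the source model, and the per-equation constant
#'   multipliers of its independent-variable terms.
#' @export
generate_dataset <- function(model, n_conditions, n_times, t_span, init_range,
                             seed, slopes = c("five_point", "analytic")) {
  slopes <- match.arg(slopes)
  stopifnot(n_times >= 5, length(t_span) == 2, length(init_range) == 2)
  if (init_range[1] <= 0) stop("init_range must be strictly positive")
  set.seed(seed)
  times <- seq(t_span[1], t_span[2], length.out = n_times)
  N <- model$n_dep
  trajs <- vector("list", n_conditions)
  for (cc in seq_len(n_conditions)) {
    x0 <- stats::runif(N, init_range[1], init_range[2])
    trajs[[cc]] <- tryCatch(
      ss_simulate(model, x0, times, condition_id = sprintf("c%d", cc)),
      error = function(e) stop(sprintf("condition c%d: %s", cc, conditionMessage(e))))
  }
  sl <- lapply(trajs, function(tr) {
    if (slopes == "analytic") analytic_slopes(model, tr) else five_point_slopes(tr)
  })
  structure(list(trajectories = trajs, slopes = sl, noise_rate = 0,
                 seed = seed, source_model = model,
                 const_mult = const_multipliers(model)),
            class = "ss_dataset")
}

#' Add multiplicative observation noise to a dataset
#'
#' Each observation is perturbed as \eqn{X (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \mathrm{rate}^2)} independently, clipped below at
#' `1e-6` to preserve positivity, and the five-point slopes are recomputed
#' from the noisy trajectories. `rate = 0` returns the input unchanged.
#'
#' @param ds An `ss_dataset`.
#' @param rate Nonnegative noise rate (standard deviation of the relative
#'   error); the benchmark protocols use 0, 0.05, 0.15 and 0.25.
#' @param seed Integer seed for the noise draws.
#' @return A new `ss_dataset` with noisy values and recomputed slopes.
#' @export
add_noise <- function(ds, rate, seed) {
  if (rate < 0) stop("noise rate must be nonnegative")
  if (rate == 0) return(ds)
  set.seed(seed)
  trajs <- lapply(ds$trajectories, function(tr) {
    eps <- matrix(stats::rnorm(length(tr$values), 0, rate),
                  nrow(tr$values), ncol(tr$values))
    tr$values <- pmax(tr$values * (1 + eps), 1e-6)
    tr
  })
  ds$trajectories <- trajs
  ds$slopes <- lapply(trajs, five_point_slopes)
  ds$noise_rate <- rate
  ds
}

#' @export
print.ss_dataset <- function(x, ...) {
  cat(sprintf(
    "ss_dataset: %d condition(s) x %d time point(s) x %d component(s), noise rate %g\n",
    length(x$trajectories), length(x$trajectories[[1]]$times),
    ncol(x$trajectories[[1]]$values), x$noise_rate))
  invisible(x)
}

#' Write / read a dataset as tab-separated text
#'
#' Columns: `condition`, `time`, then one column per dependent component
#' (`X1 ... XN`), with a single header line. Reading recomputes five-point
#' slopes from the stored trajectories, so a noise-free write/read round-trips
#' the values exactly.
#'
#' @param ds An `ss_dataset`.
#' @param path File path.
#' @param model Optional source model attached on read (restores the constant
#'   multipliers of its independent-variable terms).
#' @return `write_dataset_tsv` returns `path` invisibly; `read_dataset_tsv`
#'   returns an `ss_dataset`.
#' @export
write_dataset_tsv <- function(ds, path) {
  rows <- do.call(rbind, lapply(ds$trajectories, function(tr) {
    data.frame(condition = tr$condition_id, time = tr$times, tr$values,
               check.names = FALSE)
  }))
  names(rows) <- c("condition", "time",
                   paste0("X", seq_len(ncol(rows) - 2)))
  utils::write.table(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path, model = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  trajs <- lapply(split(df, factor(df$condition, levels = unique(df$condition))),
                  function(d) {
    structure(list(times = d$time,
                   values = unname(as.matrix(d[, -(1:2), drop = FALSE])),
                   condition_id = d$condition[1]),
              class = "ss_trajectory")
  })
  names(trajs) <- NULL
  cm <- if (!is.null(model)) const_multipliers(model) else
    cbind(cg = rep(1, ncol(trajs[[1]]$values)),
          ch = rep(1, ncol(trajs[[1]]$values)))
  structure(list(trajectories = trajs,
                 slopes = lapply(trajs, five_point_slopes),
                 noise_rate = NA_real_, seed = NA_integer_,
                 source_model = model, const_mult = cm),
            class = "ss_dataset")
}
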