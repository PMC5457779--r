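#' Construct an S-System model
#'
#' An S-System describes a biochemical network of `N` dependent components by
#' power-law ODEs
#' \deqn{dX_i/dt = \alpha_i \prod_j X_j^{g_{ij}} - \beta_i \prod_j X_j^{h_{ij}},}
#' where the products run over all `M` variables: the `N` dependent components
#' followed by `M - N` independent variables held at constant values
#' (e.g. enzyme activities at steady state). A kinetic order of zero means the
#' corresponding variable does not act on that term, so the nonzero pattern of
#' `G` and `H` *is* the network topology.
#'
#' @param alpha,beta Positive length-`N` rate constants of the production and
#'   degradation terms.
#' @param G,H `N x M` real matrices of kinetic orders (production/degradation).
#' @param fixed_vars Constant values of the `M - N` independent variables
#'   (empty for a fully dependent system).
#' @return An object of class `ssystem` with fields `n_dep`, `alpha`, `beta`,
#'   `G`, `H`, `fixed_vars`.
#' @examples
#' m <- s1_model()
#' ss_rhs(m, rep(1, 5))
#' @export
s_system <- function(alpha, beta, G, H, fixed_vars = numeric(0)) {
  G <- as.matrix(G)
  H <- as.matrix(H)
  N <- length(alpha)
  M <- N + length(fixed_vars)
  stopifnot(length(beta) == N, nrow(G) == N, nrow(H) == N,
            ncol(G) == M, ncol(H) == M)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("alpha must be positive")
  if (any(!is.finite(beta)) || any(beta <= 0)) stop("beta must be positive")
  if (any(!is.finite(G)) || any(!is.finite(H))) stop("G and H must be finite")
  if (length(fixed_vars) && any(fixed_vars <= 0))
    stop("fixed_vars must be positive")
  structure(
    list(n_dep = N, alpha = as.numeric(alpha), beta = as.numeric(beta),
         G = unname(G), H = unname(H), fixed_vars = as.numeric(fixed_vars)),
    class = "ssystem")
}

#' @export
print.ssystem <- function(x, ...) {
  M <- x$n_dep + length(x$fixed_vars)
  cat(sprintf("S-System: %d dependent component(s), %d variable(s) total\n",
              x$n_dep, M))
  cat(sprintf("  nonzero kinetic orders: %d of %d (dependent part: %d of %d)\n",
              sum(x$G != 0) + sum(x$H != 0), 2 * x$n_dep * M,
              sum(x$G[, seq_len(x$n_dep), drop = FALSE] != 0) +
                sum(x$H[, seq_len(x$n_dep), drop = FALSE] != 0),
              2 * x$n_dep^2))
  invisible(x)
}

#' Evaluate the S-System right-hand side
#'
#' @param model An [s_system()] model.
#' @param x Strictly positive state vector of length `M` (dependent components
#'   first, then independent variables), or of length `N` in which case the
#'   model's `fixed_vars` are appended.
#' @return Length-`N` vector of time derivatives of the dependent components.
#' @export
ss_rhs <- function(model, x) {
  N <- model$n_dep
  M <- N + length(model$fixed_vars)
  if (length(x) == N && M > N) x <- c(x, model$fixed_vars)
  if (length(x) != M) stop("state has wrong length")
  if (any(!is.finite(x)) || any(x <= 0)) stop("state must be strictly positive")
  lx <- log(x)
  drop(model$alpha * exp(model$G %*% lx) - model$beta * exp(model$H %*% lx))
}

#' Simulate an S-System trajectory
#'
#' Integrates the dependent components with an adaptive explicit Runge-Kutta
#' scheme (`deSolve::ode`, method `"ode45"`, `rtol = 1e-8`, `atol = 1e-10`)
#' and samples the dense solution at the requested grid. The integration is
#' carried out in log-state space (`z = log X`), which keeps every trial step
#' strictly positive -- power laws with real exponents are only defined on the
#' positive orthant, and near-zero components would otherwise make the
#' integrator overshoot below it.
#'
#' @param model An [s_system()] model.
#' @param x0 Strictly positive initial concentrations of the `N` dependent
#'   components.
#' @param times Strictly increasing time grid; the first entry is the initial
#'   time.
#' @param condition_id Label stored with the trajectory.
#' @return An `ss_trajectory`: list with `times`, a `T x N` matrix `values`,
#'   and `condition_id`.
#' @export
ss_simulate <- function(model, x0, times, condition_id = "c1") {
  N <- model$n_dep
  stopifnot(length(x0) == N)
  if (any(x0 <= 0)) stop("x0 must be strictly positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  deriv <- function(t, z, parms) {
    # clamp guards overflow on rejected trial steps only; accepted steps of a
    # positive trajectory stay far inside the window
    x <- exp(pmin(pmax(z, -30), 30))
    list(ss_rhs(model, x) / x)
  }
  sol <- deSolve::ode(y = log(as.numeric(x0)), times = times, func = deriv,
                      parms = NULL, method = "ode45",
                      rtol = 1e-8, atol = 1e-10)
  vals <- exp(unname(as.matrix(sol[, -1, drop = FALSE])))
  bad <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "trajectory left the positive orthant: component %d at t = %g",
      bad[1, 2], times[bad[1, 1]]))
  }
  structure(list(times = as.numeric(times), values = vals,
                 condition_id = condition_id),
            class = "ss_trajectory")
}

#' Write / read an S-System model file
#'
#' Flat key-value text format: scalar counts, then `alpha`, `beta`, one `G`/`H`
#' row per equation, and `fixed_vars`. Round-trips exactly (values are written
#' with full precision).
#'
#' @param model An [s_system()].
#' @param path File path.
#' @return `write_model` returns `path` invisibly; `read_model` returns the
#'   model.
#' @export
write_model <- function(model, path) {
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    sprintf("n_dep %d", model$n_dep),
    sprintf("n_fixed %d", length(model$fixed_vars)),
    paste("alpha", fmt(model$alpha)),
    paste("beta", fmt(model$beta)),
    vapply(seq_len(model$n_dep),
           function(i) paste(sprintf("G%d", i), fmt(model$G[i, ])), ""),
    vapply(seq_len(model$n_dep),
           function(i) paste(sprintf("H%d", i), fmt(model$H[i, ])), ""))
  if (length(model$fixed_vars))
    lines <- c(lines, paste("fixed_vars", fmt(model$fixed_vars)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- lapply(strsplit(lines, "[[:space:]]+"), function(p) {
    list(key = p[[1]], val = as.numeric(p[-1]))
  })
  get <- function(key) {
    hit <- Filter(function(e) identical(e$key, key), kv)
    if (!length(hit)) stop(sprintf("model file is missing field '%s'", key))
    hit[[1]]$val
  }
  N <- as.integer(get("n_dep"))
  nf <- as.integer(get("n_fixed"))
  G <- t(vapply(seq_len(N), function(i) get(sprintf("G%d", i)),
                numeric(N + nf)))
  H <- t(vapply(seq_len(N), function(i) get(sprintf("H%d", i)),
                numeric(N + nf)))
  fv <- if (nf > 0) get("fixed_vars") else numeric(0)
  s_system(get("alpha"), get("beta"), G, H, fv)
}
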