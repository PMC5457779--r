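#' Search bounds for one decoupled equation
#'
#' @param kinetic Length-2 interval for candidate kinetic orders (`[-3, 3]`
#'   for the artificial benchmark, `[-1, 1]` for the fermentation pathway).
#' @param rate Length-2 interval for the rate constants `alpha`, `beta`
#'   (`[0, 10]` and `[0, 3]` respectively); the lower bound must be
#'   nonnegative.
#' @return An `ss_bounds` object.
#' @export
ss_bounds <- function(kinetic = c(-3, 3), rate = c(0, 10)) {
  stopifnot(length(kinetic) == 2, length(rate) == 2,
            kinetic[1] < kinetic[2], rate[1] < rate[2])
  if (rate[1] < 0) stop("rate lower bound must be nonnegative")
  structure(list(kinetic = as.numeric(kinetic), rate = as.numeric(rate)),
            class = "ss_bounds")
}

bounds_vectors <- function(bounds, N) {
  list(lo = c(rep(bounds$kinetic[1], 2 * N), rep(bounds$rate[1], 2)),
       hi = c(rep(bounds$kinetic[2], 2 * N), rep(bounds$rate[2], 2)))
}

#' Construct a mixed binary/real candidate solution for one equation
#'
#' A candidate for equation `i` pairs a bit vector `bx` of length `2N`
#' (connection indicators for `g_i1..g_iN, h_i1..h_iN`) with a real vector
#' `rx` of length `2N + 2` (candidate kinetic orders followed by `alpha_i`,
#' `beta_i`). The decoded kinetic order is `bx * rx`, so the number of network
#' connections is exactly `sum(bx)` -- no magnitude threshold is ever applied.
#'
#' @param bx Integer 0/1 vector of length `2N`.
#' @param rx Numeric vector of length `2N + 2`.
#' @param eq_index Which equation the candidate describes.
#' @param err Optional cached fitting error.
#' @return An `ss_solution`.
#' @export
mixed_solution <- function(bx, rx, eq_index, err = NA_real_) {
  bx <- as.integer(bx)
  if (length(rx) != length(bx) + 2) stop("rx must have length 2N + 2")
  if (!all(bx %in% c(0L, 1L))) stop("bx must be 0/1")
  structure(list(bx = bx, rx = as.numeric(rx), eq_index = eq_index,
                 err = err, l0 = sum(bx)),
            class = "ss_solution")
}

#' Decode a mixed solution into equation parameters
#'
#' @param sol An [mixed_solution()].
#' @return List with `g`, `h` (length-`N` kinetic orders, masked by the bits),
#'   `alpha` and `beta`.
#' @export
decode <- function(sol) {
  N <- length(sol$bx) / 2
  list(g = sol$bx[1:N] * sol$rx[1:N],
       h = sol$bx[N + 1:N] * sol$rx[N + 1:N],
       alpha = sol$rx[2 * N + 1], beta = sol$rx[2 * N + 2])
}

# Stack the per-equation regression problem: log-concentrations of all points
# across conditions, the slope vector of component i, and the equation's
# constant multipliers.
eq_problem <- function(ds, eq_index) {
  vals <- do.call(rbind, lapply(ds$trajectories, function(tr) tr$values))
  if (any(vals <= 0)) stop("observed concentrations must be strictly positive")
  S <- unlist(lapply(ds$slopes, function(s) s[, eq_index]), use.names = FALSE)
  list(logX = log(pmax(vals, 1e-12)), S = S,
       cg = ds$const_mult[eq_index, 1], ch = ds$const_mult[eq_index, 2])
}

#' Slope-fitting error of a candidate equation
#'
#' The first objective of the biobjective model: the sum over all conditions
#' and time points of the squared difference between the dataset's estimated
#' slopes \eqn{S_i} and the candidate right-hand side
#' \eqn{\hat S_i = \alpha_i c_g \prod_j X_j^{g_j} - \beta_i c_h \prod_j
#' X_j^{h_j}} evaluated at the *observed* concentrations. Decoupling means the
#' other components enter as data; no candidate ODE is ever integrated.
#'
#' @param sol An [mixed_solution()].
#' @param ds An `ss_dataset`.
#' @return Nonnegative scalar.
#' @export
fitting_error <- function(sol, ds) {
  pb <- eq_problem(ds, sol$eq_index)
  p <- decode(sol)
  shat <- p$alpha * pb$cg * exp(drop(pb$logX %*% p$g)) -
    p$beta * pb$ch * exp(drop(pb$logX %*% p$h))
  sum((pb$S - shat)^2)
}

#' Connection count (L0 norm) of a candidate equation
#'
#' @param sol An [mixed_solution()].
#' @return Integer in `0..2N`: the number of set connection bits.
#' @export
l0_norm <- function(sol) sum(sol$bx)

#' Pareto dominance between two objective pairs
#'
#' Both objectives are minimised: `a` dominates `b` when it is no worse in
#' both components and strictly better in at least one.
#'
#' @param a,b Length-2 numeric objective vectors `(err, l0)`.
#' @return Logical.
#' @export
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Reduce a set of candidate solutions to a nondominated front
#'
#' Keeps, for each distinct connection count, the best-error member, then
#' drops members dominated by a sparser one, and sorts by ascending `l0`.
#' Along the resulting front the error is strictly decreasing as the
#' connection count grows.
#'
#' @param solutions List of [mixed_solution()]s for the same equation, with
#'   cached `err`.
#' @return An `ss_front`: list with `solutions` and `eq_index`.
#' @export
nondominated_filter <- function(solutions) {
  if (!length(solutions)) {
    return(structure(list(solutions = list(), eq_index = NA_integer_),
                     class = "ss_front"))
  }
  eq <- solutions[[1]]$eq_index
  err <- vapply(solutions, function(s) s$err, 0)
  l0 <- vapply(solutions, function(s) s$l0, 0)
  keep <- integer(0)
  for (lv in sort(unique(l0))) {
    cand <- which(l0 == lv)
    keep <- c(keep, cand[which.min(err[cand])])
  }
  # ascending l0: drop any level not strictly improving the error
  best <- Inf
  out <- integer(0)
  for (k in keep) {
    if (err[k] < best) {
      out <- c(out, k)
      best <- err[k]
    }
  }
  structure(list(solutions = solutions[out], eq_index = eq),
            class = "ss_front")
}

#' @export
print.ss_front <- function(x, ...) {
  cat(sprintf("ss_front: equation %s, %d nondominated solution(s)\n",
              x$eq_index, length(x$solutions)))
  if (length(x$solutions)) {
    df <- data.frame(l0 = vapply(x$solutions, function(s) s$l0, 0),
                     err = vapply(x$solutions, function(s) s$err, 0))
    print(df, row.names = FALSE)
  }
  invisible(x)
}

front_err <- function(front) vapply(front$solutions, function(s) s$err, 0)
front_l0 <- function(front) vapply(front$solutions, function(s) s$l0, 0)
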