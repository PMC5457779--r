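#' Five-point finite-difference slope estimates
#'
#' Estimates \eqn{dX_i/dt} at every sampled time point from the trajectory
#' alone, using the five-point central stencil
#' \deqn{(-f_{k+2} + 8 f_{k+1} - 8 f_{k-1} + f_{k-2}) / (12\,\Delta t)}
#' at interior points and one-sided five-point stencils of the same
#' (fourth) order at the two points on each boundary. All stencils are exact
#' for polynomials of degree at most four. The grid must be uniform.
#'
#' @param traj An `ss_trajectory` (or any list with `times` and `values`).
#' @return A `T x N` matrix of slope estimates with attribute
#'   `provenance = "five_point"`.
#' @seealso [analytic_slopes()] for exact slopes when the generating model is
#'   known.
#' @export
five_point_slopes <- function(traj) {
  times <- traj$times
  f <- traj$values
  T_ <- length(times)
  if (T_ < 5) stop("at least 5 time points are required")
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt)))
    stop("time grid must be uniform")
  h <- dt[1]
  S <- matrix(NA_real_, T_, ncol(f))
  # one-sided / offset stencils at the boundaries, central elsewhere
  S[1, ] <- (-25 * f[1, ] + 48 * f[2, ] - 36 * f[3, ] + 16 * f[4, ] - 3 * f[5, ]) / (12 * h)
  S[2, ] <- (-3 * f[1, ] - 10 * f[2, ] + 18 * f[3, ] - 6 * f[4, ] + f[5, ]) / (12 * h)
  if (T_ > 4) {
    for (k in seq(3, T_ - 2)) {
      S[k, ] <- (-f[k + 2, ] + 8 * f[k + 1, ] - 8 * f[k - 1, ] + f[k - 2, ]) / (12 * h)
    }
  }
  S[T_ - 1, ] <- (3 * f[T_, ] + 10 * f[T_ - 1, ] - 18 * f[T_ - 2, ] +
                    6 * f[T_ - 3, ] - f[T_ - 4, ]) / (12 * h)
  S[T_, ] <- (25 * f[T_, ] - 48 * f[T_ - 1, ] + 36 * f[T_ - 2, ] -
                16 * f[T_ - 3, ] + 3 * f[T_ - 4, ]) / (12 * h)
  attr(S, "provenance") <- "five_point"
  S
}

#' Exact slopes from a known model
#'
#' Evaluates the model right-hand side at every sampled state, so the slope
#' set carries no discretisation error. Mainly useful in tests and sanity
#' checks: with these slopes the fitting error of the true parameters is
#' exactly zero.
#'
#' @param model The generating [s_system()].
#' @param traj An `ss_trajectory` sampled from that model.
#' @return A `T x N` slope matrix with attribute `provenance = "analytic"`.
#' @export
analytic_slopes <- function(model, traj) {
  S <- t(apply(traj$values, 1, function(x) ss_rhs(model, x)))
  if (model$n_dep == 1) S <- matrix(as.numeric(S), ncol = 1)
  S <- unname(S)
  attr(S, "provenance") <- "analytic"
  S
}
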