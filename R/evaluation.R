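#' Confusion counts of an inferred topology against the truth
#'
#' An entry is predicted positive iff its inferred kinetic order is nonzero
#' (equivalently, its connection bit was set); truth positives are the
#' nonzero kinetic orders of the generating model. Counts run over the
#' `2 N^2` dependent-variable entries of `G` and `H`; rate constants are
#' excluded (they are always present in the model form), and independent
#' variables of the truth are not scored. A supplementary `sign_tp` counts
#' the true positives whose sign also agrees, without affecting the rates.
#'
#' @param truth,inferred [s_system()] models with the same number of
#'   dependent components.
#' @return List with integer `tp`, `fp`, `tn`, `fn` (summing to `2 N^2`) and
#'   `sign_tp`.
#' @export
confusion <- function(truth, inferred) {
  N <- truth$n_dep
  if (inferred$n_dep != N) stop("models differ in dependent dimension")
  dep <- seq_len(N)
  tG <- truth$G[, dep, drop = FALSE]
  tH <- truth$H[, dep, drop = FALSE]
  iG <- inferred$G[, dep, drop = FALSE]
  iH <- inferred$H[, dep, drop = FALSE]
  tpos <- c(tG != 0, tH != 0)
  ipos <- c(iG != 0, iH != 0)
  sign_ok <- c(sign(tG) == sign(iG), sign(tH) == sign(iH))
  list(tp = sum(tpos & ipos), fp = sum(!tpos & ipos),
       tn = sum(!tpos & !ipos), fn = sum(tpos & !ipos),
       sign_tp = sum(tpos & ipos & sign_ok))
}

#' True and false positive rates from confusion counts
#'
#' `TPR = TP / (TP + FN)` and `FPR = FP / (TN + FP)`, with `0/0` defined
#' as 0.
#'
#' @param cc A list from [confusion()].
#' @return Named numeric vector `c(tpr, fpr)`.
#' @export
tpr_fpr <- function(cc) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  c(tpr = safe(cc$tp, cc$tp + cc$fn), fpr = safe(cc$fp, cc$tn + cc$fp))
}

#' ROC curve over a selection-weight sweep
#'
#' Scores every distinct network of the sweep against the truth and returns
#' the `(FPR, TPR)` pairs sorted by FPR then TPR, duplicates collapsed (the
#' first achieving weight is kept).
#'
#' @param sweep An `ss_sweep` from [sweep_lambda()].
#' @param truth The generating [s_system()].
#' @return Data frame with columns `fpr`, `tpr`, `lambda`.
#' @export
roc_curve <- function(sweep, truth) {
  rows <- do.call(rbind, lapply(sweep$nets, function(n) {
    r <- tpr_fpr(confusion(truth, n$model))
    data.frame(fpr = r[["fpr"]], tpr = r[["tpr"]], lambda = min(n$lambdas))
  }))
  rows <- rows[order(rows$fpr, rows$tpr, rows$lambda), , drop = FALSE]
  dup <- duplicated(rows[, c("fpr", "tpr")])
  rows <- rows[!dup, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Trajectory discrepancy between two models
#'
#' Simulates both models from each initial condition over the same grid and
#' returns the per-component root-mean-square difference, averaged over
#' conditions. Conditions where either simulation fails are excluded with a
#' warning. Symmetric in its two model arguments.
#'
#' @param model_a,model_b [s_system()] models over the same dependent
#'   components.
#' @param x0s List (or matrix rows) of positive initial-condition vectors.
#' @param times Uniform or non-uniform increasing time grid.
#' @return Length-`N` numeric vector of RMSEs (`NA` if no condition could be
#'   simulated).
#' @export
dynamics_discrepancy <- function(model_a, model_b, x0s, times) {
  if (is.matrix(x0s)) x0s <- split(x0s, row(x0s)[, 1])
  N <- model_a$n_dep
  acc <- matrix(NA_real_, length(x0s), N)
  for (cc in seq_along(x0s)) {
    tr <- tryCatch({
      ta <- ss_simulate(model_a, x0s[[cc]], times)
      tb <- ss_simulate(model_b, x0s[[cc]], times)
      sqrt(colMeans((ta$values - tb$values)^2))
    }, error = function(e) {
      warning(sprintf("condition %d excluded: %s", cc, conditionMessage(e)))
      NULL
    })
    if (!is.null(tr)) acc[cc, ] <- tr
  }
  colMeans(acc, na.rm = TRUE)
}
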