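#' Configuration of the mixed-variable multiobjective EA
#'
#' Defaults follow the benchmark protocol: population 100, 2000 generations,
#' 10 independent runs per equation, parent-sourcing probabilities
#' `p1 = 0.8` (population/old-population vs. archive), `p2 = 0.7` (parent
#' reals vs. the per-individual real pool) and `p3 = 0.8` (gbest from the
#' population vs. the archive). The differential-evolution constants
#' (`de_f = 0.5`, `de_cr = 0.9`) and the binary-recombination rates
#' (`keep_prob = 0.9` for inheriting the first parent's bit where the other
#' two agree; disagreeing bits flip with probability `0.5 * de_cr`) are
#' standard defaults, exposed here so alternatives can be swapped in.
#'
#' @param pop_size Population (and archive, and pool) size; must exceed
#'   `2N + 1`.
#' @param iterations Number of generations.
#' @param n_runs Independent restarts per equation whose fronts are merged.
#' @param p1,p2,p3 Sourcing probabilities in `[0, 1]` (see above).
#' @param de_f DE/rand/1 scale factor (the centre of the dither interval).
#' @param de_f_jitter Half-width of the uniform dither on the scale factor:
#'   each offspring uses `F ~ U(de_f - de_f_jitter, de_f + de_f_jitter)`.
#'   Dithering is standard differential-evolution practice and markedly
#'   deepens the per-topology refinement of the real parameters; set to 0 for
#'   a fixed scale.
#' @param de_cr Binomial crossover rate.
#' @param keep_prob Binary recombination: probability of inheriting the first
#'   parent's bit where the other two parents agree.
#' @param flip_prob Binary recombination: probability of flipping the first
#'   parent's bit where the other two parents disagree (default `0.5 *
#'   de_cr`).
#' @param max_dup Maximum number of members sharing one bitstring that the
#'   truncated population may hold (0 disables the cap). Near-clone chains of
#'   a single topology -- the empty one especially -- otherwise crowd out the
#'   sparse-topology chains whose real parameters still need refining.
#' @param bounds An [ss_bounds()].
#' @return An `ea_config` object.
#' @export
ea_config <- function(pop_size = 100, iterations = 2000, n_runs = 10,
                      p1 = 0.8, p2 = 0.7, p3 = 0.8,
                      de_f = 0.5, de_f_jitter = 0.3, de_cr = 0.9,
                      keep_prob = 0.9, flip_prob = 0.5 * de_cr,
                      max_dup = 5, bounds = ss_bounds()) {
  stopifnot(pop_size > 2, iterations >= 1, n_runs >= 1,
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, p3 >= 0, p3 <= 1,
            de_f > 0, de_f_jitter >= 0, de_f_jitter < de_f,
            de_cr >= 0, de_cr <= 1,
            keep_prob >= 0, keep_prob <= 1, flip_prob >= 0, flip_prob <= 1,
            max_dup >= 0, inherits(bounds, "ss_bounds"))
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 n_runs = as.integer(n_runs),
                 p1 = p1, p2 = p2, p3 = p3,
                 de_f = de_f, de_f_jitter = de_f_jitter, de_cr = de_cr,
                 keep_prob = keep_prob, flip_prob = flip_prob,
                 max_dup = as.integer(max_dup), bounds = bounds),
            class = "ea_config")
}

#' Binary recombination of three parent bitstrings
#'
#' Per bit: where the second and third parents agree, the offspring inherits
#' the first parent's bit with probability `keep_prob` and the agreed value
#' otherwise; where they disagree, the first parent's bit is flipped with
#' probability `flip_prob` and kept otherwise.
#'
#' @param b1,b2,b3 Equal-length 0/1 integer vectors.
#' @param keep_prob,flip_prob Per-bit rates (defaults 0.9 and `0.5 * 0.9`,
#'   matching the default `de_cr`).
#' @return A 0/1 integer vector of the same length.
#' @export
binary_recombine <- function(b1, b2, b3, keep_prob = 0.9, flip_prob = 0.45) {
  cpp_binary_recombine(as.integer(b1), as.integer(b2), as.integer(b3),
                       keep_prob, flip_prob)
}

#' DE/rand/1 real recombination with binomial crossover and reflection
#'
#' The mutant is `r1 + F (r2 - r3)`; each coordinate of the offspring takes
#' the mutant value with probability `CR` (one coordinate is guaranteed to)
#' and `r1`'s value otherwise, and is reflected into the box bounds.
#'
#' @param r1,r2,r3 Equal-length numeric vectors.
#' @param de_f,de_cr DE scale and crossover rate.
#' @param lo,hi Per-coordinate bounds.
#' @return A numeric vector within the bounds.
#' @export
real_recombine <- function(r1, r2, r3, de_f = 0.5, de_cr = 0.9, lo, hi) {
  cpp_real_recombine(r1, r2, r3, de_f, de_cr, lo, hi)
}

#' Rank and truncate an intermediate population
#'
#' Fast nondominated sorting on `(err, l0)` (dominance depth), then within
#' each rank ascending `l0`, ties broken by lower error and then input order.
#' The first `pop_size` solutions survive; the remainder is handed to the
#' archive.
#'
#' @param solutions List of evaluated [mixed_solution()]s.
#' @param pop_size Number of survivors.
#' @return List with `pop` (survivors) and `leftovers`.
#' @export
rank_and_truncate <- function(solutions, pop_size) {
  err <- vapply(solutions, function(s) s$err, 0)
  l0 <- as.integer(vapply(solutions, function(s) s$l0, 0))
  ord <- cpp_truncate_order(err, l0)
  n <- min(pop_size, length(solutions))
  list(pop = solutions[ord[seq_len(n)]],
       leftovers = if (length(solutions) > n) solutions[ord[-seq_len(n)]] else list())
}

#' Update a fixed-size archive of promising topologies
#'
#' The archive favours topology diversity: a candidate whose bitstring is
#' already present competes only against the worst-error holder of that
#' bitstring; a candidate with a novel bitstring evicts the worst-error member
#' among duplicated bitstrings (or the worst member overall when all
#' bitstrings are unique), and only if it improves on it. The archive size
#' never changes.
#'
#' @param arc List of [mixed_solution()]s (the archive).
#' @param candidate An evaluated [mixed_solution()].
#' @return The updated archive (same length).
#' @export
update_archive <- function(arc, candidate) {
  B <- do.call(rbind, lapply(arc, function(s) s$bx))
  R <- do.call(rbind, lapply(arc, function(s) s$rx))
  err <- vapply(arc, function(s) s$err, 0)
  out <- cpp_update_archive(B, R, err, candidate$bx, candidate$rx, candidate$err)
  lapply(seq_along(arc), function(m) {
    mixed_solution(out$bits[m, ], out$reals[m, ], arc[[m]]$eq_index,
                   err = out$err[m])
  })
}

#' Infer the nondominated front of one decoupled equation
#'
#' Runs the mixed-variable MOEA (population initialisation, recombination,
#' nondominated sorting with L0-ascending truncation, archive and real-pool
#' updating) for a fixed number of generations and returns the nondominated
#' filter of the final population united with the archive. Deterministic
#' given `seed`.
#'
#' @param ds An `ss_dataset`.
#' @param eq_index Which equation (component) to infer.
#' @param config An [ea_config()].
#' @param seed Integer seed.
#' @return An `ss_front`.
#' @export
run_equation <- function(ds, eq_index, config = ea_config(), seed = 1) {
  pb <- eq_problem(ds, eq_index)
  N <- ncol(pb$logX)
  if (config$pop_size <= 2 * N + 1) stop("pop_size must exceed 2N + 1")
  bv <- bounds_vectors(config$bounds, N)
  set.seed(seed)
  res <- cpp_run_equation(pb$logX, pb$S, pb$cg, pb$ch,
                          config$pop_size, config$iterations,
                          config$p1, config$p2, config$p3,
                          config$de_f, config$de_cr,
                          config$keep_prob, config$flip_prob,
                          bv$lo, bv$hi, config$de_f_jitter, config$max_dup)
  sols <- lapply(seq_len(nrow(res$bits)), function(i) {
    mixed_solution(res$bits[i, ], res$reals[i, ], eq_index, err = res$err[i])
  })
  nondominated_filter(sols)
}

#' Merge nondominated fronts from independent runs
#'
#' @param fronts List of `ss_front`s for the same equation.
#' @return The nondominated filter of the union of all members.
#' @export
merge_runs <- function(fronts) {
  eq <- unique(vapply(fronts, function(f) f$eq_index, 0))
  if (length(eq) != 1) stop("fronts must describe the same equation")
  nondominated_filter(do.call(c, lapply(fronts, function(f) f$solutions)))
}

#' Derive a child seed for one (equation, run) job
#'
#' One global seed fans out deterministically so any single equation/run can
#' be reproduced in isolation: `(seed + 97003 * eq + 101 * run) mod
#' (2^31 - 1)`.
#'
#' @param seed Global integer seed.
#' @param eq_index Equation index.
#' @param run Run number.
#' @return An integer seed.
#' @export
child_seed <- function(seed, eq_index, run = 1) {
  as.integer((as.double(seed) + 97003 * eq_index + 101 * run) %% 2147483647)
}

#' Infer one equation with multiple merged restarts
#'
#' @inheritParams run_equation
#' @return An `ss_front` merged over `config$n_runs` seeded restarts.
#' @export
infer_equation <- function(ds, eq_index, config = ea_config(), seed = 1) {
  fronts <- lapply(seq_len(config$n_runs), function(r) {
    run_equation(ds, eq_index, config, seed = child_seed(seed, eq_index, r))
  })
  merge_runs(fronts)
}

#' Infer all equations of a dataset
#'
#' @inheritParams run_equation
#' @return List of `N` merged `ss_front`s, one per equation.
#' @export
infer_all <- function(ds, config = ea_config(), seed = 1) {
  N <- ncol(ds$trajectories[[1]]$values)
  lapply(seq_len(N), function(i) infer_equation(ds, i, config, seed))
}
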