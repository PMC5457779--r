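#' Write / read per-equation fronts as JSON
#'
#' Each front member is stored with its bitstring (as a string of 0/1), real
#' vector, cached error and connection count; re-reading restores the fronts
#' exactly.
#'
#' @param fronts List of `ss_front`s.
#' @param path File path.
#' @return `write_fronts_json` returns `path` invisibly; `read_fronts_json`
#'   returns the list of fronts.
#' @export
write_fronts_json <- function(fronts, path) {
  payload <- lapply(fronts, function(f) {
    list(eq_index = f$eq_index,
         solutions = lapply(f$solutions, function(s) {
           list(bx = paste(s$bx, collapse = ""), rx = s$rx,
                err = s$err, l0 = s$l0)
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fronts_json
#' @export
read_fronts_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(f) {
    sols <- lapply(f$solutions, function(s) {
      mixed_solution(as.integer(strsplit(s$bx, "")[[1]]),
                     unlist(s$rx), f$eq_index, err = s$err)
    })
    structure(list(solutions = sols, eq_index = f$eq_index),
              class = "ss_front")
  })
}

#' Write / read a network parameter table as CSV
#'
#' One row per equation in the standard layout: `i`, `alpha`, `g_1..g_N`,
#' `beta`, `h_1..h_N`.
#'
#' @param model An [s_system()] over dependent components only.
#' @param path File path.
#' @return `write_network_csv` returns `path` invisibly; `read_network_csv`
#'   returns the model.
#' @export
write_network_csv <- function(model, path) {
  N <- model$n_dep
  df <- data.frame(i = seq_len(N), alpha = model$alpha,
                   model$G[, seq_len(N), drop = FALSE],
                   beta = model$beta,
                   model$H[, seq_len(N), drop = FALSE])
  names(df) <- c("i", "alpha", paste0("g", seq_len(N)),
                 "beta", paste0("h", seq_len(N)))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(path) {
  df <- utils::read.csv(path)
  N <- (ncol(df) - 3) / 2
  s_system(df$alpha, df$beta,
           as.matrix(df[, paste0("g", seq_len(N))]),
           as.matrix(df[, paste0("h", seq_len(N))]))
}

benchmark_protocol <- function(benchmark) {
  switch(benchmark,
    s1 = list(model = s1_model(), n_conditions = 4, n_times = 15,
              t_span = c(0, 0.2), init_range = c(0.5, 1.5),
              bounds = ss_bounds(kinetic = c(-3, 3), rate = c(0, 10))),
    s2 = list(model = s2_model(), n_conditions = 10, n_times = 15,
              t_span = c(0, 0.5), init_range = c(0.2, 2.0),
              bounds = ss_bounds(kinetic = c(-1, 1), rate = c(0, 3))),
    stop(sprintf("unknown benchmark '%s'", benchmark)))
}

#' Run a benchmark inference end to end
#'
#' Generates the synthetic dataset for the requested benchmark protocol
#' (optionally with multiplicative noise), infers every equation with the
#' merged multi-run MOEA, applies the automatic selection procedure, and
#' scores the result against the generating model. With `out_dir` set, all
#' artifacts are written: the dataset (TSV), the merged fronts (JSON), the
#' sweep and ROC tables and final network (CSV), and a JSON manifest holding
#' the configuration and seeds.
#'
#' @param benchmark `"s1"` (artificial five-gene network) or `"s2"` (yeast
#'   fermentation pathway).
#' @param noise_rate Multiplicative noise rate (0 for noise-free).
#' @param config An [ea_config()]; its `bounds` are overridden by the
#'   benchmark protocol unless `keep_bounds = TRUE`.
#' @param seed Global seed; fans out per equation/run via [child_seed()].
#' @param out_dir Optional output directory.
#' @param keep_bounds Keep `config$bounds` instead of the protocol bounds.
#' @return List with `dataset`, `fronts`, `result` (an `ss_inference`),
#'   `confusion`, `rates` (TPR/FPR), `roc`, and `manifest`.
#' @export
run_benchmark <- function(benchmark = c("s1", "s2"), noise_rate = 0,
                          config = ea_config(), seed = 1, out_dir = NULL,
                          keep_bounds = FALSE) {
  benchmark <- match.arg(benchmark)
  proto <- benchmark_protocol(benchmark)
  if (!keep_bounds) config$bounds <- proto$bounds
  stage <- "generate"
  res <- tryCatch({
    ds <- generate_dataset(proto$model, proto$n_conditions, proto$n_times,
                           proto$t_span, proto$init_range, seed = seed)
    if (noise_rate > 0) ds <- add_noise(ds, noise_rate, seed = seed + 1)
    stage <- "infer"
    fronts <- infer_all(ds, config, seed)
    stage <- "select"
    inf <- asp(fronts, const_mult = ds$const_mult)
    stage <- "evaluate"
    cc <- confusion(proto$model, inf$model)
    list(dataset = ds, fronts = fronts, result = inf, confusion = cc,
         rates = tpr_fpr(cc),
         roc = roc_curve(inf$sweep, proto$model))
  }, error = function(e) {
    stop(sprintf("benchmark stage '%s' failed: %s", stage,
                 conditionMessage(e)))
  })
  manifest <- list(
    benchmark = benchmark, noise_rate = noise_rate, seed = seed,
    pop_size = config$pop_size, iterations = config$iterations,
    n_runs = config$n_runs,
    p = c(config$p1, config$p2, config$p3),
    de = c(config$de_f, config$de_cr), keep_prob = config$keep_prob,
    bounds = list(kinetic = config$bounds$kinetic, rate = config$bounds$rate),
    protocol = list(n_conditions = proto$n_conditions,
                    n_times = proto$n_times, t_span = proto$t_span,
                    init_range = proto$init_range),
    lambda_interval = res$result$lambda_interval,
    rates = as.list(res$rates),
    package_version = as.character(utils::packageVersion("ssinfer")))
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset_tsv(res$dataset, file.path(out_dir, "dataset.tsv"))
    write_fronts_json(res$fronts, file.path(out_dir, "fronts.json"))
    write_network_csv(res$result$model, file.path(out_dir, "network.csv"))
    utils::write.csv(res$result$sweep$grid, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(res$roc, file.path(out_dir, "roc.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
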