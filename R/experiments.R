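# Simulation-experiment harness: seeded trial generation, sweeps over
# budget x cost-function x heuristic cells, and bootstrap summaries.

#' Experiment configurations
#'
#' Each trial draws one graph and one outbreak vertex, shared by every
#' (budget, cost spec, heuristic) cell of that trial.  Per-cell randomness
#' (stochastic costs, the random heuristic) is seeded deterministically from
#' the master seed, the trial index and the cell, so a configuration
#' reproduces byte-identically.
#'
#' @param model random-graph model name (see [random_graph()]); ignored when
#'   `graph` is given.
#' @param params model parameter list.
#' @param graph optional fixed [rooted_graph]; the outbreak vertex is still
#'   re-drawn per trial.
#' @param n_trials number of trials (study default 50).
#' @param budgets integer vector of per-turn budgets.
#' @param cost_specs character vector of cost spec strings
#'   (see [parse_cost_spec()]).
#' @param heuristic_specs character vector of heuristic spec strings
#'   (see [parse_heuristic_spec()]).
#' @param seed master seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(model = NULL, params = NULL, graph = NULL,
                              n_trials = 50, budgets, cost_specs,
                              heuristic_specs, seed) {
  if (is.null(graph) && is.null(model)) stop("supply a model or a fixed graph")
  n_trials <- as.integer(n_trials)
  budgets <- as.integer(budgets)
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (any(budgets < 1)) stop("budgets must be positive")
  structure(
    list(model = model, params = params, graph = graph, n_trials = n_trials,
         budgets = budgets, cost_specs = cost_specs,
         heuristic_specs = heuristic_specs, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Load an experiment configuration from YAML
#'
#' Keys mirror the arguments of [experiment_config()].
#'
#' @param path YAML file path.
#' @return an [experiment_config].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- y$params
  # YAML 1.1 reads bare n/y keys as booleans; map them back to their letters
  names(params)[names(params) == "FALSE"] <- "n"
  names(params)[names(params) == "TRUE"] <- "y"
  experiment_config(
    model = y$model, params = params,
    n_trials = if (is.null(y$n_trials)) 50 else y$n_trials,
    budgets = unlist(y$budgets),
    cost_specs = unlist(y$cost_specs),
    heuristic_specs = unlist(y$heuristic_specs),
    seed = y$seed
  )
}

#' Run a simulation experiment
#'
#' For every trial, one graph and root are drawn; every (budget, cost spec,
#' heuristic) cell is then played to containment through the game engine.
#'
#' @param cfg an [experiment_config].
#' @return a data frame with one row per cell per trial and columns `trial`,
#'   `graph_seed`, `root`, `budget`, `cost_spec`, `heuristic`, `saved`,
#'   `contained_at`; the per-turn defence logs are attached as the
#'   `"defences"` attribute (a list of [strategy] objects, one per row).
#' @examples
#' cfg <- experiment_config("erdos_renyi", list(n = 20, p = 0.1), n_trials = 2,
#'                          budgets = 2, cost_specs = "uniform",
#'                          heuristic_specs = c("cost", "random"), seed = 7)
#' run_experiment(cfg)
#' @export
run_experiment <- function(cfg) {
  cells <- expand.grid(budget = cfg$budgets, cost_spec = cfg$cost_specs,
                       heuristic = cfg$heuristic_specs,
                       stringsAsFactors = FALSE)
  rows <- list()
  defences <- list()
  for (trial in seq_len(cfg$n_trials)) {
    graph_seed <- hash_seed(cfg$seed, "graph", trial)
    if (is.null(cfg$graph)) {
      g <- random_graph(cfg$model, cfg$params, seed = graph_seed)
    } else {
      g0 <- cfg$graph
      root <- g0$vertices[keyed_rint(1L, n_vertices(g0), cfg$seed, "root", trial)]
      g <- rooted_graph(g0$graph, root)
    }
    for (ci in seq_len(nrow(cells))) {
      cell_seed <- hash_seed(cfg$seed, "cell", trial, ci)
      cost_fn <- parse_cost_spec(cells$cost_spec[ci], seed = cell_seed)
      spec <- parse_heuristic_spec(cells$heuristic[ci],
                                   seed = hash_seed(cell_seed, "heuristic"))
      inst <- cost_fire_instance(g, cost_fn, cells$budget[ci])
      tr <- play_heuristic(inst, spec)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = trial, graph_seed = graph_seed, root = g$root,
        budget = cells$budget[ci], cost_spec = cells$cost_spec[ci],
        heuristic = cells$heuristic[ci], saved = count_saved(tr),
        contained_at = tr$contained_at, stringsAsFactors = FALSE
      )
      defences[[length(defences) + 1L]] <- tr$defences
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "defences") <- defences
  out
}

#' Summarise experiment records
#'
#' Per (budget, cost spec, heuristic) cell: the median saved count and a
#' bootstrap percentile confidence interval over trials.
#'
#' @param records data frame from [run_experiment()].
#' @param conf confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed seed for the bootstrap.
#' @return data frame with columns `budget`, `cost_spec`, `heuristic`,
#'   `median_saved`, `ci_low`, `ci_high`.
#' @export
summarize_experiment <- function(records, conf = 0.95, n_boot = 1000, seed = 1) {
  key <- interaction(records$budget, records$cost_spec, records$heuristic,
                     drop = TRUE)
  out <- lapply(split(records, key), function(cell) {
    x <- cell$saved
    meds <- with_local_seed(hash_seed(seed, cell$budget[1], cell$cost_spec[1],
                                      cell$heuristic[1]), {
      vapply(seq_len(n_boot), function(i) {
        stats::median(sample(x, replace = TRUE))
      }, 1)
    })
    alpha <- (1 - conf) / 2
    ci <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 1)
    data.frame(budget = cell$budget[1], cost_spec = cell$cost_spec[1],
               heuristic = cell$heuristic[1],
               median_saved = stats::median(x),
               ci_low = min(ci[1], stats::median(x)),
               ci_high = max(ci[2], stats::median(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$budget, out$cost_spec, out$heuristic), , drop = FALSE]
}

#' Write results / summary CSV files
#'
#' `write_results_csv` writes the exact columns `trial`, `graph_seed`,
#' `root`, `budget`, `cost_spec`, `heuristic`, `saved`, `contained_at`;
#' `write_summary_csv` writes `budget`, `cost_spec`, `heuristic`,
#' `median_saved`, `ci_low`, `ci_high`.
#'
#' @param records,summary data frames from [run_experiment()] /
#'   [summarize_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  cols <- c("trial", "graph_seed", "root", "budget", "cost_spec", "heuristic",
            "saved", "contained_at")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
write_summary_csv <- function(summary, path) {
  cols <- c("budget", "cost_spec", "heuristic", "median_saved", "ci_low", "ci_high")
  utils::write.csv(summary[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
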