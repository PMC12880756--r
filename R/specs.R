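# Compact spec strings for cost functions and heuristics, used by the
# experiment harness, config files and the command-line wrapper.

parse_kv <- function(s) {
  if (is.na(s) || s == "") return(list())
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(x) x[2])
  names(out) <- vapply(kv, function(x) x[1], "")
  out
}

#' Parse a cost-function spec string
#'
#' Formats: `uniform`, `random_pref:seed=S`, `burning_nbrs:b=B`, `dist_fire`,
#' `periodic`, `hesitation:seed=S`, `threat_stoch:spread=high|low,seed=S`.
#' For seeded families, `seed` may be supplied via the `seed` argument
#' instead of in the string (the harness derives per-cell seeds this way).
#'
#' @param spec spec string.
#' @param seed fallback seed for stochastic families.
#' @return a [cost_function].
#' @examples
#' parse_cost_spec("burning_nbrs:b=3")
#' parse_cost_spec("hesitation", seed = 11)
#' @export
parse_cost_spec <- function(spec, seed = NULL) {
  bits <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- bits[1]
  args <- parse_kv(if (length(bits) > 1) bits[2] else NA)
  pick_seed <- function() {
    s <- if (!is.null(args$seed)) as.integer(args$seed) else seed
    if (is.null(s)) stop(sprintf("cost spec '%s' needs a seed", spec))
    s
  }
  switch(name,
    uniform = uniform_cost(),
    random_pref = random_preference(pick_seed()),
    burning_nbrs = burning_neighbours(as.integer(args$b)),
    dist_fire = distance_from_fire(),
    periodic = periodic_cost(),
    hesitation = binary_hesitation(pick_seed()),
    threat_stoch = threat_stochastic(args$spread, pick_seed()),
    stop(sprintf("unknown cost spec '%s'", spec))
  )
}

#' Parse a heuristic spec string
#'
#' Formats: `random:seed=S`, `degree[:tiebreak=threat|cost]`,
#' `threat[:tiebreak=degree|cost]`, `cost[:tiebreak=degree|threat]`.
#'
#' @param spec spec string.
#' @param seed fallback seed for the random heuristic.
#' @return a [heuristic_spec].
#' @export
parse_heuristic_spec <- function(spec, seed = NULL) {
  bits <- strsplit(spec, ":", fixed = TRUE)[[1]]
  name <- bits[1]
  args <- parse_kv(if (length(bits) > 1) bits[2] else NA)
  if (name == "random") {
    s <- if (!is.null(args$seed)) as.integer(args$seed) else seed
    if (is.null(s)) stop(sprintf("heuristic spec '%s' needs a seed", spec))
    heuristic_spec("random", seed = s)
  } else {
    tiebreak <- if (!is.null(args$tiebreak)) args$tiebreak else "none"
    heuristic_spec(name, tiebreak = tiebreak, seed = seed)
  }
}
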