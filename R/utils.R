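#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so seeded operations (splits, generators, training)
#' never perturb the session RNG.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_config <- function(...) {
  stop(structure(class = c("dticross_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("dticross_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_featurize <- function(...) {
  stop(structure(class = c("dticross_featurize_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_metric <- function(...) {
  stop(structure(class = c("dticross_metric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
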