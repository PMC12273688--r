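#' Simulation grid specification
#'
#' The standard simulation protocol: each algorithm x preset cell is run
#' `n_runs` times for `n_units` units (160 units = 480 trials = 16 bins of
#' 10 per trial type), without early termination.
#'
#' @param algorithms Subset of `c("actor_critic", "q_learning")`.
#' @param presets Subset of the four named presets.
#' @param n_runs Sessions per cell (default 200).
#' @param n_units Units per session (default 160).
#' @param master_seed Integer; per-session seeds derive from it.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(algorithms = c("actor_critic", "q_learning"),
                      presets = names(.PRESETS),
                      n_runs = 200L, n_units = 160L, master_seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  bad <- setdiff(presets, names(.PRESETS))
  if (length(bad)) stop("unknown preset: ", paste(bad, collapse = ", "))
  if (n_runs < 1L) stop("n_runs must be a positive integer")
  structure(
    list(algorithms = algorithms, presets = presets,
         n_runs = as.integer(n_runs), n_units = as.integer(n_units),
         master_seed = as.integer(master_seed)),
    class = "grid_spec"
  )
}

#' Final-bin choice counts
#'
#' Counts of A, C and E choices within the last full bin of `bin_size`
#' trials of each respective pair type (a trailing partial bin is
#' excluded, as in the per-type binning of the analysis).
#'
#' @param log A `session_log` with at least `bin_size` trials of each type.
#' @param bin_size Bin length (default 10).
#' @return Named integer vector `c(count_A, count_C, count_E)`.
#' @export
summarize_final_bin <- function(log, bin_size = 10L) {
  tr <- log$trials
  cnt <- function(pair, role) {
    ch <- tr$choice[tr$pair == pair]
    k <- length(ch) %/% bin_size
    if (k < 1L) stop("fewer than ", bin_size, " trials of type ", pair)
    sum(ch[((k - 1L) * bin_size + 1L):(k * bin_size)] == role)
  }
  c(count_A = cnt("AB", "A"), count_C = cnt("CD", "C"),
    count_E = cnt("EF", "E"))
}

#' Run the algorithm x preset simulation grid
#'
#' Runs every session of the grid and summarizes each by its final-bin
#' choice counts and end-of-session weighted choice rates. Per-session
#' seeds are derived from the master seed with [derive_seeds()], so the
#' grid is reproducible and cells are independent of each other's order.
#'
#' @param spec A [grid_spec()].
#' @return Data frame with one row per session: `algorithm`, `preset`,
#'   `run`, `seed`, `count_A`, `count_C`, `count_E`, `p_A`, `p_C`, `p_E`.
#' @export
#' @examples
#' run_grid(grid_spec(presets = "long_trace", algorithms = "q_learning",
#'                    n_runs = 2, n_units = 20, master_seed = 1))
run_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- expand.grid(preset = spec$presets, algorithm = spec$algorithms,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  seeds <- derive_seeds(spec$master_seed, n_cells * spec$n_runs)
  out <- vector("list", n_cells * spec$n_runs)
  k <- 0L
  for (ci in seq_len(n_cells)) {
    params <- agent_preset(cells$preset[ci], cells$algorithm[ci])
    for (run in seq_len(spec$n_runs)) {
      k <- k + 1L
      cfg <- session_config(n_units = spec$n_units,
                            termination_enabled = FALSE, seed = seeds[k])
      log <- run_agent_session(params, cfg,
                               participant_id = sprintf("%s_%s_%03d",
                                                        cells$algorithm[ci],
                                                        cells$preset[ci], run))
      fb <- summarize_final_bin(log)
      cr <- choice_rates(log)
      out[[k]] <- data.frame(
        algorithm = cells$algorithm[ci], preset = cells$preset[ci],
        run = run, seed = seeds[k],
        count_A = fb[["count_A"]], count_C = fb[["count_C"]],
        count_E = fb[["count_E"]],
        p_A = cr$p_A, p_C = cr$p_C, p_E = cr$p_E,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Choice-rate scatter data
#'
#' Emits the (P_C, P_A) / (P_C, P_E) coordinate table underlying the
#' choice-rate scatter summaries, optionally overlaying externally
#' supplied human rates.
#'
#' @param summaries Data frame from [run_grid()].
#' @param human_rates Optional data frame with columns `p_A`, `p_C`, `p_E`
#'   (and optionally `report_category`) of precomputed human choice rates.
#' @return Data frame with columns `source` (`"simulation"` / `"human"`),
#'   `algorithm`, `preset`, `p_C`, `p_A`, `p_E`.
#' @export
scatter_summary <- function(summaries, human_rates = NULL) {
  if (nrow(summaries) == 0L) stop("empty summaries")
  sim <- data.frame(
    source = "simulation", algorithm = summaries$algorithm,
    preset = summaries$preset, p_C = summaries$p_C, p_A = summaries$p_A,
    p_E = summaries$p_E, stringsAsFactors = FALSE
  )
  if (is.null(human_rates)) return(sim)
  hum <- data.frame(
    source = "human", algorithm = NA_character_,
    preset = if ("report_category" %in% names(human_rates))
      human_rates$report_category else NA_character_,
    p_C = human_rates$p_C, p_A = human_rates$p_A, p_E = human_rates$p_E,
    stringsAsFactors = FALSE
  )
  rbind(sim, hum)
}
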