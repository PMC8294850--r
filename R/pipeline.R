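#' Headline analysis report for one session
#'
#' Runs the standard pipeline on a node sequence: bout structure, mode
#' occupancies, exploration efficiency, turning biases, end-node
#' preferences, and (optionally) the cross-validated decision models.
#'
#' @param seq A `node_sequence`, `synthetic_session` or `sim_session`.
#' @param maze A `maze_graph` (taken from the session when available).
#' @param markov Also fit the junction-decision models (slower;
#'   default FALSE).
#' @param ... Passed to [segment_modes()] (e.g. `rewarded`).
#' @return A named list of summary statistics.
#' @export
session_report <- function(seq, maze = NULL, markov = FALSE, ...) {
  if (inherits(seq, "synthetic_session")) {
    if (is.null(maze)) maze <- seq$maze
    seq <- seq$seq
  } else if (inherits(seq, "sim_session")) seq <- seq$seq
  if (is.null(maze)) stop("maze required", call. = FALSE)
  bouts <- segment_bouts(seq)
  segs <- segment_modes(seq, maze, ...)
  eth <- ethogram(segs)
  eff <- n32_efficiency(discovery_curve(seq, maze, ...))
  biases <- estimate_biases(seq, maze, ...)
  occ <- endnode_occupancy(seq, maze)
  out <- list(
    n_bouts = nrow(bouts),
    n_steps = sum(pmax(bouts$end - bouts$start, 0L)),
    time_in_maze_s = sum(bouts$exit_time - bouts$entry_time),
    explore_fraction = unname(eth$occupancy["explore"]),
    drink_fraction = unname(eth$occupancy["drink"]),
    efficiency_E = eff$E,
    N32 = eff$N32,
    PSF = biases$PSF, PSA = biases$PSA, PBF = biases$PBF, PBS = biases$PBS,
    outer_inner_ratio = outer_inner_ratio(occ, maze))
  if (markov) {
    cmp <- compare_models(seq, maze, ks = 1:2, m_grid = 10L, ...)
    out$H_fixed_k1 <- cmp$H_bits[cmp$model == "fixed k=1"]
    out$H_variable <- min(cmp$H_bits[grepl("^variable", cmp$model)])
  }
  out
}

#' Run the analysis pipeline from a configuration
#'
#' Thin orchestration over the package functions, suitable for scripted
#' runs. The configuration (a YAML file or an equivalent nested list) has
#' sections `seed`, `maze` (`n_junction_levels`, `water_port_leaf`),
#' `simulate` (`n_sessions`, `duration`, `rewarded`) and `out_dir`. Stages:
#' `"simulate"` generates synthetic sessions and writes their node
#' sequences; `"report"` analyses every written (or supplied) sequence and
#' aggregates a summary table.
#'
#' @param config Path to a YAML file, or a list.
#' @param stages Character vector of stages to run (default both).
#' @param inputs Optional character vector of node-sequence files to analyse
#'   instead of simulated ones.
#' @return Invisibly, the summary data.frame (one row per session).
#' @export
run_pipeline <- function(config, stages = c("simulate", "report"),
                         inputs = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$out_dir)) stop("config needs out_dir", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  mc <- do.call(maze_config, if (is.null(cfg$maze)) list() else cfg$maze)
  maze <- build_maze(mc)
  rewarded <- if (is.null(cfg$simulate$rewarded)) TRUE else
    isTRUE(cfg$simulate$rewarded)

  files <- inputs
  if ("simulate" %in% stages && is.null(inputs)) {
    n_sessions <- if (is.null(cfg$simulate$n_sessions)) 1L else
      as.integer(cfg$simulate$n_sessions)
    duration <- if (is.null(cfg$simulate$duration)) 25200 else
      cfg$simulate$duration
    files <- character(n_sessions)
    for (i in seq_len(n_sessions)) {
      recipe <- session_recipe(duration = duration, maze_config = mc,
                               rewarded = rewarded)
      ses <- generate_session(recipe, seed = seed + i)
      files[i] <- file.path(cfg$out_dir, sprintf("session_%02d.tsv", i))
      write_node_sequence(ses$seq, files[i])
    }
  }
  summary <- NULL
  if ("report" %in% stages) {
    if (is.null(files)) stop("no inputs to report on", call. = FALSE)
    rows <- lapply(seq_along(files), function(i) {
      seq <- read_node_sequence(files[i])
      rep <- session_report(seq, maze, rewarded = rewarded)
      cbind(data.frame(session = basename(files[i])), as.data.frame(rep))
    })
    summary <- do.call(rbind, rows)
    utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}
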