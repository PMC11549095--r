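#' Classify the release route of a trajectory
#'
#' Geometric route rules (the toy analogue of inspecting release events):
#' crossing the cytoplasmic exit plane after visiting at least half of the
#' path-1 (resp. path-2) waypoint spheres of radius `waypoint_radius` labels
#' the run `cytoplasm_path1` (resp. `cytoplasm_path2`); crossing the
#' periplasmic exit plane labels it `periplasm`; otherwise a final frame
#' within `site_radius` of M3 is `retained_M3`, and anything else
#' `retained_M1`.  If both exits are crossed the earlier crossing wins (a
#' simultaneous crossing is an error); if the cytoplasmic exit is crossed
#' with both waypoint majorities satisfied, the path with more visited
#' waypoints wins (ties go to path 1, the structurally primary route).
#'
#' @param traj a `Trajectory`
#' @param sys the `ToySystem` it was run on
#' @param waypoint_radius sphere radius for waypoint visits (default 3 A)
#' @param site_radius retention radius around sites (default 3 A)
#' @return a `RouteLabel` character scalar, one of `cytoplasm_path1`,
#'   `cytoplasm_path2`, `periplasm`, `retained_M3`, `retained_M1`; attributes
#'   record waypoint visit counts, the first crossing frame, and the first
#'   passage frame out of the M1 sphere
#' @export
classify_release_route <- function(traj, sys, waypoint_radius = 3,
                                   site_radius = 3) {
  if (length(traj$times) < 2) stop("trajectory too short to classify")
  pos <- traj$pos
  visited <- function(path) {
    w <- sys$waypoints[[path]]
    vapply(seq_len(nrow(w)), function(i)
      any(rowSums(sweep(pos, 2, w[i, ])^2) <= waypoint_radius^2), logical(1))
  }
  v1 <- visited("path1"); v2 <- visited("path2")
  z_cyt <- sys$sites["cytoplasmic_exit", "z"]
  z_peri <- sys$sites["periplasmic_exit", "z"]
  cross_cyt <- which(pos[, 3] <= z_cyt)[1]
  cross_peri <- which(pos[, 3] >= z_peri)[1]
  first_out <- which(rowSums(sweep(pos, 2, sys$sites["M1", ])^2) >
                       site_radius^2)[1]
  label <- NULL
  if (!is.na(cross_cyt) && !is.na(cross_peri)) {
    if (cross_cyt == cross_peri)
      stop("ambiguous crossing: both exits reached in the same frame")
    if (cross_peri < cross_cyt) label <- "periplasm"
  }
  if (is.null(label) && !is.na(cross_peri) && is.na(cross_cyt))
    label <- "periplasm"
  if (is.null(label) && !is.na(cross_cyt)) {
    maj1 <- sum(v1) >= length(v1) / 2
    maj2 <- sum(v2) >= length(v2) / 2
    if (maj1 && maj2) {
      label <- if (sum(v2) / length(v2) > sum(v1) / length(v1))
        "cytoplasm_path2" else "cytoplasm_path1"
    } else if (maj1) label <- "cytoplasm_path1"
    else if (maj2) label <- "cytoplasm_path2"
    else label <- "cytoplasm_path2"  # direct drop: no waypoint majority
  }
  if (is.null(label)) {
    final <- pos[nrow(pos), ]
    if (sum((final - sys$sites["M3", ])^2) <= site_radius^2)
      label <- "retained_M3"
    else label <- "retained_M1"
  }
  structure(label, class = "RouteLabel",
            visited_path1 = sum(v1), visited_path2 = sum(v2),
            crossing_frame = if (!is.na(cross_cyt) || !is.na(cross_peri))
              min(cross_cyt, cross_peri, na.rm = TRUE) else NA_integer_,
            first_passage_frame = if (is.na(first_out)) NA_integer_ else first_out)
}

#' Run the replicate WT-MTD experiment for one scenario
#'
#' Builds the scenario system, runs `n_replicates` well-tempered
#' metadynamics simulations with seeds `base_seed + 1 .. base_seed + n`,
#' classifies each release route, and aggregates the counts -- the toy
#' analogue of the per-scenario run summary table.
#'
#' @param config a [scenario_config()]
#' @param n_replicates number of replicate runs (default 5, matching the
#'   three-to-five runs per scenario of the study design)
#' @param base_seed integer; replicate i uses seed `base_seed + i`
#' @param mtd a [wtmtd_config()]
#' @param sim a [sim_config()] template (its seed is overridden per
#'   replicate)
#' @param keep_trajectories retain the Trajectory objects in the report
#' @return a `ScenarioReport` with a per-replicate table (seed, route,
#'   first-passage step, waypoints visited) and aggregate route counts
#' @export
run_scenario <- function(config, n_replicates = 5, base_seed = 0,
                         mtd = wtmtd_config(), sim = sim_config(n_steps = 2e5),
                         keep_trajectories = FALSE) {
  stopifnot(n_replicates >= 1)
  sys <- build_toy_system(config, seed = base_seed %% 1000 + 1)
  rows <- vector("list", n_replicates)
  trajs <- if (keep_trajectories) vector("list", n_replicates) else NULL
  for (i in seq_len(n_replicates)) {
    cfg <- sim
    cfg$seed <- base_seed + i
    row <- tryCatch({
      traj <- run_simulation(sys, cfg, init = "M1", mtd = mtd)
      lab <- classify_release_route(traj, sys)
      if (keep_trajectories) trajs[[i]] <- traj
      data.frame(replicate = i, seed = cfg$seed, route = as.character(lab),
                 first_passage_step = {
                   f <- attr(lab, "first_passage_frame")
                   if (is.na(f)) NA_integer_
                   else as.integer(round(traj$times[f] / cfg$dt))
                 },
                 visited_path1 = attr(lab, "visited_path1"),
                 visited_path2 = attr(lab, "visited_path2"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(replicate = i, seed = cfg$seed, route = NA_character_,
                 first_passage_step = NA_integer_, visited_path1 = NA_integer_,
                 visited_path2 = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  levels <- c("cytoplasm_path1", "cytoplasm_path2", "periplasm",
              "retained_M3", "retained_M1")
  counts <- table(factor(tab$route, levels = levels))
  structure(list(scenario = config$name, replicates = tab,
                 counts = as.integer(counts),
                 routes = levels, base_seed = base_seed,
                 system = sys, trajectories = trajs),
            class = "ScenarioReport")
}

#' @export
print.ScenarioReport <- function(x, ...) {
  cat(sprintf("<ScenarioReport %s> %d replicates (base seed %d)\n",
              x$scenario, nrow(x$replicates), x$base_seed))
  for (i in seq_along(x$routes))
    if (x$counts[i] > 0)
      cat(sprintf("  %-16s %d\n", x$routes[i], x$counts[i]))
  n_err <- sum(!is.na(x$replicates$error))
  if (n_err > 0) cat(sprintf("  failed replicates: %d\n", n_err))
  invisible(x)
}

#' Write a scenario report as columnar text plus a summary
#'
#' @param report a `ScenarioReport`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# scenario %s base_seed %d", report$scenario,
                     report$base_seed), con)
  writeLines(sprintf("# counts %s",
                     paste(sprintf("%s=%d", report$routes, report$counts),
                           collapse = " ")), con)
  utils::write.table(report$replicates, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
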