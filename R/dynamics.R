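#' Simulation configuration
#'
#' Overdamped (Brownian) Langevin dynamics of the ion on the frozen
#' landscape: x <- x + (D/kT) F dt + sqrt(2 D dt) xi.  The observable of
#' interest is the CV-space free energy, which at equilibrium does not
#' depend on the integrator, so the inertial thermostatted dynamics of the
#' all-atom system is replaced by its overdamped limit with a single
#' mobility parameter D.
#'
#' @param n_steps number of steps
#' @param dt time step, ps (default 0.01)
#' @param diffusion ion diffusion coefficient D, A^2/ps (default 0.5; the M1
#'   basin correlation time is then of order 1e2 steps)
#' @param temperature Kelvin (default 303)
#' @param seed RNG seed recorded in the trajectory metadata
#' @param record_stride store every k-th frame (default 10)
#' @param mobility drift mobility D/kT in A^2/(kJ/mol)/ps; derived from
#'   `diffusion` at the run temperature by default.  At zero temperature the
#'   noise vanishes and the drift keeps the mobility referenced to 303 K, so
#'   the deterministic limit stays finite.
#' @return a `SimConfig` list
#' @export
sim_config <- function(n_steps = 1e5, dt = 0.01, diffusion = 0.5,
                       temperature = 303, seed = 1, record_stride = 10L,
                       mobility = NULL) {
  stopifnot(dt > 0, temperature >= 0, diffusion > 0, n_steps >= 0)
  if (is.null(mobility))
    mobility <- diffusion / kT(if (temperature > 0) temperature else 303)
  structure(list(n_steps = n_steps, dt = dt, diffusion = diffusion,
                 temperature = temperature, seed = seed,
                 record_stride = as.integer(record_stride),
                 mobility = mobility),
            class = "SimConfig")
}

#' One Euler-Maruyama step of overdamped Langevin dynamics
#'
#' Reference (pure R) implementation of the update used by the simulation
#' engine: drift (D/kT) F dt plus Gaussian noise of variance 2 D dt per
#' coordinate.  At zero temperature both terms involving kT are taken in the
#' deterministic limit (no noise; drift uses the supplied mobility).
#'
#' @param pos current position (length 3)
#' @param total_force force in kJ/mol/A (length 3)
#' @param config a [sim_config()]
#' @return new position
#' @export
langevin_step <- function(pos, total_force, config) {
  if (!all(is.finite(total_force))) stop("non-finite force in langevin_step")
  noise <- if (config$temperature > 0)
    sqrt(2 * config$mobility * kT(config$temperature) * config$dt) * rnorm(3)
  else 0
  pos + config$mobility * total_force * config$dt + noise
}

#' Run a (possibly biased) simulation of the ion on the landscape
#'
#' Propagates the ion from the named site center with overdamped Langevin
#' dynamics.  If `mtd` is given, well-tempered hills are deposited in CV
#' space every `deposition_interval` and their forces act on the ion through
#' the chain rule over the spherical-CV gradients.  If `steered` is given, a
#' moving harmonic restraint on rho is applied.  The trajectory records
#' frames every `record_stride` steps with time, position, CV values (rho,
#' theta, phi, CN) and the instantaneous bias energy.
#'
#' @param sys a `ToySystem`
#' @param config a [sim_config()]
#' @param init site name (default "M1") or a length-3 position
#' @param mtd optional [wtmtd_config()]
#' @param steered optional `list(k =, times =, targets =)` schedule for rho
#' @param cn_spec coordination-number definition for the recorded CN
#' @return a `Trajectory` object; if the ion leaves the bounding box the
#'   trajectory is truncated and flagged with the escape reason
#' @export
run_simulation <- function(sys, config, init = "M1", mtd = NULL,
                           steered = NULL, cn_spec = coordination_spec()) {
  if (is.character(init)) {
    if (!init %in% rownames(sys$sites)) stop("unknown initial site: ", init)
    x0 <- sys$sites[init, ]
  } else x0 <- as.numeric(init)
  mtd_list <- NULL
  if (!is.null(mtd)) {
    stopifnot(inherits(mtd, "WTMTDConfig"))
    mtd_list <- list(w0 = mtd$w0, bias_factor = mtd$bias_factor,
                     sigma = .active_sigma(mtd),
                     interval_steps = max(1, round(mtd$deposition_interval / config$dt)))
  }
  if (!is.null(steered)) {
    stopifnot(all(c("k", "times", "targets") %in% names(steered)))
    if (is.unsorted(steered$times, strictly = TRUE))
      stop("steering schedule times must be strictly increasing")
    if (is.unsorted(steered$targets) && is.unsorted(rev(steered$targets)))
      stop("steering schedule must be monotone")
  }
  grp <- as.matrix(sys$atoms[, c("x", "y", "z")])
  if (!is.null(cn_spec$group)) grp <- grp[cn_spec$group, , drop = FALSE]
  set.seed(config$seed)
  res <- cpp_run_sim(as.numeric(x0), sys$landscape, grp, cn_spec$r0,
                     cn_spec$n, cn_spec$m,
                     list(dt = config$dt, mobility = config$mobility,
                          temperature = config$temperature,
                          n_steps = config$n_steps,
                          record_stride = config$record_stride,
                          box = unname(sys$box)),
                     mtd_list, steered)
  cv <- as.data.frame(res$cv)
  names(cv) <- c("rho", "theta", "phi", "cn")
  hills <- empty_hills(if (!is.null(mtd)) mtd$bias_factor else 10)
  if (!is.null(mtd) && nrow(res$hills) > 0) {
    h <- as.data.frame(res$hills)
    names(h) <- c("time", "rho", "theta", "phi", "sigma_rho", "sigma_theta",
                  "sigma_phi", "height")
    h$biasf <- mtd$bias_factor
    hills <- structure(h, class = c("HillRecord", "data.frame"))
  }
  structure(list(times = res$times, pos = res$pos, cv = cv, bias = res$bias,
                 hills = hills, escaped = res$escaped,
                 escape_reason = if (res$escaped)
                   sprintf("ion left the box at step %d", res$escape_step)
                 else NA_character_,
                 config = config, mtd = mtd, system_scenario = sys$config$name,
                 seed = config$seed),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames over %.1f ps (seed %d)%s\n",
              length(x$times), max(x$times), x$seed,
              if (isTRUE(x$escaped)) paste0(" [", x$escape_reason, "]") else ""))
  if (nrow(x$hills) > 0)
    cat(sprintf("  %d hills deposited, final bias %.2f kJ/mol\n",
                nrow(x$hills), x$bias[length(x$bias)]))
  invisible(x)
}

#' Steered pulling along rho with a moving harmonic restraint
#'
#' Applies 0.5 k (rho - target(t))^2 with a target interpolated linearly
#' along the schedule.  The default force constant maps the stiff pulling
#' spring of 1000 kcal/(mol A^2) to kJ/mol units (4184 kJ/(mol A^2)); in the
#' stiff-spring limit the final rho tracks the final target to within about
#' 3 sqrt(kT/k).  Note the explicit Euler-Maruyama update is stable only for
#' dt < 1 / (mobility * k): with the default mobility the stiff spring needs
#' dt of order 1e-4 ps (see [sim_config()]).
#'
#' @param sys a `ToySystem`
#' @param config a [sim_config()]
#' @param from,to start and end rho targets (A); the ion starts at `init`
#' @param k force constant, kJ/mol/A^2
#' @param init initial site or position
#' @return a `Trajectory`
#' @export
steered_pull <- function(sys, config, from, to, k = 1000 * 4.184,
                         init = "M1") {
  total <- config$n_steps * config$dt
  run_simulation(sys, config, init = init,
                 steered = list(k = k, times = c(0, total),
                                targets = c(from, to)))
}

#' Write / read a trajectory's CV time series as columnar text
#'
#' Whitespace-delimited columns time, rho, theta, phi, cn, bias with a
#' single header line -- the same shape as a PLUMED COLVAR file.
#'
#' @param traj a `Trajectory`
#' @param path file path
#' @return reader returns a data frame; writer returns `path` invisibly
#' @export
write_colvar <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$cv, bias = traj$bias)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("#", names(df)), collapse = " "), con)
  writeLines(apply(as.matrix(df), 1, function(r)
    paste(sprintf("%.10g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path, n = 1)
  if (!startsWith(lines[1], "#")) stop("malformed COLVAR file: ", path)
  cols <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "\\s+")[[1]]
  df <- utils::read.table(path, skip = 1, col.names = cols)
  df
}
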