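# Fixture builders shared across tests.  All fixtures are generated in code;
# systems derived from the scenario builder are modified copies so the
# engine sees exactly the container it expects.

toy1 <- function(seed = 7) build_toy_system(scenario_config(1), seed = seed)

# landscape with no wells/barriers/pore: free diffusion inside the rho wall
flat_system <- function(wall_limit = 25, wall_k = 50) {
  sys <- toy1()
  sys$landscape$wells <- matrix(numeric(0), 0, 5)
  sys$landscape$barriers <- matrix(numeric(0), 0, 5)
  sys$landscape$pore <- NULL
  sys$landscape$wall_limit <- wall_limit
  sys$landscape$wall_k <- wall_k
  sys
}

# isotropic harmonic trap: one-sided quadratic wall with zero rest radius
harmonic_system <- function(k = 10) {
  sys <- flat_system(wall_limit = 0, wall_k = k)
  sys
}

# custom landscape from explicit well/barrier tables
custom_system <- function(wells = NULL, barriers = NULL, wall_limit = 25,
                          wall_k = 50, pore = NULL) {
  sys <- flat_system(wall_limit, wall_k)
  if (!is.null(wells)) sys$landscape$wells <- rbind(wells)
  if (!is.null(barriers)) sys$landscape$barriers <- rbind(barriers)
  sys$landscape$pore <- pore
  sys
}

# double well along -z from the reference COM, at rho = r1 and r2
double_well_system <- function(d1 = 10, d2 = 7, width = 1.2, r1 = 5, r2 = 10) {
  rc <- c(1.5, 0, 3)
  custom_system(wells = rbind(c(rc + c(0, 0, -r1), d1, width),
                              c(rc + c(0, 0, -r2), d2, width)),
                wall_limit = 14, wall_k = 50)
}

# minimal duck-typed system for CV unit checks with an explicit reference
fake_ref_system <- function(ref_positions, masses = NULL) {
  ref_positions <- rbind(ref_positions)
  n <- nrow(ref_positions)
  list(atoms = data.frame(x = ref_positions[, 1], y = ref_positions[, 2],
                          z = ref_positions[, 3]),
       masses = if (is.null(masses)) rep(1, n) else masses,
       groups = list(reference = seq_len(n)))
}

# small synthetic protein-like structure for superposition fixtures
synthetic_structure <- function(n = 40, seed = 1) {
  set.seed(seed)
  xyz <- matrix(rnorm(n * 3, sd = 8), ncol = 3)
  structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resid = seq_len(n), chain = "A", insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, bfactor = 0, het = FALSE, stringsAsFactors = FALSE),
    class = c("Structure", "data.frame"), title = "synthetic fixture")
}

# hand-built Trajectory passing through the given positions
fake_trajectory <- function(positions, dt = 1) {
  positions <- rbind(positions)
  n <- nrow(positions)
  structure(list(times = (seq_len(n) - 1) * dt, pos = positions,
                 cv = data.frame(rho = rep(1, n), theta = 0, phi = 0, cn = 0),
                 bias = rep(0, n), hills = empty_hills(),
                 escaped = FALSE, escape_reason = NA_character_,
                 config = sim_config(n_steps = n, seed = 1), mtd = NULL,
                 seed = 1), class = "Trajectory")
}

# straight-line sweep visiting each waypoint of a path then an exit
route_positions <- function(sys, path = "path1", exit = "cytoplasmic_exit",
                            start = "M1") {
  pts <- rbind(sys$sites[start, ], sys$waypoints[[path]], sys$sites[exit, ])
  if (exit == "cytoplasmic_exit") pts <- rbind(pts, c(0, 0, -20))
  if (exit == "periplasmic_exit") pts <- rbind(pts, c(0, 0, 15))
  # interpolate so crossings are well resolved
  out <- NULL
  for (i in seq_len(nrow(pts) - 1))
    out <- rbind(out, t(sapply(seq(0, 1, length.out = 5), function(f)
      (1 - f) * pts[i, ] + f * pts[i + 1, ])))
  out
}
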