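#' Scenario configuration for the four release experiments
#'
#' The four simulation scenarios differ in the occupancy of the M2 and M3
#' metal-binding sites and the folding state of the cytoplasmic loop (IL2):
#' scenario 1 has M1/M2 occupied, no metal at M3 and an unfolded IL2;
#' scenario 2 has M1-M3 occupied and a folded IL2; scenario 3 has M1/M2
#' occupied with a pre-formed but empty M3 site and a folded IL2; scenario 4
#' is scenario 2 with the M2 metal removed.  A folded IL2 narrows the direct
#' cytoplasmic channel (path 2); an occupied M3 site places a repulsive bump
#' on the M3 channel (path 1).
#'
#' @param scenario integer 1-4 or string "scenario1".."scenario4"
#' @param m2_occupied,m3_state,il2_folded optional explicit flags; if given
#'   together with a named scenario they must agree with its definition
#' @return a `ScenarioConfig` list with fields `name`, `m2_occupied`,
#'   `m3_state` (one of "absent", "occupied", "preformed_empty") and
#'   `il2_folded`
#' @examples
#' scenario_config(2)
#' @export
scenario_config <- function(scenario, m2_occupied = NULL, m3_state = NULL,
                            il2_folded = NULL) {
  if (is.numeric(scenario)) scenario <- paste0("scenario", scenario)
  canon <- list(
    scenario1 = list(m2_occupied = TRUE,  m3_state = "absent",          il2_folded = FALSE),
    scenario2 = list(m2_occupied = TRUE,  m3_state = "occupied",        il2_folded = TRUE),
    scenario3 = list(m2_occupied = TRUE,  m3_state = "preformed_empty", il2_folded = TRUE),
    scenario4 = list(m2_occupied = FALSE, m3_state = "occupied",        il2_folded = TRUE)
  )
  if (!scenario %in% names(canon))
    stop("unknown scenario '", scenario, "' (expected scenario1..scenario4)")
  def <- canon[[scenario]]
  for (fld in names(def)) {
    supplied <- get(fld)
    if (!is.null(supplied) && !identical(supplied, def[[fld]]))
      stop("inconsistent scenario flags: ", scenario, " requires ", fld,
           " = ", def[[fld]], " but ", supplied, " was supplied")
  }
  structure(c(list(name = scenario), def), class = "ScenarioConfig")
}

#' @export
print.ScenarioConfig <- function(x, ...) {
  cat(sprintf("<ScenarioConfig %s> M2 %s, M3 %s, IL2 %s\n", x$name,
              if (x$m2_occupied) "occupied" else "empty", x$m3_state,
              if (x$il2_folded) "folded" else "unfolded"))
  invisible(x)
}

# default geometry of the coarse-grained transporter (angstrom)
.toy_geometry <- function() {
  sites <- rbind(
    M1               = c(0, 0, 0),
    M2               = c(0, 2.5, 3.5),
    transient        = c(2, 0, -6),
    M3               = c(3, 0, -12),
    periplasmic_exit = c(0, 0, 14),
    cytoplasmic_exit = c(0, 0, -18)
  )
  colnames(sites) <- c("x", "y", "z")
  waypoints <- list(
    path1 = rbind(c(2, 0, -6), c(2.5, 0, -9), c(3, 0, -12), c(2.5, 0, -15)),
    path2 = rbind(c(-3, 0, -7), c(-3, 0, -11), c(-2.5, 0, -15)),
    periplasmic = rbind(c(0, 1, 4), c(0, 1.5, 8), c(0, 1, 11))
  )
  list(sites = sites, waypoints = waypoints,
       ref_com = c(1.5, 0, 3),
       box = rbind(lo = c(-30, -30, -30), hi = c(30, 30, 30)))
}

# pseudo-atom scaffold/transport cage plus coordination ligands
.toy_atoms <- function(geom, seed) {
  rows <- list(); grp <- character(0); ele <- character(0)
  add <- function(xyz, group, element) {
    rows[[length(rows) + 1L]] <<- xyz
    grp <<- c(grp, rep(group, nrow(xyz)))
    ele <<- c(ele, rep(element, nrow(xyz)))
  }
  rc <- geom$ref_com
  add(rbind(rc + c(3, 0, 0), rc + c(-3, 0, 0), rc + c(0, 3, 0),
            rc + c(0, -3, 0)), "reference", "C")
  ring <- function(radius, z, n, offset) {
    a <- offset + 2 * pi * (seq_len(n) - 1) / n
    cbind(radius * cos(a), radius * sin(a), z)
  }
  add(do.call(rbind, lapply(c(-12, -6, 0, 6), function(z) ring(7, z, 6, 0))),
      "scaffold", "C")
  add(do.call(rbind, lapply(c(-9, -3, 3, 9), function(z) ring(7, z, 4, pi / 6))),
      "transport", "C")
  s <- geom$sites
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  add(sweep(2.2 * tet, 2, s["M1", ], `+`), "ligand", "O")
  add(sweep(2.2 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), 2, s["M2", ], `+`),
      "ligand", "O")
  add(sweep(2.2 * rbind(c(1, 0, 1), c(-1, 0, -1)) / sqrt(2), 2,
            s["transient", ], `+`), "ligand", "N")
  add(sweep(2.2 * rbind(c(1, 0, 0), c(0, 1, 0), c(0, -1, 0)), 2, s["M3", ], `+`),
      "ligand", "N")
  xyz <- do.call(rbind, rows)
  # small seeded jitter on the cage only, so repeated builds are identical
  jit <- grp %in% c("scaffold", "transport")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  xyz[jit, ] <- xyz[jit, ] + matrix(rnorm(sum(jit) * 3, sd = 0.05), ncol = 3)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  atoms <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = ele, group = grp,
                      stringsAsFactors = FALSE)
  atoms
}

#' Build the coarse-grained transporter system for a scenario
#'
#' Constructs the pseudo-atom cage, the planted binding sites (M1, M2, M3,
#' transient), the channel waypoints (path 1 via M3, path 2 direct,
#' periplasmic), and the smooth energy landscape: Gaussian wells at sites and
#' along channel grooves, Gaussian barriers forming the septum between the
#' two cytoplasmic channels and the periplasmic gate, a one-sided quadratic
#' wall on the ion-to-reference distance rho at `wall_limit`, and a smooth
#' cylindrical pore wall.  Occupied sites are replaced by repulsive bumps of
#' height equal to the removed well depth (an electrostatic-repulsion proxy);
#' a folded IL2 adds a barrier on path 2.
#'
#' @param config a [scenario_config()] object
#' @param seed integer seed for the (tiny) cage jitter; builds are
#'   deterministic given the seed
#' @param depths named list overriding well depths in kJ/mol
#'   (`M1`, `M2`, `M3`, `transient`, `groove1`, `groove2`, `groove_peri`)
#' @param wall_limit,wall_k rho restraint: limit (default 25 A) and force
#'   constant kJ/mol/A^2
#' @return a `ToySystem` object
#' @examples
#' sys <- build_toy_system(scenario_config(1), seed = 7)
#' @export
build_toy_system <- function(config, seed = 1, depths = list(),
                             wall_limit = 25, wall_k = 10) {
  stopifnot(inherits(config, "ScenarioConfig"))
  geom <- .toy_geometry()
  d <- utils::modifyList(list(M1 = 20, M2 = 16, M3 = 14, M3_partial = 10,
                              transient = 12, groove1 = 6, groove2 = 5,
                              groove_peri = 3), depths)
  s <- geom$sites
  wells <- list(); barriers <- list()
  well <- function(center, depth, width)
    wells[[length(wells) + 1L]] <<- c(center, depth, width)
  bump <- function(center, height, width)
    barriers[[length(barriers) + 1L]] <<- c(center, height, width)

  occupied <- character(0)
  well(s["M1", ], d$M1, 2)
  if (config$m2_occupied) {
    bump(s["M2", ], d$M2, 2); occupied <- c(occupied, "M2")
  } else well(s["M2", ], d$M2, 2)
  well(s["transient", ], d$transient, 2)
  if (config$m3_state == "occupied") {
    # a bound divalent cation (plus the folded loop) obstructs the whole
    # channel cross-section, hence the wide repulsive footprint
    bump(s["M3", ], d$M3, 3); occupied <- c(occupied, "M3")
  } else if (config$m3_state == "preformed_empty") {
    well(s["M3", ], d$M3, 2)
  } else {
    # IL2 unfolded: the acidic ligands alone still chelate at the M3
    # station, leaving a shallower well there
    well(s["M3", ], d$M3_partial, 2)
  }
  # shared vestibule below M1 from which the two cytoplasmic channels split
  well(c(0, 0, -2.5), 4, 2)
  for (i in seq_len(nrow(geom$waypoints$path1)))
    well(geom$waypoints$path1[i, ], d$groove1, 2.5)
  for (i in seq_len(nrow(geom$waypoints$path2)))
    well(geom$waypoints$path2[i, ], d$groove2, 2.5)
  for (i in seq_len(nrow(geom$waypoints$periplasmic)))
    well(geom$waypoints$periplasmic[i, ], d$groove_peri, 2.5)

  # septum separating path 1 (x > 0) from path 2 (x < 0)
  for (y in c(-4.5, -3, -1.5, 0, 1.5, 3, 4.5))
    for (z in c(-6, -9, -12, -15))
      bump(c(0, y, z), 25, 1.0)
  # periplasmic gate: release to the periplasm is rare
  bump(c(0, 1, 6), 20, 2.5)
  blocked <- character(0)
  if (config$m3_state == "occupied") blocked <- c(blocked, "path1")
  if (config$il2_folded) {
    # the folded loop narrows (does not seal) the direct channel: passage
    # needs a rearrangement, so it carries a kinetic penalty
    bump(c(-3, 0, -9), 8, 2)
    blocked <- c(blocked, "path2")
  }

  wells <- do.call(rbind, wells)
  barriers <- do.call(rbind, barriers)
  colnames(wells) <- c("x", "y", "z", "depth", "width")
  colnames(barriers) <- c("x", "y", "z", "height", "width")
  if (any(wells[, 4:5] <= 0) || any(barriers[, 4:5] <= 0))
    stop("landscape depths, heights and widths must be strictly positive")

  atoms <- .toy_atoms(geom, seed)
  groups <- lapply(c(reference = "reference", scaffold = "scaffold",
                     transport = "transport", ligand = "ligand"),
                   function(g) which(atoms$group == g))
  landscape <- list(
    wells = wells, barriers = barriers,
    wall_limit = wall_limit, wall_k = wall_k,
    ref_com = unname(geom$ref_com),
    pore = list(radius = 5.5, k = 10, z_min = -16, z_max = 12, taper = 1.5),
    blocked_paths = blocked, occupied_sites = occupied
  )
  sys <- structure(list(
    atoms = atoms, groups = groups, masses = rep(1, nrow(atoms)),
    sites = s, waypoints = geom$waypoints, landscape = landscape,
    box = geom$box, config = config, seed = seed
  ), class = "ToySystem")
  validate_toy_system(sys)
  sys
}

#' Validate a ToySystem against its invariants
#'
#' Site centers must be at least 6 A apart except the binuclear M1-M2 pair
#' (4-5 A, mirroring the transport site); channel waypoints must lie inside
#' the bounding box; the reference group must be non-empty.
#'
#' @param sys a `ToySystem`
#' @return `sys`, invisibly; errors name the violated invariant
#' @export
validate_toy_system <- function(sys) {
  s <- sys$sites
  dm <- as.matrix(stats::dist(s))
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(s))) {
    if (i >= j) next
    pair <- sort(c(rownames(s)[i], rownames(s)[j]))
    if (identical(pair, c("M1", "M2"))) {
      if (dm[i, j] < 4 || dm[i, j] > 5)
        stop("invariant violated: M1-M2 separation must be 4-5 A, got ",
             round(dm[i, j], 2))
    } else if (dm[i, j] < 6) {
      stop("invariant violated: sites ", pair[1], " and ", pair[2],
           " closer than 6 A")
    }
  }
  for (p in names(sys$waypoints)) {
    w <- sys$waypoints[[p]]
    inside <- w >= matrix(sys$box["lo", ], nrow(w), 3, byrow = TRUE) &
      w <= matrix(sys$box["hi", ], nrow(w), 3, byrow = TRUE)
    if (!all(inside))
      stop("invariant violated: waypoint of ", p, " outside the box")
  }
  if (length(sys$groups$reference) == 0)
    stop("invariant violated: reference group is empty")
  invisible(sys)
}

#' @export
print.ToySystem <- function(x, ...) {
  cat(sprintf("<ToySystem %s> %d pseudo-atoms, %d wells, %d barriers\n",
              x$config$name, nrow(x$atoms), nrow(x$landscape$wells),
              nrow(x$landscape$barriers)))
  cat("  sites:", paste(rownames(x$sites), collapse = ", "), "\n")
  cat("  blocked paths:",
      if (length(x$landscape$blocked_paths)) paste(x$landscape$blocked_paths, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Landscape energy and analytic gradient at ion positions
#'
#' Total smooth potential: sum of well/barrier Gaussians, the one-sided
#' quadratic rho wall, and the cylindrical pore wall.
#'
#' @param sys a `ToySystem`
#' @param pos a length-3 position or an n x 3 matrix (angstrom)
#' @return list with `energy` (kJ/mol) and `gradient` (kJ/mol/A, n x 3)
#' @examples
#' sys <- build_toy_system(scenario_config(1))
#' potential_energy(sys, c(0, 0, 0))$energy  # deep: the M1 well
#' @export
potential_energy <- function(sys, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  if (!all(is.finite(pos))) stop("ion position must be finite")
  res <- cpp_potential(pos, sys$landscape)
  if (nrow(pos) == 1) res$gradient <- drop(res$gradient)
  res
}

#' Brute-force Boltzmann free-energy oracle
#'
#' Computes F(bin) = -kT log integral of exp(-U(x)/kT) over all ion positions
#' whose collective variables fall in the bin, by dense quadrature on a
#' regular 3D grid.  This is the independent oracle that reweighted surfaces
#' are checked against.
#'
#' @param sys a `ToySystem`
#' @param cv `"rho_cn"` for the 2D (rho, coordination-number) surface or
#'   `"rho"` for the 1D profile
#' @param breaks list of bin edges; defaults to rho in \[0, 25\] x 100 bins
#'   and CN in \[0, 8\] x 80 bins
#' @param temperature Kelvin (default 303)
#' @param spacing quadrature spacing in angstrom (default 0.25)
#' @param quad_box 2 x 3 matrix (rows lo, hi) bounding the quadrature;
#'   defaults to a box enclosing the full rho-wall sphere (wall_limit plus a
#'   3 A tail), i.e. the whole accessible region
#' @param cn_spec coordination-number definition, see [coordination_spec()]
#' @return a [fes_grid()] object with provenance `"oracle"`
#' @export
analytic_fes <- function(sys, cv = c("rho_cn", "rho"), breaks = NULL,
                         temperature = 303, spacing = 0.25, quad_box = NULL,
                         cn_spec = coordination_spec()) {
  cv <- match.arg(cv)
  if (is.null(breaks)) {
    breaks <- list(rho = seq(0, 25, length.out = 101))
    if (cv == "rho_cn") breaks$cn <- seq(0, 8, length.out = 81)
  }
  rc <- sys$landscape$ref_com
  if (is.null(quad_box)) {
    r <- sys$landscape$wall_limit + 3
    quad_box <- rbind(lo = rc - r, hi = rc + r)
  }
  gx <- seq(quad_box[1, 1] + spacing / 2, quad_box[2, 1], by = spacing)
  gy <- seq(quad_box[1, 2] + spacing / 2, quad_box[2, 2], by = spacing)
  gz <- seq(quad_box[1, 3] + spacing / 2, quad_box[2, 3], by = spacing)
  grp <- as.matrix(sys$atoms[, c("x", "y", "z")])
  if (!is.null(cn_spec$group)) grp <- grp[cn_spec$group, , drop = FALSE]
  ktemp <- kT(temperature)
  # accumulate Boltzmann mass slab-by-slab in z to bound memory
  nbin <- prod(vapply(breaks, function(b) length(b) - 1L, integer(1)))
  mass <- numeric(nbin); dims <- NULL
  chunk <- max(1L, floor(2e6 / (length(gx) * length(gy))))
  for (z0 in seq(1, length(gz), by = chunk)) {
    zi <- gz[z0:min(z0 + chunk - 1, length(gz))]
    pts <- as.matrix(expand.grid(x = gx, y = gy, z = zi,
                                 KEEP.OUT.ATTRS = FALSE))
    U <- cpp_potential(pts, sys$landscape)$energy
    w <- exp(-U / ktemp)
    samples <- data.frame(
      rho = sqrt((pts[, 1] - rc[1])^2 + (pts[, 2] - rc[2])^2 +
                   (pts[, 3] - rc[3])^2))
    if (cv == "rho_cn")
      samples$cn <- cpp_cn_values(pts, grp, cn_spec$r0, cn_spec$n, cn_spec$m)
    g <- .bin_mass(samples, w, breaks)
    mass <- mass + g$mass
    dims <- g$dim
  }
  g <- list(mass = mass, dim = dims)
  if (all(g$mass == 0))
    stop("grid excludes all probability mass")
  F <- -ktemp * log(g$mass)
  sampled <- is.finite(F)
  F[!sampled] <- NA_real_
  F <- F - min(F, na.rm = TRUE)
  fes_grid(breaks = breaks, F = array(F, dim = g$dim), sampled = array(sampled, dim = g$dim),
           temperature = temperature, provenance = "oracle",
           metadata = list(spacing = spacing, quad_box = quad_box))
}

# shared histogram helper: weighted mass per bin over arbitrary CV columns
.bin_mass <- function(samples, w, breaks) {
  nms <- names(breaks)
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- rep(1L, nrow(samples)); mult <- 1L; keep <- rep(TRUE, nrow(samples))
  for (k in seq_along(nms)) {
    b <- breaks[[k]]
    i <- findInterval(samples[[nms[k]]], b, rightmost.closed = TRUE)
    keep <- keep & i >= 1L & i <= nb[k]
    i[!keep] <- 1L
    idx <- idx + (i - 1L) * mult
    mult <- mult * nb[k]
  }
  mass <- numeric(prod(nb))
  if (any(keep)) {
    acc <- rowsum(w[keep], idx[keep])
    mass[as.integer(rownames(acc))] <- acc[, 1]
  }
  list(mass = mass, dim = nb)
}

#' Generate a structure pair related by a known hinge + vertical slide
#'
#' Returns the base structure and a copy in which the transport-domain
#' selection has been rotated by `hinge_angle` about the axis through
#' `pivot`, then translated by `vertical_shift` along the membrane normal.
#' Scaffold atoms are untouched.  Used as ground-truth fixtures for
#' [hinge_decompose()].
#'
#' @param base a `Structure` (see [read_pdb()])
#' @param hinge_angle rotation in degrees
#' @param hinge_axis unit axis vector
#' @param pivot rotation pivot; defaults to the centroid of the transport
#'   selection (the canonical pivot recovered by [hinge_decompose()])
#' @param vertical_shift translation along `membrane_normal` in angstrom
#' @param transport_selection integer or logical atom selection
#' @param membrane_normal unit vector, default +z
#' @param seed optional seed (reserved for jittered fixtures; unused when
#'   `noise = 0`)
#' @param noise isotropic Gaussian noise (A) added to the moved copy
#' @return list with elements `ref` and `mobile`
#' @export
make_conformer_pair <- function(base, hinge_angle, hinge_axis = c(1, 0, 0),
                                pivot = NULL, vertical_shift = 0,
                                transport_selection,
                                membrane_normal = c(0, 0, 1),
                                seed = NULL, noise = 0) {
  sel <- .as_index(transport_selection, nrow(base))
  if (length(sel) == 0) stop("transport selection is empty")
  if (abs(sqrt(sum(hinge_axis^2)) - 1) > 1e-8)
    stop("hinge axis must be a unit vector")
  xyz <- as.matrix(base[, c("x", "y", "z")])
  if (is.null(pivot)) pivot <- colMeans(xyz[sel, , drop = FALSE])
  R <- rotation_matrix(hinge_axis, hinge_angle * pi / 180)
  moved <- t(R %*% (t(xyz[sel, , drop = FALSE]) - pivot) + pivot +
               vertical_shift * membrane_normal)
  out <- base
  out[sel, c("x", "y", "z")] <- moved
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    out[sel, c("x", "y", "z")] <- out[sel, c("x", "y", "z")] +
      matrix(rnorm(length(sel) * 3, sd = noise), ncol = 3)
  }
  list(ref = base, mobile = out)
}

#' Rotation matrix from axis and angle (Rodrigues form)
#'
#' @param axis unit 3-vector
#' @param angle radians
#' @return 3 x 3 proper rotation matrix
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# accept logical or integer selections
.as_index <- function(sel, n) {
  if (is.logical(sel)) which(sel) else as.integer(sel)
}

#' Convert a ToySystem (optionally with an ion) to a Structure table
#'
#' Pseudo-atoms become ATOM records (one residue each, chain A, residue names
#' derived from the group tag); the ion, if given, becomes a ZN heteroatom.
#'
#' @param sys a `ToySystem`
#' @param ion_pos optional length-3 ion position
#' @param ion_occupancy occupancy recorded for the ion record
#' @return a `Structure` data frame
#' @export
as_structure <- function(sys, ion_pos = NULL, ion_occupancy = 1) {
  a <- sys$atoms
  resname <- c(reference = "REF", scaffold = "SCA", transport = "TRA",
               ligand = "LIG")[a$group]
  n <- nrow(a)
  df <- data.frame(
    serial = seq_len(n), name = ifelse(a$element == "C", "CA", a$element),
    element = a$element, resname = unname(resname), resid = seq_len(n),
    chain = "A", insert = "", x = a$x, y = a$y, z = a$z,
    occupancy = 1, bfactor = 0, het = FALSE, stringsAsFactors = FALSE)
  if (!is.null(ion_pos)) {
    df <- rbind(df, data.frame(serial = n + 1L, name = "ZN", element = "Zn",
                               resname = "ZN", resid = n + 1L, chain = "A",
                               insert = "", x = ion_pos[1], y = ion_pos[2],
                               z = ion_pos[3], occupancy = ion_occupancy,
                               bfactor = 0, het = TRUE))
  }
  structure(df, class = c("Structure", "data.frame"),
            title = paste("toy transporter", sys$config$name))
}

#' Write / read a scenario configuration as YAML
#'
#' @param config a `ScenarioConfig`
#' @param path file path
#' @param extra optional named list of additional keys (CV specs, radii, ...)
#' @return `read_scenario_config` returns a `ScenarioConfig`; the writer
#'   returns `path` invisibly
#' @export
write_scenario_config <- function(config, path, extra = list()) {
  yaml::write_yaml(c(unclass(config), extra), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario_config(y$name, m2_occupied = y$m2_occupied, m3_state = y$m3_state,
                  il2_folded = y$il2_folded)
}
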