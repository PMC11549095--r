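#' Center of mass of a group of atoms
#'
#' @param positions n x 3 matrix of positions (angstrom)
#' @param masses vector of positive masses; default equal masses, in which
#'   case the COM is the centroid
#' @return length-3 position
#' @examples
#' center_of_mass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3))  # (3, 0, 0)
#' @export
center_of_mass <- function(positions, masses = NULL) {
  positions <- rbind(positions)
  if (nrow(positions) == 0) stop("center of mass of an empty group")
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  if (any(masses <= 0)) stop("masses must be positive")
  colSums(positions * masses) / sum(masses)
}

#' Spherical collective variables of the ion about the reference group
#'
#' rho is the distance of the ion from the center of mass of the reference
#' group (the proxy for the transporter's TM bundle COM), theta the polar
#' angle from the membrane normal (+z), and phi the azimuthal angle
#' atan2(y, x).  phi is undefined on the polar axis; there it is reported as
#' 0 with a zero gradient, and the theta gradient is evaluated on the phi = 0
#' meridian so all values stay finite.
#'
#' @param ion_pos length-3 ion position
#' @param sys a `ToySystem` (supplies reference atoms and masses)
#' @param reference_group atom indices; default the system's reference group
#' @return list of three CV values, each `list(value, gradient)` with the
#'   gradient taken with respect to the ion position
#' @examples
#' sys <- build_toy_system(scenario_config(1))
#' spherical_cvs(sys$landscape$ref_com + c(0, 0, 5), sys)$rho$value  # 5
#' @export
spherical_cvs <- function(ion_pos, sys, reference_group = NULL) {
  if (is.null(reference_group)) reference_group <- sys$groups$reference
  if (length(reference_group) == 0) stop("reference group is empty")
  com <- center_of_mass(as.matrix(sys$atoms[reference_group, c("x", "y", "z")]),
                        sys$masses[reference_group])
  v <- as.numeric(ion_pos) - as.numeric(com)
  rho <- sqrt(sum(v^2))
  if (rho <= 1e-9)
    stop("degenerate geometry: ion coincides with the reference center of mass")
  ct <- max(-1, min(1, v[3] / rho))
  theta <- acos(ct)
  st <- sin(theta)
  if (st < 1e-9) {
    phi <- 0
    gtheta <- c(ct, 0, -st) / rho
    gphi <- c(0, 0, 0)
  } else {
    phi <- atan2(v[2], v[1])
    gtheta <- c(ct * cos(phi), ct * sin(phi), -st) / rho
    gphi <- c(-sin(phi), cos(phi), 0) / (rho * st)
  }
  list(rho = list(value = rho, gradient = v / rho),
       theta = list(value = theta, gradient = gtheta),
       phi = list(value = phi, gradient = gphi))
}

#' Coordination-number CV specification
#'
#' Rational switching function counting contacts between the ion and the
#' transporter pseudo-atoms: each pair contributes
#' (1 - (r/r0)^n) / (1 - (r/r0)^m).  The defaults r0 = 4 A, n = 8, m = 16
#' define a contact within about 4 A.  When m = 2n the term is evaluated as
#' 1 / (1 + (r/r0)^n), which removes the r = r0 singularity exactly (the two
#' forms are algebraically identical).
#'
#' @param r0 contact cutoff in angstrom (default 4)
#' @param n,m integer powers with m > n > 0 (defaults 8 and 16)
#' @param group atom indices of the counted group; `NULL` means all
#'   pseudo-atoms
#' @return a `CoordinationSpec` list
#' @export
coordination_spec <- function(r0 = 4, n = 8L, m = 16L, group = NULL) {
  if (!(m > n && n > 0)) stop("coordination powers must satisfy m > n > 0")
  if (r0 <= 0) stop("r0 must be positive")
  structure(list(r0 = r0, n = as.integer(n), m = as.integer(m), group = group),
            class = "CoordinationSpec")
}

# scalar switching term and derivative; vectorised over r
.switch_term <- function(r, spec) {
  x <- r / spec$r0
  if (spec$m == 2L * spec$n) {
    xn <- x^spec$n
    s <- 1 / (1 + xn)
    dsdx <- -spec$n * x^(spec$n - 1) / (1 + xn)^2
  } else {
    s <- dsdx <- numeric(length(x))
    at1 <- abs(x - 1) < 1e-10
    s[at1] <- spec$n / spec$m
    dsdx[at1] <- -0.5 * spec$n * (spec$m - spec$n) / spec$m
    xo <- x[!at1]
    xn <- xo^spec$n; xm <- xo^spec$m
    s[!at1] <- (1 - xn) / (1 - xm)
    dsdx[!at1] <- (-spec$n * xo^(spec$n - 1) * (1 - xm) +
                     spec$m * xo^(spec$m - 1) * (1 - xn)) / (1 - xm)^2
  }
  list(s = s, dsdr = dsdx / spec$r0)
}

#' Coordination number of the ion with the transporter atoms
#'
#' @param ion_pos length-3 ion position
#' @param sys a `ToySystem`
#' @param spec a [coordination_spec()]
#' @return `list(value, gradient)`; the gradient is with respect to the ion
#'   position and is analytic
#' @examples
#' sys <- build_toy_system(scenario_config(1))
#' coordination_number(sys$sites["M1", ], sys)$value  # about 4 ligands
#' @export
coordination_number <- function(ion_pos, sys, spec = coordination_spec()) {
  grp <- as.matrix(sys$atoms[, c("x", "y", "z")])
  if (!is.null(spec$group)) grp <- grp[spec$group, , drop = FALSE]
  d <- sweep(grp, 2, as.numeric(ion_pos), `-`)
  r <- sqrt(rowSums(d^2))
  sw <- .switch_term(r, spec)
  grad <- colSums((-sw$dsdr / pmax(r, 1e-12)) * d)
  list(value = sum(sw$s), gradient = grad)
}
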