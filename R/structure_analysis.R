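#' Read a PDB coordinate file into a Structure table
#'
#' Fixed-column ATOM/HETATM parsing is delegated to bio3d.  Alternate
#' locations are resolved by keeping the highest-occupancy conformer of each
#' (chain, residue, atom name, insertion) group; insertion codes are
#' preserved.  A file with MODEL blocks returns a list of Structures when
#' `multi = TRUE`.
#'
#' @param path PDB file
#' @param multi return all models as a list (default: first model only)
#' @return a `Structure` data frame with columns serial, name, element,
#'   resname, resid, chain, insert, x, y, z, occupancy, bfactor, het
#' @export
read_pdb <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  build <- function(xyz) {
    df <- data.frame(
      serial = a$eleno, name = a$elety, element = a$elesy,
      resname = a$resid, resid = a$resno, chain = a$chain,
      insert = ifelse(is.na(a$insert), "", a$insert),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = ifelse(is.na(a$o), 1, a$o),
      bfactor = ifelse(is.na(a$b), 0, a$b),
      het = a$type == "HETATM", stringsAsFactors = FALSE)
    df$chain[is.na(df$chain)] <- ""
    df$element[is.na(df$element)] <- ""
    # altLoc: keep the highest-occupancy conformer
    alt <- ifelse(is.na(a$alt), "", a$alt)
    if (any(nzchar(alt))) {
      key <- paste(df$chain, df$resid, df$insert, df$name)
      keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
        i[which.max(df$occupancy[i])]
      }), use.names = FALSE)
      df <- df[sort(keep), ]
      rownames(df) <- NULL
    }
    structure(df, class = c("Structure", "data.frame"), title = basename(path))
  }
  if (multi && nrow(pdb$xyz) > 1) {
    lapply(seq_len(nrow(pdb$xyz)), function(m)
      build(matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)))
  } else {
    build(matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE))
  }
}

#' Write a Structure (or list of model Structures) as PDB
#'
#' Records are written through bio3d in fixed-column format with 1-based
#' residue numbering and populated occupancy and B-factor columns; a list of
#' Structures is written as MODEL/ENDMDL blocks.
#'
#' @param s a `Structure` or list of Structures
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(s, path) {
  one <- function(df, file) {
    bio3d::write.pdb(
      file = file,
      xyz = as.numeric(t(as.matrix(df[, c("x", "y", "z")]))),
      type = ifelse(df$het, "HETATM", "ATOM"),
      resno = df$resid, resid = df$resname, eleno = df$serial,
      elety = df$name, chain = ifelse(nzchar(df$chain), df$chain, " "),
      insert = ifelse(nzchar(df$insert), df$insert, ""),
      o = df$occupancy, b = df$bfactor, elesy = df$element)
  }
  if (is.data.frame(s)) {
    one(s, path)
  } else {
    blocks <- vapply(seq_along(s), function(m) {
      tmp <- tempfile(fileext = ".pdb")
      on.exit(unlink(tmp))
      one(s[[m]], tmp)
      lines <- readLines(tmp)
      lines <- lines[!grepl("^END", lines)]
      paste(c(sprintf("MODEL     %4d", m), lines, "ENDMDL"), collapse = "\n")
    }, character(1))
    writeLines(c(blocks, "END"), path)
  }
  invisible(path)
}

# parse "chain:resid:atom" selectors (list form also accepted)
.parse_selector <- function(sel) {
  if (is.list(sel)) return(sel)
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) stop("selector must be chain:resid:atom, got ", sel)
  list(chain = parts[1], resid = as.integer(parts[2]), name = parts[3])
}

.find_atom <- function(s, sel) {
  p <- .parse_selector(sel)
  i <- which(s$chain == p$chain & s$resid == p$resid & s$name == p$name)
  if (length(i) == 0)
    stop("no atom matches selector ", p$chain, ":", p$resid, ":", p$name)
  i[1]
}

#' Select atom indices of a Structure
#'
#' @param s a `Structure`
#' @param chain,resid,name,element,resname optional filters (vectors allowed)
#' @return integer indices
#' @export
sel_atoms <- function(s, chain = NULL, resid = NULL, name = NULL,
                      element = NULL, resname = NULL) {
  keep <- rep(TRUE, nrow(s))
  if (!is.null(chain)) keep <- keep & s$chain %in% chain
  if (!is.null(resid)) keep <- keep & s$resid %in% resid
  if (!is.null(name)) keep <- keep & s$name %in% name
  if (!is.null(element)) keep <- keep & s$element %in% element
  if (!is.null(resname)) keep <- keep & s$resname %in% resname
  which(keep)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation (det = +1, never a reflection) and
#' translation mapping the selected atoms of `mobile` onto those of `ref`.
#'
#' @param mobile,ref `Structure` tables (or n x 3 coordinate matrices)
#' @param selection paired atom indices applied to both (default all)
#' @return `list(R, t, rmsd)` such that `R x_mobile + t` approximates
#'   `x_ref`, with the RMSD over the selection
#' @export
kabsch_superpose <- function(mobile, ref, selection = NULL) {
  Xm <- if (is.data.frame(mobile)) as.matrix(mobile[, c("x", "y", "z")]) else as.matrix(mobile)
  Xr <- if (is.data.frame(ref)) as.matrix(ref[, c("x", "y", "z")]) else as.matrix(ref)
  if (!is.null(selection)) {
    sel <- .as_index(selection, nrow(Xm))
    Xm <- Xm[sel, , drop = FALSE]; Xr <- Xr[sel, , drop = FALSE]
  }
  if (nrow(Xm) != nrow(Xr)) stop("selections must pair equal atom counts")
  if (nrow(Xm) < 3) stop("need at least 3 paired atoms")
  cm <- colMeans(Xm); cr <- colMeans(Xr)
  A <- sweep(Xm, 2, cm); B <- sweep(Xr, 2, cr)
  sv_check <- svd(A)
  if (sv_check$d[2] < 1e-8 * max(sv_check$d[1], 1))
    stop("paired atoms are collinear; superposition is degenerate")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  fitted <- sweep(Xm %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - Xr)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

# angle (rad) and axis of a rotation matrix
.rotation_angle_axis <- function(R, fallback_axis = c(0, 0, 1)) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  angle <- acos(ct)
  if (angle < 1e-9) return(list(angle = 0, axis = fallback_axis))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(w^2)) < 1e-12) {
    # angle ~ pi: axis from eigenvector of eigenvalue +1
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, i])
  } else axis <- w / sqrt(sum(w^2))
  list(angle = angle, axis = axis / sqrt(sum(axis^2)))
}

#' Hinge + vertical-sliding decomposition of domain motion
#'
#' Aligns the two structures on the scaffold domain, fits the residual
#' transport-domain motion as a rigid transform, and decomposes it into a
#' hinge rotation about an axis line plus a translation along the membrane
#' normal.  Because a vertical translation can be absorbed into an offset of
#' a horizontal hinge axis, the decomposition is canonicalised by choosing
#' the axis line closest to the transport-domain centroid of the reference
#' structure; fixtures built by [make_conformer_pair()] with the default
#' (centroid) pivot are recovered exactly.
#'
#' @param pair list of two Structures `(ref, mobile)` (as returned by
#'   [make_conformer_pair()]) or the two structures given separately
#' @param mobile second structure when `pair` is the first
#' @param scaffold_selection,transport_selection atom indices valid in both
#' @param membrane_normal unit vector, default +z
#' @return a `HingeResult`: `angle_deg`, `axis` (unit), `pivot`, `vertical`
#'   (A along the normal), `residual_rmsd` (transport domain after applying
#'   the fitted transform) and `scaffold_rmsd`
#' @export
hinge_decompose <- function(pair, mobile = NULL, scaffold_selection,
                            transport_selection,
                            membrane_normal = c(0, 0, 1)) {
  if (is.null(mobile)) { ref <- pair$ref; mob <- pair$mobile }
  else { ref <- pair; mob <- mobile }
  ssel <- .as_index(scaffold_selection, nrow(ref))
  tsel <- .as_index(transport_selection, nrow(ref))
  if (length(ssel) < 3 || length(tsel) < 3)
    stop("scaffold and transport selections need at least 3 atoms each")
  n <- membrane_normal / sqrt(sum(membrane_normal^2))
  fit0 <- kabsch_superpose(mob, ref, ssel)
  Xmob <- as.matrix(mob[, c("x", "y", "z")])
  Xmob <- sweep(Xmob %*% t(fit0$R), 2, fit0$t, `+`)
  Xref <- as.matrix(ref[, c("x", "y", "z")])
  fit <- kabsch_superpose(Xref[tsel, , drop = FALSE],
                          Xmob[tsel, , drop = FALSE])
  R <- fit$R; tv <- fit$t
  centroid <- colMeans(Xref[tsel, , drop = FALSE])
  aa <- .rotation_angle_axis(R, fallback_axis = n)
  if (aa$angle < 1e-9) {
    pivot <- centroid
    vertical <- sum(tv * n)
    axis <- n
  } else {
    axis <- aa$axis
    # solve (I - R) c + v n = t for (c, v); among exact solutions pick the
    # axis point closest to the transport centroid
    M <- cbind(diag(3) - R, n)
    sv <- svd(M, nu = 3, nv = 4)
    tol <- max(sv$d) * 1e-9
    posv <- which(sv$d > tol)
    u0 <- sv$v[, posv, drop = FALSE] %*%
      ((t(sv$u[, posv, drop = FALSE]) %*% tv) / sv$d[posv])
    N <- sv$v[, setdiff(seq_len(4), posv), drop = FALSE]
    if (ncol(N) > 0) {
      Nc <- N[1:3, , drop = FALSE]
      rhs <- centroid - u0[1:3]
      alpha <- qr.solve(t(Nc) %*% Nc + 1e-12 * diag(ncol(N)), t(Nc) %*% rhs)
      u <- u0 + N %*% alpha
    } else u <- u0
    pivot <- as.numeric(u[1:3])
    vertical <- u[4]
  }
  structure(list(angle_deg = aa$angle * 180 / pi, axis = axis, pivot = pivot,
                 vertical = as.numeric(vertical),
                 residual_rmsd = fit$rmsd, scaffold_rmsd = fit0$rmsd),
            class = "HingeResult")
}

#' @export
print.HingeResult <- function(x, ...) {
  cat(sprintf(
    "<HingeResult> hinge %.3f deg about (%.3f, %.3f, %.3f), vertical slide %.3f A\n",
    x$angle_deg, x$axis[1], x$axis[2], x$axis[3], x$vertical))
  cat(sprintf("  residual RMSD %.2e A (scaffold RMSD %.2e A)\n",
              x$residual_rmsd, x$scaffold_rmsd))
  invisible(x)
}

#' Distance between two named atoms
#'
#' @param s a `Structure`
#' @param selA,selB selectors "chain:resid:atom" or lists
#' @return Euclidean distance in angstrom
#' @export
atom_distance <- function(s, selA, selB) {
  ia <- .find_atom(s, selA); ib <- .find_atom(s, selB)
  sqrt(sum((as.numeric(s[ia, c("x", "y", "z")]) -
              as.numeric(s[ib, c("x", "y", "z")]))^2))
}

#' Distance time series over an ensemble of structures
#'
#' @param structures list of `Structure` frames
#' @param selA,selB atom selectors
#' @return data frame with columns `frame` and `distance`
#' @export
distance_series <- function(structures, selA, selB) {
  d <- vapply(structures, atom_distance, numeric(1), selA = selA, selB = selB)
  data.frame(frame = seq_along(structures), distance = d)
}

#' Root-mean-square fluctuation per atom and residue
#'
#' All frames are aligned on `align_selection` (Kabsch) to the first frame;
#' RMSF_i = sqrt(mean |x_i - <x_i>|^2) for each selected atom, reported
#' per atom with a per-residue aggregation over C-alpha atoms.
#'
#' @param structures list of `Structure` frames (>= 2)
#' @param selection atoms to report (default all)
#' @param align_selection atoms used for alignment (default the selection)
#' @return data frame chain, resid, name, rmsf; attribute `per_residue`
#'   holds the C-alpha per-residue table
#' @export
rmsf <- function(structures, selection = NULL, align_selection = NULL) {
  if (length(structures) < 2) stop("RMSF needs at least two frames")
  s0 <- structures[[1]]
  if (is.null(selection)) selection <- seq_len(nrow(s0))
  selection <- .as_index(selection, nrow(s0))
  if (is.null(align_selection)) align_selection <- selection
  align_selection <- .as_index(align_selection, nrow(s0))
  coords <- lapply(structures, function(s) {
    X <- as.matrix(s[, c("x", "y", "z")])
    fit <- kabsch_superpose(X[align_selection, , drop = FALSE],
                            as.matrix(s0[align_selection, c("x", "y", "z")]))
    sweep(X %*% t(fit$R), 2, fit$t, `+`)
  })
  arr <- simplify2array(lapply(coords, function(X) X[selection, , drop = FALSE]))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- apply((arr - array(mean_pos, dim = dim(arr)))^2, c(1, 3), sum)
  r <- sqrt(rowMeans(dev2))
  out <- data.frame(chain = s0$chain[selection], resid = s0$resid[selection],
                    name = s0$name[selection], rmsf = r,
                    stringsAsFactors = FALSE)
  ca <- out[out$name == "CA", ]
  attr(out, "per_residue") <- ca[order(ca$chain, ca$resid),
                                 c("chain", "resid", "rmsf")]
  out
}

#' Synthetic stand-in for a crosslinked transport-site structure
#'
#' Builds a small SYNTHETIC coordinate set that mirrors the published
#' geometry of the metal sites of the crosslinked transporter variant: the
#' two scaffold/transport reporter C-alpha atoms 10.1 A apart (residues 95
#' and 214), the binuclear transport site with two Cd ions 4.4 A apart
#' (occupancies 0.85 and 0.42), a chloride 2.6 A from the M1 cadmium, an Hg
#' ion (occupancy 0.36) bridging the two reporter residues, and the M3 site
#' cadmium (occupancy 0.84) near its chelating residues 144/149/151/276.
#' This is NOT deposited data -- it is a generated fixture for exercising
#' the measurement pipeline (distances, occupancy lookup) offline.
#'
#' @return a `Structure` data frame
#' @export
synthetic_transport_site <- function() {
  atom <- function(serial, name, element, resname, resid, x, y, z,
                   occ = 1, b = 20, het = FALSE)
    data.frame(serial = serial, name = name, element = element,
               resname = resname, resid = resid, chain = "A", insert = "",
               x = x, y = y, z = z, occupancy = occ, bfactor = b, het = het,
               stringsAsFactors = FALSE)
  df <- rbind(
    atom(1, "CA", "C", "CYS", 95, 0, 0, 0),
    atom(2, "CA", "C", "CYS", 214, 10.1, 0, 0),
    atom(3, "CA", "C", "HIS", 177, 4, 4, 2),
    atom(4, "CA", "C", "ASP", 144, 6, -14, -2),
    atom(5, "CA", "C", "HIS", 149, 9, -15, 1),
    atom(6, "CA", "C", "HIS", 151, 7, -17, 2),
    atom(7, "CA", "C", "GLU", 276, 9, -16, -3),
    atom(8, "CD", "Cd", "CD", 401, 5, 3, 0, occ = 0.85, het = TRUE),
    atom(9, "CD", "Cd", "CD", 402, 5, 3, 4.4, occ = 0.42, het = TRUE),
    atom(10, "CL", "Cl", "CL", 403, 5, 3, -2.6, occ = 0.9, het = TRUE),
    atom(11, "HG", "Hg", "HG", 404, 5.05, 0, 0, occ = 0.36, het = TRUE),
    atom(12, "CD", "Cd", "CD", 405, 7.8, -15.5, -0.5, occ = 0.84, het = TRUE)
  )
  structure(df, class = c("Structure", "data.frame"),
            title = "synthetic transport-site stand-in")
}

#' Occupancy of the heteroatom bound at a site
#'
#' Finds the heteroatom of the requested element nearest to the centroid of
#' the hint atoms (within 5 A) and returns its occupancy field -- e.g. the
#' metal bound at a site defined by its coordinating residues.
#'
#' @param s a `Structure`
#' @param element element symbol of the heteroatom (e.g. "Cd", "Hg", "Zn")
#' @param hint selectors (vector/list) of atoms whose centroid marks the site
#' @param max_dist search radius in angstrom (default 5)
#' @return occupancy in \[0, 1\]
#' @export
site_occupancy <- function(s, element, hint, max_dist = 5) {
  if (is.character(hint)) hint <- as.list(hint)
  idx <- vapply(hint, function(h) .find_atom(s, h), integer(1))
  centroid <- colMeans(as.matrix(s[idx, c("x", "y", "z")]))
  cand <- which(s$het & toupper(s$element) == toupper(element))
  if (length(cand) == 0)
    stop("no heteroatom of element ", element, " in structure")
  d <- sqrt(rowSums(sweep(as.matrix(s[cand, c("x", "y", "z")]), 2,
                          centroid)^2))
  if (min(d) > max_dist)
    stop("no ", element, " heteroatom within ", max_dist,
         " A of the hinted site")
  s$occupancy[cand[which.min(d)]]
}
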