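#' Free-energy-surface grid container
#'
#' Holds free energies (kJ/mol, min-shifted to 0) on a regular 1D or 2D grid
#' over collective variables, a mask of sampled bins (unsampled bins are NA,
#' never zero-filled), the temperature, and provenance metadata ("oracle" or
#' "reweighted" plus run details).
#'
#' @param breaks named list of bin-edge vectors (axis order defines array
#'   dimensions)
#' @param F array of free energies, `NA` where unsampled
#' @param sampled logical array
#' @param temperature Kelvin
#' @param provenance "oracle" or "reweighted"
#' @param metadata free-form list (quadrature spacing, run seed, ...)
#' @return an `FESGrid` object
#' @export
fes_grid <- function(breaks, F, sampled, temperature, provenance,
                     metadata = list()) {
  mids <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  F <- array(F, dim = vapply(mids, length, integer(1)))
  sampled <- array(sampled, dim = dim(F))
  if (any(sampled) && abs(min(F[sampled]) ) > 1e-9)
    F <- F - min(F[sampled])
  structure(list(breaks = breaks, mids = mids, F = F, sampled = sampled,
                 temperature = temperature, provenance = provenance,
                 adjacency = if (length(breaks) == 1) "2-neighbor" else "8-neighbor",
                 metadata = metadata),
            class = "FESGrid")
}

#' @export
print.FESGrid <- function(x, ...) {
  cat(sprintf("<FESGrid %s> %s grid, %d/%d bins sampled, relief %.1f kJ/mol\n",
              x$provenance, paste(dim(x$F), collapse = " x "),
              sum(x$sampled), length(x$F),
              max(x$F[x$sampled]) - min(x$F[x$sampled])))
  invisible(x)
}

#' @export
plot.FESGrid <- function(x, kt_units = FALSE, ...) {
  f <- x$F
  if (kt_units) f <- f / kT(x$temperature)
  if (length(dim(f)) == 1 || length(x$mids) == 1) {
    plot(x$mids[[1]], f, type = "l", xlab = names(x$breaks)[1],
         ylab = if (kt_units) "F (kT)" else "F (kJ/mol)", ...)
  } else {
    graphics::filled.contour(x$mids[[1]], x$mids[[2]], f,
                             xlab = names(x$breaks)[1],
                             ylab = names(x$breaks)[2],
                             color.palette = grDevices::terrain.colors, ...)
  }
  invisible(x)
}

#' Per-frame reweighting weights for a biased trajectory
#'
#' `final_bias`: w_i proportional to exp(+V_final(s_i)/kT) where V_final is
#' the full deposited bias evaluated at each frame's CVs.  `time_dependent`:
#' w_i proportional to exp(+(V(s_i, t_i) - c(t_i))/kT), using the recorded
#' running bias and the standard well-tempered offset c(t) evaluated on a CV
#' grid after each deposition.  Weights are normalised to sum to 1.  For an
#' unbiased trajectory both methods give uniform weights.
#'
#' @param traj a `Trajectory` (bias per frame recorded)
#' @param hills hill list; defaults to the trajectory's own
#' @param method `"final_bias"` or `"time_dependent"`
#' @param mtd the [wtmtd_config()] of the run (needed for `time_dependent`);
#'   defaults to the trajectory's own
#' @return numeric weights summing to 1
#' @export
frame_weights <- function(traj, hills = NULL,
                          method = c("final_bias", "time_dependent"),
                          mtd = NULL) {
  method <- match.arg(method)
  if (is.null(hills)) hills <- traj$hills
  if (is.null(traj$bias)) stop("trajectory has no bias records")
  ktemp <- kT(traj$config$temperature)
  if (nrow(hills) == 0) {
    w <- rep(1, length(traj$times))
    return(w / sum(w))
  }
  if (method == "final_bias") {
    V <- cpp_bias_values(.hills_matrix(hills),
                         as.matrix(traj$cv[, c("rho", "theta", "phi")]))
    logw <- V / ktemp
  } else {
    if (is.null(mtd)) mtd <- traj$mtd
    if (is.null(mtd)) stop("time_dependent reweighting needs the WT-MTD config")
    ct <- .tempered_offset(hills, mtd, ktemp)
    idx <- findInterval(traj$times, hills$time)  # 0 before first hill
    c_at <- c(0, ct)[idx + 1]
    logw <- (traj$bias - c_at) / ktemp
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

# c(t) after each deposition: kT log( <e^{a V}> / <e^{b V}> ) on a CV grid,
# a = gamma/((gamma-1) kT), b = 1/((gamma-1) kT)
.tempered_offset <- function(hills, mtd, ktemp) {
  g <- mtd$bias_factor
  dims <- mtd$dims
  ax <- list()
  if ("rho" %in% dims) ax$rho <- seq(0.25, 24.75, length.out = 50)
  if ("theta" %in% dims) ax$theta <- seq(0.05, pi - 0.05, length.out = 16)
  if ("phi" %in% dims) ax$phi <- seq(-pi + pi / 16, pi - pi / 16, length.out = 16)
  grid <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  full <- matrix(0, nrow(grid), 3)
  colnames(full) <- c("rho", "theta", "phi")
  full[, colnames(grid)] <- grid
  V <- numeric(nrow(full))
  ct <- numeric(nrow(hills))
  a <- g / ((g - 1) * ktemp); b <- 1 / ((g - 1) * ktemp)
  for (i in seq_len(nrow(hills))) {
    sig <- c(hills$sigma_rho[i], hills$sigma_theta[i], hills$sigma_phi[i])
    e <- numeric(nrow(full))
    for (k in 1:3) {
      if (sig[k] <= 0) next
      d <- full[, k] - as.numeric(hills[i, c("rho", "theta", "phi")[k]])
      if (k == 3) d <- (d + pi) %% (2 * pi) - pi
      e <- e + d^2 / (2 * sig[k]^2)
    }
    V <- V + hills$height[i] * exp(-e)
    ma <- max(a * V)
    mb <- max(b * V)
    ct[i] <- ktemp * ((ma + log(mean(exp(a * V - ma)))) -
                        (mb + log(mean(exp(b * V - mb)))))
  }
  ct
}

#' Weighted free-energy surface from CV samples
#'
#' F = -kT log of the weighted histogram over the grid, min-shifted to 0;
#' empty bins are masked.  Scaling all weights by a constant leaves the
#' surface unchanged.
#'
#' @param samples data frame (or matrix) with one column per CV named as in
#'   `breaks` (typically `rho` and `cn`)
#' @param weights per-sample weights
#' @param breaks named list of bin-edge vectors
#' @param temperature Kelvin
#' @param metadata provenance details to store
#' @return a [fes_grid()] with provenance `"reweighted"`
#' @export
weighted_fes <- function(samples, weights, breaks, temperature = 303,
                         metadata = list()) {
  samples <- as.data.frame(samples)
  if (nrow(samples) != length(weights))
    stop("samples and weights must have the same length")
  g <- .bin_mass(samples, weights, breaks)
  if (all(g$mass == 0)) stop("no samples fall inside the grid")
  ktemp <- kT(temperature)
  F <- -ktemp * log(g$mass)
  sampled <- is.finite(F)
  F[!sampled] <- NA_real_
  fes_grid(breaks = breaks, F = F, sampled = sampled,
           temperature = temperature, provenance = "reweighted",
           metadata = metadata)
}

# flat-index neighbors under the grid adjacency
.neighbors <- function(i, dims) {
  if (length(dims) == 1) {
    out <- c(i - 1L, i + 1L)
    return(out[out >= 1L & out <= dims[1]])
  }
  nx <- dims[1]; ny <- dims[2]
  ix <- (i - 1L) %% nx + 1L
  iy <- (i - 1L) %/% nx + 1L
  out <- integer(0)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    jx <- ix + dx; jy <- iy + dy
    if (jx >= 1 && jx <= nx && jy >= 1 && jy <= ny)
      out <- c(out, (jy - 1L) * nx + jx)
  }
  out
}

#' Local free-energy basins of an FES
#'
#' Finds basins by a watershed sweep in order of increasing F, then merges
#' away minima whose depth (lowest connecting saddle minus basin minimum) is
#' below `depth_threshold`, so histogram-noise minima are suppressed.  The
#' global basin's depth is the total relief of the surface.  Basins are
#' labeled in increasing order of their minimum free energy.  Adding a
#' constant to the surface does not change the result.
#'
#' @param fes an `FESGrid`
#' @param depth_threshold kJ/mol (default 1 kT at the grid temperature)
#' @return list of `Basin` objects: `label`, `bins` (flat indices),
#'   `min_bin`, `F_min`, `depth`; possibly empty
#' @export
find_minima <- function(fes, depth_threshold = kT(fes$temperature)) {
  dims <- dim(fes$F)
  Fv <- as.vector(fes$F)
  sampled <- as.vector(fes$sampled)
  ord <- order(Fv, na.last = NA)
  label <- integer(length(Fv))
  minbin <- integer(0); fmin <- numeric(0)
  saddle <- list()  # saddle[[paste(i,j)]] = lowest meeting F
  skey <- function(i, j) paste(min(i, j), max(i, j))
  for (b in ord) {
    nb <- .neighbors(b, dims)
    nb <- nb[label[nb] > 0L]
    if (length(nb) == 0) {
      minbin <- c(minbin, b); fmin <- c(fmin, Fv[b])
      label[b] <- length(minbin)
    } else {
      labs <- unique(label[nb])
      best <- labs[which.min(fmin[labs])]
      label[b] <- best
      for (l in setdiff(labs, best)) {
        k <- skey(best, l)
        if (is.null(saddle[[k]])) saddle[[k]] <- Fv[b]
      }
    }
  }
  nb0 <- length(minbin)
  if (nb0 == 0) return(list())
  S <- matrix(Inf, nb0, nb0)
  for (k in names(saddle)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    S[ij[1], ij[2]] <- S[ij[2], ij[1]] <- saddle[[k]]
  }
  alive <- rep(TRUE, nb0)
  parent <- seq_len(nb0)
  repeat {
    worst <- NA; worst_depth <- Inf; worst_to <- NA
    for (i in which(alive)) {
      lower <- which(alive & fmin < fmin[i])
      if (length(lower) == 0) next  # global basin
      d <- S[i, lower]
      if (all(!is.finite(d))) next  # disconnected: kept
      j <- lower[which.min(d)]
      dep <- min(d) - fmin[i]
      if (dep < worst_depth) { worst_depth <- dep; worst <- i; worst_to <- j }
    }
    if (!is.finite(worst_depth) || worst_depth >= depth_threshold) break
    alive[worst] <- FALSE
    parent[parent == worst] <- worst_to
    S[worst_to, ] <- pmin(S[worst_to, ], S[worst, ])
    S[, worst_to] <- pmin(S[, worst_to], S[, worst])
    S[worst_to, worst_to] <- Inf
  }
  # resolve merge chains
  resolve <- function(i) { while (!alive[i]) i <- parent[i]; i }
  label[label > 0L] <- vapply(label[label > 0L], resolve, integer(1))
  kept <- which(alive)
  relief <- max(Fv[sampled]) - min(Fv[sampled])
  basins <- list()
  for (i in kept) {
    lower <- which(alive & fmin < fmin[i])
    dep <- if (length(lower) == 0) relief else min(S[i, lower]) - fmin[i]
    if (dep < depth_threshold) next
    basins[[length(basins) + 1L]] <-
      structure(list(label = NA_integer_, bins = which(label == i),
                     min_bin = minbin[i], F_min = fmin[i], depth = dep),
                class = "Basin")
  }
  if (length(basins) == 0) return(list())
  o <- order(vapply(basins, `[[`, numeric(1), "F_min"))
  basins <- basins[o]
  for (i in seq_along(basins)) basins[[i]]$label <- i
  basins
}

#' Flat bin index of a CV point on an FES grid
#'
#' @param fes an `FESGrid`
#' @param point named (or axis-ordered) CV values
#' @return flat index into `fes$F`, or NA if outside the grid
#' @export
fes_bin_index <- function(fes, point) {
  point <- as.numeric(point)
  dims <- dim(fes$F)
  idx <- 0L; mult <- 1L
  for (k in seq_along(fes$breaks)) {
    i <- findInterval(point[k], fes$breaks[[k]], rightmost.closed = TRUE)
    if (i < 1 || i > dims[k]) return(NA_integer_)
    idx <- idx + (i - 1L) * mult
    mult <- mult * dims[k]
  }
  idx + 1L
}

#' Minimax (watershed) path between two basins
#'
#' Returns the path through sampled bins that minimises the maximum free
#' energy along it, and the barrier = max F on the path minus the minimum of
#' basin A.  This is the coarse-grid analogue of the physical saddle.
#'
#' @param fes an `FESGrid`
#' @param basinA,basinB `Basin` objects (from [find_minima()]) or flat bin
#'   indices
#' @return `list(path, barrier)`; `path` is the vector of flat bin indices
#'   from A's minimum to B's minimum (empty if A == B)
#' @export
min_energy_path <- function(fes, basinA, basinB) {
  start <- if (inherits(basinA, "Basin")) basinA$min_bin else as.integer(basinA)
  goal <- if (inherits(basinB, "Basin")) basinB$min_bin else as.integer(basinB)
  dims <- dim(fes$F)
  Fv <- as.vector(fes$F)
  sampled <- as.vector(fes$sampled)
  if (!sampled[start] || !sampled[goal]) stop("basin minimum is unsampled")
  if (start == goal) return(list(path = integer(0), barrier = 0))
  n <- length(Fv)
  cost <- rep(Inf, n); prev <- rep(NA_integer_, n); done <- rep(FALSE, n)
  cost[start] <- Fv[start]
  repeat {
    cand <- which(!done & is.finite(cost))
    if (length(cand) == 0)
      stop("basins are not connected through sampled bins")
    u <- cand[which.min(cost[cand])]
    if (u == goal) break
    done[u] <- TRUE
    for (v in .neighbors(u, dims)) {
      if (!sampled[v] || done[v]) next
      nc <- max(cost[u], Fv[v])
      if (nc < cost[v]) { cost[v] <- nc; prev[v] <- u }
    }
  }
  path <- goal
  while (path[1] != start) path <- c(prev[path[1]], path)
  list(path = path, barrier = cost[goal] - Fv[start])
}

#' Free-energy difference between two basins
#'
#' Delta F = -kT log( sum_B exp(-F/kT) / sum_A exp(-F/kT) ), the
#' population-weighted basin free-energy difference.
#'
#' @param fes an `FESGrid`
#' @param basinA,basinB `Basin` objects or flat-index vectors (disjoint)
#' @return kJ/mol (negative means B is more stable)
#' @export
delta_f <- function(fes, basinA, basinB) {
  ba <- if (inherits(basinA, "Basin")) basinA$bins else as.integer(basinA)
  bb <- if (inherits(basinB, "Basin")) basinB$bins else as.integer(basinB)
  if (length(ba) == 0 || length(bb) == 0) stop("empty basin")
  if (length(intersect(ba, bb)) > 0) stop("basins must be disjoint")
  Fv <- as.vector(fes$F)
  ktemp <- kT(fes$temperature)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  -ktemp * (lse(-Fv[bb] / ktemp) - lse(-Fv[ba] / ktemp))
}

#' Write / read an FES grid as columnar text
#'
#' One row per bin: bin centers, free energy (NA if unsampled) and the
#' sampled flag; header records axis names, temperature and provenance.
#'
#' @param fes an `FESGrid`
#' @param path file path
#' @return reader returns an `FESGrid`; writer returns `path` invisibly
#' @export
write_fes <- function(fes, path) {
  grid <- expand.grid(fes$mids, KEEP.OUT.ATTRS = FALSE)
  df <- cbind(grid, F = as.vector(fes$F), sampled = as.integer(fes$sampled))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# fes %s temperature %.6g axes %s bins %s",
                     fes$provenance, fes$temperature,
                     paste(names(fes$breaks), collapse = ","),
                     paste(dim(fes$F), collapse = ",")), con)
  writeLines(sprintf("# breaks %s",
                     paste(vapply(fes$breaks, function(b)
                       paste(sprintf("%.10g", b), collapse = ":"), ""),
                       collapse = " ")), con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fes
#' @export
read_fes <- function(path) {
  lines <- readLines(path, n = 2)
  h <- strsplit(lines[1], "\\s+")[[1]]
  prov <- h[3]; temp <- as.numeric(h[5])
  axes <- strsplit(h[7], ",")[[1]]
  brk_txt <- strsplit(sub("^# breaks ", "", lines[2]), " ")[[1]]
  breaks <- lapply(brk_txt, function(s) as.numeric(strsplit(s, ":")[[1]]))
  names(breaks) <- axes
  df <- utils::read.table(path, skip = 2, header = TRUE)
  fes_grid(breaks = breaks, F = df$F, sampled = df$sampled == 1,
           temperature = temp, provenance = prov)
}
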