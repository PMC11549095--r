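#' Well-tempered metadynamics configuration
#'
#' Defaults follow the production settings of the transporter study: hills of
#' initial height 1.0 kJ/mol deposited every 5 ps with widths 0.5 A in rho,
#' pi/16 in theta and pi/8 in phi, tempered with bias factor 10 at 303 K.
#' Hills live jointly in (rho, theta, phi); `dims` restricts biasing to a
#' subset (e.g. rho only for 1D checks) by zeroing the inactive widths.
#'
#' @param w0 initial hill height, kJ/mol
#' @param deposition_interval time between hills, ps
#' @param sigma named widths `c(rho=, theta=, phi=)`
#' @param bias_factor tempering factor gamma > 1
#' @param temperature Kelvin
#' @param dims character subset of `c("rho","theta","phi")` to bias
#' @return a `WTMTDConfig` list
#' @export
wtmtd_config <- function(w0 = 1.0, deposition_interval = 5,
                         sigma = c(rho = 0.5, theta = pi / 16, phi = pi / 8),
                         bias_factor = 10, temperature = 303,
                         dims = c("rho", "theta", "phi")) {
  stopifnot(bias_factor > 1, all(sigma > 0), w0 > 0)
  dims <- match.arg(dims, c("rho", "theta", "phi"), several.ok = TRUE)
  structure(list(w0 = w0, deposition_interval = deposition_interval,
                 sigma = sigma, bias_factor = bias_factor,
                 temperature = temperature, dims = dims),
            class = "WTMTDConfig")
}

# widths with inactive dimensions zeroed (the engine treats sigma <= 0 as
# "dimension not biased")
.active_sigma <- function(config) {
  s <- config$sigma[c("rho", "theta", "phi")]
  s[setdiff(c("rho", "theta", "phi"), config$dims)] <- 0
  unname(s)
}

#' Empty hill list
#'
#' Hills are kept as a data frame with one row per deposited Gaussian:
#' deposition time (ps), center in (rho, theta, phi), widths, height
#' (kJ/mol) and the bias factor in force at deposition.
#'
#' @param bias_factor recorded tempering factor
#' @return zero-row `HillRecord` data frame
#' @export
empty_hills <- function(bias_factor = 10) {
  structure(data.frame(time = numeric(0), rho = numeric(0),
                       theta = numeric(0), phi = numeric(0),
                       sigma_rho = numeric(0), sigma_theta = numeric(0),
                       sigma_phi = numeric(0), height = numeric(0),
                       biasf = numeric(0)),
            class = c("HillRecord", "data.frame"))
}

.hills_matrix <- function(hills) {
  as.matrix(hills[, c("time", "rho", "theta", "phi", "sigma_rho",
                      "sigma_theta", "sigma_phi", "height")])
}

#' Metadynamics bias and force at a CV point
#'
#' V(s) is the sum of deposited Gaussians; the phi difference is wrapped to
#' (-pi, pi], theta and rho are plain differences.  Dimensions whose stored
#' width is zero do not contribute.
#'
#' @param hills a `HillRecord` data frame
#' @param s CV point `c(rho, theta, phi)` (missing entries default 0)
#' @return `list(value, force)` with `force = -dV/ds` (length 3)
#' @export
bias_value <- function(hills, s) {
  s <- c(s, 0, 0)[1:3]
  if (nrow(hills) == 0)
    return(list(value = 0, force = c(0, 0, 0)))
  d_rho <- s[1] - hills$rho
  d_th <- s[2] - hills$theta
  d_phi <- (s[3] - hills$phi + pi) %% (2 * pi) - pi
  e <- rep(0, nrow(hills)); parts <- list()
  sig <- cbind(hills$sigma_rho, hills$sigma_theta, hills$sigma_phi)
  dd <- cbind(d_rho, d_th, d_phi)
  for (k in 1:3) {
    act <- sig[, k] > 0
    e[act] <- e[act] + dd[act, k]^2 / (2 * sig[act, k]^2)
  }
  g <- hills$height * exp(-e)
  force <- numeric(3)
  for (k in 1:3) {
    act <- sig[, k] > 0
    force[k] <- sum(g[act] * dd[act, k] / sig[act, k]^2)
  }
  list(value = sum(g), force = force)
}

#' Vectorised bias evaluation over many CV points
#'
#' @param hills a `HillRecord` data frame
#' @param points n x 3 matrix of (rho, theta, phi) points (missing columns
#'   default to 0)
#' @return numeric vector of bias values, kJ/mol
#' @export
bias_values <- function(hills, points) {
  points <- rbind(points)
  if (ncol(points) < 3)
    points <- cbind(points, matrix(0, nrow(points), 3 - ncol(points)))
  if (nrow(hills) == 0) return(numeric(nrow(points)))
  cpp_bias_values(.hills_matrix(hills), points)
}

#' Tempered height of the next hill
#'
#' h = w0 exp(-V / ((gamma - 1) kB T)): the deeper the bias already deposited
#' at the current CV point, the smaller the next hill, so the total bias
#' converges to -(1 - 1/gamma) F.
#'
#' @param V_at_s current bias at the deposition point, kJ/mol (>= 0)
#' @param config a [wtmtd_config()]
#' @return height in kJ/mol, in (0, w0\]
#' @examples
#' next_hill_height(0, wtmtd_config())       # 1.0
#' next_hill_height(22.674, wtmtd_config())  # about w0/e
#' @export
next_hill_height <- function(V_at_s, config) {
  stopifnot(V_at_s >= 0)
  config$w0 * exp(-V_at_s / ((config$bias_factor - 1) * kB * config$temperature))
}

#' Deposit a hill at a CV point
#'
#' Appends a `HillRecord` whose height is the tempered height evaluated at
#' `s` before deposition.
#'
#' @param hills current hill list
#' @param s CV point `c(rho, theta, phi)`
#' @param t deposition time, ps; must exceed the last deposition time
#' @param config a [wtmtd_config()]
#' @return updated hill list
#' @export
deposit <- function(hills, s, t, config) {
  if (nrow(hills) > 0 && t <= max(hills$time))
    stop("out-of-order deposition time")
  s <- c(s, 0, 0)[1:3]
  h <- next_hill_height(bias_value(hills, s)$value, config)
  sig <- .active_sigma(config)
  rec <- data.frame(time = t, rho = s[1], theta = s[2], phi = s[3],
                    sigma_rho = sig[1], sigma_theta = sig[2],
                    sigma_phi = sig[3], height = h,
                    biasf = config$bias_factor)
  structure(rbind(as.data.frame(hills), rec),
            class = c("HillRecord", "data.frame"))
}

#' Write / read hills as columnar text (HILLS-style)
#'
#' One header line, then one row per hill: time, center triple, width
#' triple, height, bias factor.  Values are written with full double
#' precision, so `read_hills(write_hills(x))` reproduces `x` to 1e-12.
#'
#' @param hills a `HillRecord` data frame
#' @param path file path
#' @return the reader returns a `HillRecord`; the writer returns `path`
#'   invisibly
#' @export
write_hills <- function(hills, path) {
  cols <- c("time", "rho", "theta", "phi", "sigma_rho", "sigma_theta",
            "sigma_phi", "height", "biasf")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("#", cols), collapse = " "), con)
  if (nrow(hills) > 0) {
    m <- as.matrix(hills[, cols])
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_hills
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#"))
    stop("malformed hills file (missing header): ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty_hills())
  cols <- c("time", "rho", "theta", "phi", "sigma_rho", "sigma_theta",
            "sigma_phi", "height", "biasf")
  out <- vector("list", length(body))
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(vals) != length(cols) || anyNA(vals))
      stop("malformed hills line ", i + 1, " in ", path)
    out[[i]] <- vals
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- cols
  if (any(!is.finite(df$height)) || any(df$height <= 0))
    stop("invalid hill height in ", path)
  structure(df, class = c("HillRecord", "data.frame"))
}
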