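test_that("frame weights reduce to uniform without bias and follow exponents", {
  traj <- fake_trajectory(matrix(rnorm(30), ncol = 3))
  w <- frame_weights(traj)
  expect_equal(w, rep(1 / 10, 10))
  # one hill of height kT log 2 at rho = 5: frame at the center carries
  # exactly twice the weight of a frame far away (final-bias reweighting)
  h <- empty_hills()
  h[1, ] <- list(time = 5, rho = 5, theta = 0, phi = 0, sigma_rho = 0.5,
                 sigma_theta = 0, sigma_phi = 0, height = kT() * log(2),
                 biasf = 10)
  tr <- fake_trajectory(rbind(c(0, 0, 0), c(1, 1, 1)))
  tr$cv <- data.frame(rho = c(20, 5), theta = 0, phi = 0, cn = 0)
  tr$hills <- h
  w <- frame_weights(tr, method = "final_bias")
  expect_equal(w[2] / w[1], 2, tolerance = 1e-12)
})

test_that("weighted FES handles masking, normalisation and errors", {
  breaks <- list(rho = seq(0, 10, by = 1), cn = seq(0, 4, by = 1))
  s <- data.frame(rho = rep(2.5, 5), cn = rep(1.5, 5))
  f <- weighted_fes(s, rep(0.2, 5), breaks)
  expect_equal(sum(f$sampled), 1)
  expect_equal(f$F[f$sampled], 0)
  expect_true(all(is.na(f$F[!f$sampled])))
  # scaling weights leaves the surface unchanged
  s2 <- data.frame(rho = runif(50, 0, 10), cn = runif(50, 0, 4))
  w <- runif(50)
  f1 <- weighted_fes(s2, w, breaks)
  f2 <- weighted_fes(s2, 2 * w, breaks)
  expect_equal(f1$F, f2$F)
  expect_error(weighted_fes(s2, w[-1], breaks), "same length")
  expect_error(weighted_fes(data.frame(rho = 99, cn = 99), 1, breaks),
               "no samples")
})

test_that("basin detection finds single wells and respects the threshold", {
  rc <- c(1.5, 0, 3)
  sys <- custom_system(wells = c(rc + c(0, 0, -5), 20, 1.5),
                       wall_limit = 10, wall_k = 50)
  fes <- analytic_fes(sys, "rho", breaks = list(rho = seq(0, 10, by = 0.5)),
                      spacing = 0.25)
  b <- find_minima(fes)
  expect_equal(length(b), 1)
  expect_equal(fes$mids$rho[b[[1]]$min_bin], 5, tolerance = 0.5)
  # a threshold above the total relief leaves nothing
  relief <- max(fes$F[fes$sampled])
  expect_length(find_minima(fes, depth_threshold = relief + 1), 0)
  # adding a constant does not change the basins
  fes2 <- fes
  fes2$F <- fes2$F + 7
  b2 <- find_minima(fes2)
  expect_equal(lapply(b2, `[[`, "bins"), lapply(b, `[[`, "bins"))
})

test_that("minimax path matches the threshold-connectivity oracle", {
  # 1D: barrier is the single saddle between the two wells
  f1 <- fes_grid(breaks = list(rho = 0:6),
                 F = c(0, 1, 3, 1.5, 0.5, 2), sampled = rep(TRUE, 6),
                 temperature = 303, provenance = "oracle")
  res <- min_energy_path(f1, 1L, 5L)
  expect_equal(res$barrier, 3)
  expect_equal(res$path, 1:5)
  expect_equal(min_energy_path(f1, 2L, 2L)$barrier, 0)
  expect_length(min_energy_path(f1, 2L, 2L)$path, 0)
  # disconnected grids raise
  f1$sampled[3] <- FALSE
  f1$F[3] <- NA
  expect_error(min_energy_path(f1, 1L, 5L), "not connected")
  # 2D random surfaces: minimax value equals the smallest threshold at
  # which start and goal are connected (independent BFS oracle)
  set.seed(99)
  for (rep in 1:5) {
    Fm <- matrix(runif(30, 0, 10), 6, 5)
    fes <- fes_grid(breaks = list(a = 0:6, b = 0:5), F = Fm,
                    sampled = matrix(TRUE, 6, 5), temperature = 303,
                    provenance = "oracle")
    Fv <- as.vector(fes$F)
    start <- which.min(Fv); goal <- which.max(-abs(Fv - stats::median(Fv)))
    if (start == goal) next
    connected_below <- function(t) {
      ok <- Fv <= t
      if (!ok[start] || !ok[goal]) return(FALSE)
      seen <- rep(FALSE, 30); queue <- start; seen[start] <- TRUE
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        for (v in zipmtd:::.neighbors(u, c(6, 5))) {
          if (ok[v] && !seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
        }
      }
      seen[goal]
    }
    oracle <- min(Filter(connected_below, sort(Fv)))
    res <- min_energy_path(fes, start, goal)
    expect_equal(max(Fv[res$path]), oracle)
    expect_equal(res$barrier, oracle - Fv[start])
  }
})

test_that("basin free-energy differences obey closed-form identities", {
  # mirror-symmetric double well: delta F = 0
  F <- c(0, 2, 4, 2, 0)
  fes <- fes_grid(breaks = list(rho = 0:5), F = F, sampled = rep(TRUE, 5),
                  temperature = 303, provenance = "oracle")
  expect_equal(delta_f(fes, 1:2, 4:5), 0, tolerance = 1e-12)
  # deepening B by delta in every bin lowers delta F by exactly delta
  fes2 <- fes
  fes2$F[4:5] <- fes2$F[4:5] - 1.7
  expect_equal(delta_f(fes2, 1:2, 4:5), -1.7, tolerance = 1e-12)
  expect_error(delta_f(fes, 1:3, 3:5), "disjoint")
  expect_error(delta_f(fes, integer(0), 4:5), "empty")
})

test_that("binned basin delta F agrees with direct quadrature", {
  sys <- double_well_system(d1 = 9, d2 = 6, width = 1.2, r1 = 5, r2 = 10)
  fes <- analytic_fes(sys, "rho", breaks = list(rho = seq(0, 14, by = 0.25)),
                      spacing = 0.25)
  mid <- 7.5
  A <- which(fes$mids$rho < mid & fes$sampled)
  B <- which(fes$mids$rho >= mid & fes$sampled)
  dF <- delta_f(fes, A, B)
  # independent route: direct 3D Boltzmann integral split at rho = mid
  rc <- sys$landscape$ref_com
  sp <- 0.25
  g <- seq(-17 + sp / 2, 17, by = sp)
  pts <- as.matrix(expand.grid(x = g + rc[1], y = g + rc[2], z = g + rc[3]))
  U <- potential_energy(sys, pts)$energy
  rho <- sqrt(rowSums(sweep(pts, 2, rc)^2))
  w <- exp(-U / kT())
  dF_direct <- -kT() * log(sum(w[rho >= mid]) / sum(w[rho < mid]))
  expect_lt(abs(dF - dF_direct), 0.3 * kT())
})

test_that("unbiased and well-tempered runs give consistent surfaces", {
  sys <- double_well_system(d1 = 8, d2 = 6, width = 1.2, r1 = 5, r2 = 10)
  breaks <- list(rho = seq(0, 14, by = 0.5))
  t_un <- run_simulation(sys, sim_config(n_steps = 1e6, seed = 21,
                                         record_stride = 20),
                         init = sys$landscape$ref_com + c(0, 0, -5))
  f_un <- weighted_fes(t_un$cv["rho"], frame_weights(t_un), breaks)
  t_bi <- run_simulation(sys, sim_config(n_steps = 1e6, seed = 22,
                                         record_stride = 20),
                         init = sys$landscape$ref_com + c(0, 0, -5),
                         mtd = wtmtd_config(dims = "rho"))
  f_bi <- weighted_fes(t_bi$cv["rho"],
                       frame_weights(t_bi, method = "time_dependent"), breaks)
  counts <- tabulate(findInterval(t_un$cv$rho, breaks$rho), length(breaks$rho) - 1)
  well <- counts > 200 & f_un$sampled & f_bi$sampled
  d <- (f_bi$F - f_un$F)[well]
  d <- d - mean(d)
  expect_lt(max(abs(d)), 0.5 * kT())
})

test_that("both reweighting estimators agree on the basin split at long times", {
  sys <- double_well_system(d1 = 8, d2 = 6, width = 1.2, r1 = 5, r2 = 10)
  breaks <- list(rho = seq(0, 14, by = 0.5))
  t_bi <- run_simulation(sys, sim_config(n_steps = 4e6, seed = 22,
                                         record_stride = 20),
                         init = sys$landscape$ref_com + c(0, 0, -5),
                         mtd = wtmtd_config(dims = "rho"))
  f_td <- weighted_fes(t_bi$cv["rho"],
                       frame_weights(t_bi, method = "time_dependent"), breaks)
  f_fb <- weighted_fes(t_bi$cv["rho"],
                       frame_weights(t_bi, method = "final_bias"), breaks)
  mid <- 7.5
  A <- which(f_td$mids$rho < mid & f_td$sampled & f_fb$sampled)
  B <- which(f_td$mids$rho >= mid & f_td$sampled & f_fb$sampled)
  expect_lt(abs(delta_f(f_td, A, B) - delta_f(f_fb, A, B)), 0.2 * kT())
})

test_that("the rho-shell entropy shows up in sampled surfaces", {
  sys <- flat_system(wall_limit = 14, wall_k = 50)
  traj <- run_simulation(sys, sim_config(n_steps = 1e6, seed = 17,
                                         record_stride = 10),
                         init = sys$landscape$ref_com + c(0, 0, -7))
  breaks <- list(rho = seq(0, 14, by = 1))
  f <- weighted_fes(traj$cv["rho"], frame_weights(traj), breaks)
  r1 <- 5.5; r2 <- 10.5
  i1 <- findInterval(r1, breaks$rho); i2 <- findInterval(r2, breaks$rho)
  expected <- -2 * kT() * log(r2 / r1)
  expect_equal(f$F[i2] - f$F[i1], expected, tolerance = 0.15)
  fo <- analytic_fes(sys, "rho", breaks = breaks, spacing = 0.25)
  expect_equal(fo$F[i2] - fo$F[i1], expected, tolerance = 0.02)
})

test_that("FES text serialisation round-trips", {
  sys <- double_well_system()
  fes <- analytic_fes(sys, "rho", breaks = list(rho = seq(0, 14, by = 0.5)),
                      spacing = 0.5)
  path <- tempfile(fileext = ".fes")
  write_fes(fes, path)
  back <- read_fes(path)
  expect_equal(back$F, fes$F, tolerance = 1e-6)
  expect_equal(back$sampled, fes$sampled)
  expect_equal(back$breaks$rho, fes$breaks$rho)
  expect_identical(back$provenance, "oracle")
})
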