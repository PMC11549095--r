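test_that("PDB writing and reading round-trip to format precision", {
  sys <- toy1()
  s <- as_structure(sys, ion_pos = c(0.1234, -2.5678, 3.14159),
                    ion_occupancy = 0.85)
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  back <- read_pdb(path)
  expect_equal(nrow(back), nrow(s))
  expect_equal(back$x, s$x, tolerance = 1e-3)
  expect_equal(back$y, s$y, tolerance = 1e-3)
  expect_equal(back$z, s$z, tolerance = 1e-3)
  expect_equal(back$occupancy, s$occupancy, tolerance = 1e-2)
  expect_equal(back$resid, s$resid)
  expect_equal(back$name, s$name)
  expect_equal(back$het, s$het)
  expect_error(read_pdb(tempfile()), "no such file")
})

test_that("multi-model files return one Structure per model", {
  s1 <- synthetic_structure(n = 10, seed = 1)
  s2 <- s1; s2$x <- s2$x + 1
  path <- tempfile(fileext = ".pdb")
  write_pdb(list(s1, s2), path)
  models <- read_pdb(path, multi = TRUE)
  expect_length(models, 2)
  expect_equal(models[[2]]$x - models[[1]]$x, rep(1, 10), tolerance = 1e-3)
})

test_that("the highest-occupancy altLoc conformer is kept", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA  ALA A   2       5.000   0.000   0.000  1.00 10.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  s <- read_pdb(path)
  expect_equal(nrow(s), 2)
  expect_equal(s$x[s$resid == 1], 0, tolerance = 1e-6)
  expect_equal(s$occupancy[s$resid == 1], 0.6)
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  s <- synthetic_structure(n = 25, seed = 2)
  self <- kabsch_superpose(s, s)
  expect_equal(self$R, diag(3), tolerance = 1e-10)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  R30 <- rotation_matrix(c(0, 0, 1), 30 * pi / 180)
  moved <- s
  moved[, c("x", "y", "z")] <- t(R30 %*% t(as.matrix(s[, c("x", "y", "z")])))
  fit <- kabsch_superpose(s, moved)
  expect_equal(fit$R, R30, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(acos((sum(diag(fit$R)) - 1) / 2) * 180 / pi, 30,
               tolerance = 1e-6)
})

test_that("superposition never returns a reflection and is rigidly invariant", {
  s <- synthetic_structure(n = 20, seed = 3)
  mirrored <- s
  mirrored$z <- -mirrored$z
  fit <- kabsch_superpose(s, mirrored)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
  # RMSD is invariant under an arbitrary rigid pre-transform of mobile
  pre <- rotation_matrix(c(1, 1, 0) / sqrt(2), 0.7)
  s2 <- s
  s2[, c("x", "y", "z")] <-
    sweep(as.matrix(s[, c("x", "y", "z")]) %*% t(pre), 2, c(3, -2, 5), `+`)
  expect_equal(kabsch_superpose(s2, mirrored)$rmsd, fit$rmsd,
               tolerance = 1e-8)
  expect_error(kabsch_superpose(s[1:2, ], s[1:2, ]), "at least 3")
  coll <- s[1:5, ]
  coll[, c("x", "y", "z")] <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(coll, coll), "collinear")
})

test_that("superposition RMSD agrees with the bio3d reference", {
  s <- synthetic_structure(n = 30, seed = 4)
  noisy <- s
  set.seed(9)
  noisy[, c("x", "y", "z")] <- as.matrix(s[, c("x", "y", "z")]) %*%
    t(rotation_matrix(c(0, 1, 0), 0.4)) + matrix(rnorm(90, sd = 0.3), ncol = 3)
  ours <- kabsch_superpose(noisy, s)$rmsd
  xyz_fixed <- as.numeric(t(as.matrix(s[, c("x", "y", "z")])))
  xyz_mob <- as.numeric(t(as.matrix(noisy[, c("x", "y", "z")])))
  ref <- bio3d::fit.xyz(fixed = xyz_fixed, mobile = xyz_mob,
                        fixed.inds = 1:90, mobile.inds = 1:90)
  rmsd_ref <- sqrt(mean(colSums(matrix((ref - xyz_fixed)^2, nrow = 3))))
  expect_equal(ours, rmsd_ref, tolerance = 1e-6)
})

test_that("hinge decomposition recovers planted motions exactly", {
  base <- synthetic_structure(n = 60, seed = 5)
  ssel <- 1:30; tsel <- 31:60
  pair <- make_conformer_pair(base, 15, c(1, 0, 0), vertical_shift = 6,
                              transport_selection = tsel)
  h <- hinge_decompose(pair, scaffold_selection = ssel,
                       transport_selection = tsel)
  expect_equal(h$angle_deg, 15, tolerance = 1e-6)
  expect_equal(h$vertical, 6, tolerance = 1e-6)
  expect_lt(h$residual_rmsd, 1e-8)
  # identical structures: no motion
  h0 <- hinge_decompose(list(ref = base, mobile = base),
                        scaffold_selection = ssel, transport_selection = tsel)
  expect_equal(h0$angle_deg, 0, tolerance = 1e-9)
  expect_equal(h0$vertical, 0, tolerance = 1e-9)
  # pure vertical translation decomposes as slide only
  slid <- base
  slid[tsel, "z"] <- slid[tsel, "z"] + 6
  hz <- hinge_decompose(list(ref = base, mobile = slid),
                        scaffold_selection = ssel, transport_selection = tsel)
  expect_lt(hz$angle_deg, 1e-4)
  expect_equal(hz$vertical, 6, tolerance = 1e-6)
})

test_that("hinge decomposition is exact across random planted fixtures", {
  base <- synthetic_structure(n = 80, seed = 6)
  ssel <- 1:40; tsel <- 41:80
  set.seed(123)
  for (i in 1:25) {
    ang <- runif(1, 1, 40)
    shift <- runif(1, -8, 8)
    ax <- c(rnorm(2), 0); ax <- ax / sqrt(sum(ax^2))  # horizontal hinge axis
    pair <- make_conformer_pair(base, ang, ax, vertical_shift = shift,
                                transport_selection = tsel)
    h <- hinge_decompose(pair, scaffold_selection = ssel,
                         transport_selection = tsel)
    expect_equal(h$angle_deg, ang, tolerance = 1e-6)
    expect_equal(h$vertical, shift, tolerance = 1e-6)
    expect_lt(h$residual_rmsd, 1e-8)
    expect_equal(abs(sum(h$axis * ax)), 1, tolerance = 1e-6)
    # arbitrary pivots: parameters may be absorbed differently but the
    # fitted transform itself stays exact
    pair2 <- make_conformer_pair(base, ang, ax, pivot = rnorm(3, sd = 10),
                                 vertical_shift = shift,
                                 transport_selection = tsel)
    h2 <- hinge_decompose(pair2, scaffold_selection = ssel,
                          transport_selection = tsel)
    expect_lt(h2$residual_rmsd, 1e-8)
    expect_equal(h2$angle_deg, ang, tolerance = 1e-6)
  }
})

test_that("atom distances and series behave on fixtures", {
  s <- synthetic_structure(n = 4, seed = 7)
  s[, c("x", "y", "z")] <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1),
                                 c(2, 2, 2))
  expect_equal(atom_distance(s, "A:1:CA", "A:2:CA"), 5)
  expect_error(atom_distance(s, "A:1:CA", "B:9:CA"), "B:9:CA")
  frames <- lapply(0:5, function(i) { si <- s; si$x[1] <- i; si })
  ds <- distance_series(frames, "A:1:CA", "A:3:CA")
  expect_equal(nrow(ds), 6)
  expect_equal(ds$distance,
               vapply(0:5, function(i) sqrt((1 - i)^2 + 2), numeric(1)))
  const <- distance_series(rep(list(s), 4), "A:1:CA", "A:2:CA")
  expect_equal(const$distance, rep(5, 4))
})

test_that("the synthetic transport-site stand-in reproduces its planted values", {
  s <- synthetic_transport_site()
  expect_equal(atom_distance(s, "A:95:CA", "A:214:CA"), 10.1, tolerance = 1e-9)
  cd1 <- which(s$resid == 401); cd2 <- which(s$resid == 402)
  d12 <- sqrt(sum((as.numeric(s[cd1, c("x","y","z")]) -
                     as.numeric(s[cd2, c("x","y","z")]))^2))
  expect_equal(d12, 4.4, tolerance = 1e-9)
  # occupancy lookups via the coordinating-residue hints
  expect_equal(site_occupancy(s, "Cd", c("A:177:CA", "A:95:CA")), 0.85)
  expect_equal(site_occupancy(s, "Hg", c("A:95:CA", "A:214:CA")), 0.36)
  expect_equal(site_occupancy(s, "Cd",
                              c("A:144:CA", "A:149:CA", "A:151:CA", "A:276:CA")),
               0.84)
  expect_error(site_occupancy(s, "Zn", "A:95:CA"), "no heteroatom")
  # round-trips through PDB like any structure
  path <- tempfile(fileext = ".pdb")
  write_pdb(s, path)
  back <- read_pdb(path)
  expect_equal(site_occupancy(back, "Cd",
                              c("A:144:CA", "A:149:CA", "A:151:CA", "A:276:CA")),
               0.84)
})

test_that("RMSF separates mobile from static atoms and matches the Gaussian law", {
  base <- synthetic_structure(n = 12, seed = 8)
  sigma <- 0.4
  set.seed(77)
  frames <- lapply(1:8000, function(i) {
    s <- base
    s[11:12, c("x", "y", "z")] <- s[11:12, c("x", "y", "z")] +
      matrix(rnorm(6, sd = sigma), ncol = 3)
    s
  })
  expect_error(rmsf(frames[1]), "at least two")
  r <- rmsf(frames, align_selection = 1:10)
  expect_lt(max(r$rmsf[1:10]), 1e-10)
  expect_equal(mean(r$rmsf[11:12]), sigma * sqrt(3), tolerance = 0.02)
  # identical frames have zero fluctuation everywhere
  r0 <- rmsf(rep(list(base), 3), align_selection = 1:10)
  expect_equal(max(r0$rmsf), 0, tolerance = 1e-12)
})
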