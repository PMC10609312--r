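random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

test_that("superposition removes rigid motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-10)
  R <- random_rotation()
  moved <- sweep(ref %*% t(R), 2, c(3, -7, 1), "+")
  fit <- kabsch_superpose(ref, moved)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$coords, ref, tolerance = 1e-8)
})

test_that("Kabsch matches a brute-force rotation search and bio3d", {
  set.seed(2)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  mobile <- ref + matrix(rnorm(15, sd = 0.7), 5, 3)
  got <- kabsch_superpose(ref, mobile)$rmsd
  # refined random-rotation search oracle (centered clouds; translation is
  # optimal at the centroid)
  best <- oracle_kabsch_rmsd(ref, mobile)
  expect_lte(got, best + 1e-9)
  expect_equal(got, best, tolerance = 1e-2)
  # independent package oracle
  fit <- suppressWarnings(bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(mobile))))
  rmsd_b <- sqrt(mean(colSums(matrix((fit - as.numeric(t(ref)))^2, 3))))
  expect_equal(got, rmsd_b, tolerance = 1e-6)
})

test_that("superposition errors on degenerate input", {
  expect_error(kabsch_superpose(matrix(0, 4, 3), matrix(0, 4, 3)), "degenerate")
  expect_error(kabsch_superpose(matrix(1, 4, 3), matrix(1, 5, 3)), "congruent")
})

test_that("RMSD series is zero for static and rigidly rotating trajectories", {
  set.seed(3)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  static <- array(rep(base, each = 4), c(4, 10, 3))
  expect_equal(rmsd_series(trajectory(static))$rmsd, rep(0, 4), tolerance = 1e-9)
  rot <- array(0, c(4, 10, 3))
  for (t in 1:4) rot[t, , ] <- sweep(base %*% t(random_rotation()), 2, rnorm(3), "+")
  expect_equal(rmsd_series(trajectory(rot))$rmsd, rep(0, 4), tolerance = 1e-7)
})

test_that("RMSD is symmetric and invariant to pre-rotation", {
  set.seed(4)
  a <- matrix(rnorm(24, sd = 3), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-9)
  R <- random_rotation()
  expect_equal(kabsch_superpose(a, b %*% t(R))$rmsd,
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-9)
})

test_that("RMSF is zero for static input and d for a lone oscillator", {
  base <- matrix(rnorm(150, sd = 8), 50, 3)
  static <- array(rep(base, each = 3), c(3, 50, 3))
  expect_equal(rmsf_profile(trajectory(static))$rmsf, rep(0, 50), tolerance = 1e-9)
  expect_error(rmsf_profile(trajectory(static[1, , , drop = FALSE])), "2 frames")
  # one node oscillating +-d along x at the centroid of the rest
  d <- 1.2
  co <- array(rep(base, each = 40), c(40, 50, 3))
  co[, 1, 1] <- mean(base[-1, 1]) + d * rep(c(1, -1), 20)
  co[, 1, 2] <- mean(base[-1, 2]); co[, 1, 3] <- mean(base[-1, 3])
  prof <- rmsf_profile(trajectory(co))
  expect_equal(prof$rmsf[1], d, tolerance = 0.05)
  expect_lt(max(prof$rmsf[-1]), 0.1)
})

test_that("RMSF is invariant under a global rigid motion of all frames", {
  set.seed(6)
  tr <- sample_enm_trajectory(ca_structure(1:30, rep("ALA", 30),
                                           packed_cluster(30, radius = 9, seed = 6)),
                              n_frames = 50, amplitude = 0.5, seed = 2)
  R <- random_rotation()
  co2 <- tr$coords
  for (t in seq_len(dim(co2)[1])) {
    co2[t, , ] <- sweep(co2[t, , ] %*% t(R), 2, c(5, 5, -2), "+")
  }
  expect_equal(rmsf_profile(trajectory(co2))$rmsf, rmsf_profile(tr)$rmsf,
               tolerance = 1e-7)
})

test_that("sampled trajectories fluctuate about the generating amplitude", {
  s <- two_domain_fixture()$open
  tr <- sample_enm_trajectory(s, n_frames = 400, amplitude = 1, ar1 = NULL, seed = 3)
  rs <- rmsd_series(tr)$rmsd
  target <- sqrt(2 * mean(attr(tr, "generating_msf")$msf))
  expect_equal(mean(rs[-1]), target, tolerance = 0.2)
})

test_that("RMSF of a sampled trajectory recovers the generating profile", {
  s <- two_domain_fixture()$open
  for (src in c("anm", "gnm")) {
    tr <- sample_enm_trajectory(s, n_frames = 1000, amplitude = 1, ar1 = NULL,
                                source = src, seed = 4)
    r <- cor(rmsf_profile(tr)$rmsf^2, attr(tr, "generating_msf")$msf)
    expect_gt(r, 0.8)
  }
})

test_that("projected per-mode variances match equipartition at long times", {
  co <- packed_cluster(40, radius = 10, seed = 12)
  s <- ca_structure(1:40, rep("ALA", 40), co)
  a <- anm(s)
  tr <- sample_enm_trajectory(s, n_frames = 5000, amplitude = 1, ar1 = NULL,
                              rms_cap = 1e9, n_modes = 30, seed = 13)
  co0 <- ca_coords(s)
  dev <- t(vapply(seq_len(5000), function(t) {
    as.numeric(t(matrix(tr$coords[t, , ], ncol = 3))) - as.numeric(t(co0))
  }, numeric(120)))
  for (k in c(2, 10, 25)) {
    v <- a$vectors[, a$n_zero + k]
    expect_equal(stats::var(as.numeric(dev %*% v)),
                 1 / a$values[a$n_zero + k], tolerance = 0.15)
  }
})

test_that("NRI features carry positions and consistent velocities", {
  # uniform linear motion: constant velocity features
  co <- array(0, c(10, 3, 3))
  for (t in 1:10) co[t, , ] <- matrix(1:9, 3) + (t - 1) * 0.5
  f <- featurize_nri(trajectory(co))
  raw <- unstandardize_features(f)
  expect_equal(max(abs(raw[2:9, , 4:6] - 0.5)), 0, tolerance = 1e-10)
  # standardization round trip
  expect_equal(raw[, , 1:3], co, tolerance = 1e-10)
})

test_that("finite-difference velocities agree with simulator velocities", {
  sim <- simulate_springs(n = 4, steps = 8000, seed = 5)
  tr <- sim$trajectory
  no_vel <- trajectory(tr$coords, dt = tr$dt)
  f_fd <- featurize_nri(no_vel)
  raw_fd <- unstandardize_features(f_fd)
  true_v <- tr$velocities
  # interior frames, central differences: first-order agreement
  Tn <- dim(tr$coords)[1]
  err <- max(abs(raw_fd[2:(Tn - 1), , 4:6] - true_v[2:(Tn - 1), , ]))
  # bound: dt * max acceleration (per recorded-frame units)
  acc <- abs(diff(true_v[, 1, 1]))
  expect_lt(err, max(abs(diff(matrix(true_v, Tn)))) + 1e-6)
  expect_lt(err, 0.1 * max(abs(true_v)))
})

test_that("XYZ files round trip", {
  set.seed(8)
  tr <- trajectory(array(rnorm(5 * 4 * 3), c(5, 4, 3)))
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  tr2 <- read_xyz(f)
  expect_equal(tr2$coords, tr$coords, tolerance = 1e-6)
})
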