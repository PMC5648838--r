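rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(1)
  x <- matrix(rnorm(21), ncol = 3)
  tr <- kabschSuperpose(x, x)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-9)
  expect_equal(tr$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(tr$rmsd, 0, tolerance = 1e-9)

  y <- x %*% t(rot_z(90)) + matrix(c(5, 0, 0), nrow(x), 3, byrow = TRUE)
  tr2 <- kabschSuperpose(x, y)
  expect_lt(tr2$rmsd, 1e-9)
  expect_equal(det(tr2$rotation), 1, tolerance = 1e-6)
  # apply-then-invert is identity
  back <- applyTransform(applyTransform(x, tr2),
                         list(rotation = t(tr2$rotation),
                              translation = -as.vector(t(tr2$rotation) %*%
                                                         tr2$translation)))
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("Kabsch is a proper rotation, never a reflection", {
  set.seed(7)
  x <- matrix(rnorm(15), ncol = 3)
  y <- x %*% diag(c(-1, 1, 1))  # mirrored target
  tr <- kabschSuperpose(x, y)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-6)
  expect_gt(tr$rmsd, 0.1)  # mirror image cannot be reached by rotation
})

test_that("Kabsch degenerate inputs raise geometry errors", {
  expect_error(kabschSuperpose(matrix(rnorm(6), 2, 3),
                               matrix(rnorm(6), 2, 3)), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperpose(line, line + 1), "degenerate")
})

test_that("Kabsch RMSD matches the dense rotation-grid oracle", {
  for (seed in c(11, 23, 31)) {
    set.seed(seed)
    x <- matrix(rnorm(18), ncol = 3)
    y <- matrix(rnorm(18), ncol = 3)
    fit <- kabschSuperpose(x, y)$rmsd
    grid <- oracle_grid_rmsd(x, y)
    expect_gte(grid, fit - 1e-9)  # grid can never beat the optimum
    expect_lt(abs(grid - fit), 1e-3)
  }
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  set.seed(5)
  x <- matrix(rnorm(30), ncol = 3)
  y <- x %*% t(rot_z(40)) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE) +
    matrix(rnorm(30, sd = 0.3), ncol = 3)
  ours <- kabschSuperpose(x, y)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(y)), as.vector(t(x)), fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-3)
})

test_that("trajectory alignment collapses pure tumbling and is idempotent", {
  base <- random_frames_traj(1, seed = 2)
  xyz0 <- frameCoords(base, 0)
  nf <- 6
  coords <- array(0, dim = c(nrow(xyz0), 3, nf))
  set.seed(99)
  for (f in 1:nf) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- diag(3)
    R <- matrix(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
                  2 * (q[2] * q[4] + q[1] * q[3]),
                  2 * (q[2] * q[3] + q[1] * q[4]),
                  1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
                  2 * (q[2] * q[4] - q[1] * q[3]),
                  2 * (q[3] * q[4] + q[1] * q[2]),
                  1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    coords[, , f] <- xyz0 %*% t(R) +
      matrix(runif(3, -8, 8), nrow(xyz0), 3, byrow = TRUE)
  }
  tumbling <- makeTrajectory(topology(base), coords)
  sel <- resolveSelection(topology(base), "calpha")
  aligned <- alignTrajectory(tumbling, "calpha")
  for (f in 1:(nf - 1))
    expect_lt(max(abs(frameCoords(aligned, f) - frameCoords(aligned, 0))),
              1e-6)
  # idempotence
  again <- alignTrajectory(aligned, "calpha")
  expect_lt(max(abs(again@coords - aligned@coords)), 1e-6)
  # per-frame fit-selection RMSD never increases through alignment
  before <- computeRmsd(tumbling, sel, prefit = FALSE)
  after <- computeRmsd(aligned, sel, prefit = FALSE)
  expect_true(all(after <= before + 1e-9))
})

test_that("RMSD: closed forms and direct-formula oracle", {
  traj <- random_frames_traj(4, seed = 8)
  sel <- atoms(traj)$serial[1:10]
  # static trajectory -> all zeros
  static <- makeTrajectory(topology(traj),
                           array(rep(frameCoords(traj, 0), 3),
                                 dim = c(nAtoms(traj), 3, 3)))
  expect_equal(computeRmsd(static, sel, prefit = FALSE), c(0, 0, 0))
  # single displaced atom, closed form
  coords <- array(rep(frameCoords(traj, 0), 2),
                  dim = c(nAtoms(traj), 3, 2))
  coords[3, 1, 2] <- coords[3, 1, 2] + 2.0
  one <- makeTrajectory(topology(traj), coords)
  expect_equal(computeRmsd(one, atoms(traj)$serial[3], prefit = FALSE),
               c(0, 2.0))
  # random trajectory vs naive oracle
  expect_equal(computeRmsd(traj, sel, prefit = FALSE),
               oracle_rmsd(traj, sel), tolerance = 1e-9)
  expect_error(computeRmsd(traj, integer(0)), "empty")
})

test_that("RMSF: closed forms, oracle, and rigid-motion invariance", {
  traj <- random_frames_traj(5, seed = 13)
  sel <- atoms(traj)$serial[1:8]
  static <- makeTrajectory(topology(traj),
                           array(rep(frameCoords(traj, 0), 4),
                                 dim = c(nAtoms(traj), 3, 4)))
  expect_equal(computeRmsf(static, sel, prefit = FALSE)$rmsf, rep(0, 8))
  # alternating +1/-1 in x -> RMSF exactly 1
  coords <- array(rep(frameCoords(traj, 0), 4),
                  dim = c(nAtoms(traj), 3, 4))
  coords[5, 1, ] <- coords[5, 1, ] + c(1, -1, 1, -1)
  alt <- makeTrajectory(topology(traj), coords)
  expect_equal(computeRmsf(alt, atoms(traj)$serial[5],
                           prefit = FALSE)$rmsf, 1.0)
  expect_equal(computeRmsf(traj, sel, prefit = FALSE)$rmsf,
               oracle_rmsf(traj, sel), tolerance = 1e-9, ignore_attr = TRUE)
  # uniform rigid motion of all frames leaves prefit RMSF unchanged
  R <- rot_z(33)
  moved <- traj
  for (f in 1:5)
    moved@coords[, , f] <- traj@coords[, , f] %*% t(R) +
      matrix(c(4, -7, 2), nAtoms(traj), 3, byrow = TRUE)
  expect_equal(computeRmsf(moved, sel, prefit = TRUE)$rmsf,
               computeRmsf(traj, sel, prefit = TRUE)$rmsf,
               tolerance = 1e-6)
  expect_error(computeRmsf(random_frames_traj(1), sel), "single frame")
  # per-residue reduction averages within residues
  byres <- computeRmsf(traj, "calpha", prefit = FALSE, by_residue = TRUE)
  expect_true(all(c("resnum", "rmsf") %in% names(byres)))
})

test_that("pocket volume: analytic sphere, occlusion, fine-grid oracle", {
  f <- tempfile(fileext = ".pdb")
  generateVolumePhantom(f)
  tr <- readTrajectory(readTopology(f), f)
  v_empty <- pocketVolume(tr, 1, radius = 10, spacing = 0.5)
  expect_lt(abs(v_empty - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)

  # single occluder at center vs fine-grid oracle
  generateVolumePhantom(f, data.frame(x = 0.3, y = -0.2, z = 0.1))
  tr1 <- readTrajectory(readTopology(f), f)
  v1 <- pocketVolume(tr1, 1, radius = 6, spacing = 0.5)
  vo <- oracle_volume(c(0, 0, 0), 6, 0.1,
                      matrix(c(0.3, -0.2, 0.1), 1, 3), 1.7)
  expect_lt(abs(v1 - vo) / vo, 0.03)

  # volume is monotone non-increasing as occluders are added
  occs <- data.frame(x = c(2, -3, 0), y = c(1, 2, -4), z = c(0, 1, 2))
  prev <- v_empty
  for (k in 1:3) {
    generateVolumePhantom(f, occs[1:k, , drop = FALSE])
    trk <- readTrajectory(readTopology(f), f)
    vk <- pocketVolume(trk, 1, radius = 10, spacing = 0.5)
    expect_lte(vk, prev + 1e-9)
    prev <- vk
  }

  # missing center atom
  expect_error(pocketVolume(tr, 999), "center atom")
  expect_error(pocketVolume(tr, 1, spacing = 5), "spacing")
})
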