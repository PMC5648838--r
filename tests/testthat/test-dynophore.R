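sched_dyn <- function(n, schedules, ligand = "amino", seed = 1, ...) {
  spec <- toySpec(n, ligand = ligand, schedules = schedules, seed = seed, ...)
  toy <- generateToyTrajectory(spec)
  list(dyn = buildDynophore(toy$trajectory), toy = toy)
}

test_that("scheduled occurrences aggregate into one superfeature", {
  r <- sched_dyn(50, list(schedule("HBD", "hydroxyl", "bbO", 0:17)))
  sfs <- superfeatures(r$dyn)
  expect_length(sfs, 1)
  sf <- sfs[[1]]
  expect_equal(sf@type, "HBD")
  expect_equal(length(sf@frames), 18)
  expect_equal(superfeatureFrequency(sf), 36)
  expect_equal(sf@frames, 0:17)
})

test_that("a ligand out of reach yields a zero-superfeature dynophore", {
  spec <- toySpec(4, schedules = list())
  toy <- generateToyTrajectory(spec)
  expect_warning(dyn <- buildDynophore(toy$trajectory), "no interactions")
  expect_length(superfeatures(dyn), 0)
  expect_equal(nFrames(dyn), 4)
})

test_that("same donor, two partners: one superfeature, two profiles", {
  n <- 40
  r <- sched_dyn(n, list(
    schedule("HBD", "hydroxyl", "bbO", seq(0, n - 1, 2)),
    schedule("HBD", "hydroxyl", "bbO2", seq(1, n - 1, 2))))
  sfs <- superfeatures(r$dyn)
  expect_length(sfs, 1)
  sf <- sfs[[1]]
  expect_equal(superfeatureFrequency(sf), 100)
  pf <- partnerFrequency(sf)
  expect_setequal(names(pf), c("GLY/1/A", "GLY/2/A"))
  expect_equal(unname(pf["GLY/1/A"]), 50)
  expect_equal(unname(pf["GLY/2/A"]), 50)
})

test_that("simultaneous partners can each reach 100 percent", {
  r <- sched_dyn(12, list(
    schedule("NI", "boronate", "MN1", 0:11),
    schedule("NI", "boronate", "MN2", 0:11)), ligand = "boronate")
  sf <- superfeatures(r$dyn)[[1]]
  pf <- partnerFrequency(sf)
  expect_equal(sum(pf), 200)
  expect_equal(unname(pf), c(100, 100))
})

test_that("frequency definitions: boundary values and undefined cases", {
  r <- sched_dyn(10, list(schedule("HBD", "hydroxyl", "bbO", 0:9)))
  sf <- superfeatures(r$dyn)[[1]]
  expect_equal(superfeatureFrequency(sf), 100)
  wide <- sf
  wide@frames <- 0:451          # 452 occurrences out of 1000 frames
  wide@nFrames <- 1000L
  wide@events <- sf@events[0, ]
  expect_equal(superfeatureFrequency(wide), 45.2)
  expect_equal(superfeatureFrequency(wide, n_frames = 452), 100)
  empty <- sf
  empty@events <- sf@events[0, ]
  empty@frames <- integer(0)
  expect_warning(v <- partnerFrequency(empty), "undefined")
  expect_true(is.nan(v))
  expect_error(superfeatureFrequency(sf, 0), "n_frames")
})

test_that("distance histograms conserve counts and match naive binning", {
  set.seed(31)
  r <- sched_dyn(60, list(schedule("HBD", "hydroxyl", "bbO", 0:44)),
                 jitter_sigma = 0.1, seed = 9)
  sf <- superfeatures(r$dyn)[[1]]
  h <- distanceHistogram(sf)
  expect_equal(sum(h$counts), nrow(sf@events))
  expect_equal(h$counts, oracle_bins(sf@events$distance, h$breaks))
  # identical distances concentrate in a single bin
  r0 <- sched_dyn(10, list(schedule("HBD", "hydroxyl", "bbO", 0:9)))
  h0 <- distanceHistogram(superfeatures(r0$dyn)[[1]])
  expect_equal(sum(h0$counts > 0), 1)
  expect_equal(max(h0$counts), 10)
  empty <- superfeatures(r0$dyn)[[1]]
  empty@events <- empty@events[0, ]
  expect_error(distanceHistogram(empty), "no events")
})

test_that("bar codes: counts, partner OR, and known schedule", {
  n <- 6
  r <- sched_dyn(n, list(schedule("HBD", "hydroxyl", "bbO", c(1, 3, 5))))
  sf <- superfeatures(r$dyn)[[1]]
  expect_equal(occurrenceBarcode(sf),
               c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  r2 <- sched_dyn(20, list(
    schedule("HBD", "hydroxyl", "bbO", seq(0, 19, 2)),
    schedule("HBD", "hydroxyl", "bbO2", c(1, 5, 9))))
  sf2 <- superfeatures(r2$dyn)[[1]]
  expect_equal(sum(occurrenceBarcode(sf2)), length(sf2@frames))
  ored <- occurrenceBarcode(sf2, "GLY/1/A") | occurrenceBarcode(sf2, "GLY/2/A")
  expect_equal(occurrenceBarcode(sf2), ored)
  # conservation: union of partner frame sets = superfeature frames
  u <- sort(unique(sf2@events$frame))
  expect_equal(u, sf2@frames)
})

test_that("point clouds have one point per occurrence and a stable centroid", {
  r <- sched_dyn(30, list(schedule("HBD", "hydroxyl", "bbO", 0:11)),
                 jitter_sigma = 0.08, seed = 4)
  sf <- superfeatures(r$dyn)[[1]]
  pc <- pointCloud(sf)
  expect_equal(nrow(pc), length(sf@frames))
  # oracle: recompute centroids from the aligned trajectory
  spec <- toySpec(30, schedules = list(schedule("HBD", "hydroxyl", "bbO",
                                                0:11)),
                  jitter_sigma = 0.08, seed = 4)
  toy <- generateToyTrajectory(spec)
  aligned <- alignTrajectory(toy$trajectory, "calpha")
  a <- atoms(aligned)
  og <- a$serial[a$name == "OG" & a$resname == "LIG"]
  for (k in seq_len(nrow(pc))) {
    xyz <- frameCoords(aligned, pc$frame[k])[match(og, a$serial), ]
    expect_equal(unlist(pc[k, c("x", "y", "z")]), xyz,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("concatenated trajectories give additive occurrence counts", {
  s1 <- toySpec(20, schedules = list(schedule("HBD", "hydroxyl", "bbO", 0:6)),
                seed = 2)
  s2 <- toySpec(30, schedules = list(schedule("HBD", "hydroxyl", "bbO", 0:10)),
                seed = 3)
  t1 <- generateToyTrajectory(s1)$trajectory
  t2 <- generateToyTrajectory(s2)$trajectory
  d1 <- buildDynophore(t1)
  d2 <- buildDynophore(t2)
  dc <- buildDynophore(concatTrajectories(t1, t2))
  sf <- superfeatures(dc)[[1]]
  expect_equal(length(sf@frames),
               length(superfeatures(d1)[[1]]@frames) +
                 length(superfeatures(d2)[[1]]@frames))
  expect_equal(nFrames(dc), 50)
})

test_that("loosening criteria never lowers a superfeature frequency", {
  traj <- random_frames_traj(10, seed = 77)
  tight <- defaultCriteria()
  loose <- tight
  loose@hbondDistMax <- 4.3
  loose@ionicDistMax <- 6.5
  loose@hydrophobDistMax <- 5.2
  loose@metalCoordMax <- 3.6
  loose@hbondAngleMin <- 110
  dt <- suppressWarnings(buildDynophore(traj, criteria = tight,
                                        align = FALSE))
  dl <- suppressWarnings(buildDynophore(traj, criteria = loose,
                                        align = FALSE))
  freq_l <- vapply(superfeatures(dl), superfeatureFrequency, numeric(1))
  for (lab in names(superfeatures(dt))) {
    ft <- superfeatureFrequency(superfeatures(dt)[[lab]])
    expect_gte(freq_l[[lab]], ft)
  }
})

test_that("report export round-trips frequencies bit-exactly", {
  r <- sched_dyn(25, list(
    schedule("HBD", "hydroxyl", "bbO", c(0:7, 12, 19)),
    schedule("NI", "carboxylate", "argGua", 3:20)), jitter_sigma = 0.05,
    seed = 6)
  out <- tempfile()
  exportReport(r$dyn, out)
  expect_true(file.exists(file.path(out, "dynophore.json")))
  expect_true(file.exists(file.path(out, "superfeatures.csv")))
  expect_true(file.exists(file.path(out, "barcodes.csv")))
  rep <- readReport(file.path(out, "dynophore.json"))
  expect_equal(rep$n_frames, 25)
  for (s in rep$superfeatures) {
    sf <- superfeatures(r$dyn)[[s$label]]
    expect_equal(s$frequency, superfeatureFrequency(sf), tolerance = 0)
    for (p in s$partners)
      expect_equal(p$frequency, partnerFrequency(sf, p$key), tolerance = 0)
    # frequencies recompute from the exported bar codes
    bc <- utils::read.csv(file.path(out, "barcodes.csv"),
                          check.names = FALSE)
    expect_equal(100 * sum(bc[[s$label]]) / nrow(bc), s$frequency)
  }
  # cloud PDBs exist and have one pseudo-atom per occurrence frame
  sf1 <- superfeatures(r$dyn)[[1]]
  cloud_file <- file.path(out, paste0("cloud_",
                                      gsub("[^A-Za-z0-9.-]+", "_",
                                           sf1@label), ".pdb"))
  expect_true(file.exists(cloud_file))
  ctop <- readTopology(cloud_file)
  expect_equal(nAtoms(ctop), length(sf1@frames))
  # zero-superfeature dynophore still exports valid JSON
  spec0 <- toySpec(3, schedules = list())
  dyn0 <- suppressWarnings(
    buildDynophore(generateToyTrajectory(spec0)$trajectory))
  out0 <- tempfile()
  exportReport(dyn0, out0)
  rep0 <- readReport(file.path(out0, "dynophore.json"))
  expect_length(rep0$superfeatures, 0)
})

test_that("plot helpers run headless", {
  r <- sched_dyn(12, list(schedule("HBD", "hydroxyl", "bbO", 0:5)))
  sf <- superfeatures(r$dyn)[[1]]
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  m <- plotBarcode(sf)
  plot(distanceHistogram(sf))
  grDevices::dev.off()
  expect_equal(dim(m), c(2L, 12L))
  expect_true(file.size(f) > 0)
})
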