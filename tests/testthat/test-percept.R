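toy_top <- function(ligand = "amino") {
  spec <- toySpec(1, ligand = ligand, schedules = list())
  generateToyTrajectory(spec, verify = FALSE)$topology
}

test_that("boronate probe typing: 3 donors, one group acceptor, one NI", {
  top <- toy_top("boronate")
  tm <- perceiveFeatures(top, "ligand")
  types <- vapply(tm, function(t) t@type, character(1))
  expect_equal(sum(types == "HBD"), 3)
  expect_equal(sum(types == "HBA"), 1)
  expect_equal(sum(types == "NI"), 1)
  expect_equal(length(tm), 5)
  a <- atoms(top)
  hba <- tm[[which(types == "HBA")]]
  expect_equal(a$name[match(hba@atoms, a$serial)], "B")
  ni <- tm[[which(types == "NI")]]
  expect_setequal(a$name[match(ni@atoms, a$serial)],
                  c("B", "O1", "O2", "O3"))
})

test_that("amino probe typing: carboxylate NI, amine PI + HBD, tail H", {
  top <- toy_top("amino")
  tm <- perceiveFeatures(top, "ligand")
  a <- atoms(top)
  types <- vapply(tm, function(t) t@type, character(1))
  ni <- tm[types == "NI"]
  expect_length(ni, 1)
  expect_setequal(a$name[match(ni[[1]]@atoms, a$serial)], c("O1", "O2"))
  pi_t <- tm[types == "PI"]
  expect_length(pi_t, 1)
  expect_equal(a$name[match(pi_t[[1]]@atoms, a$serial)], "N")
  hbd_atoms <- lapply(tm[types == "HBD"], function(t)
    a$name[match(t@atoms, a$serial)])
  expect_true(any(vapply(hbd_atoms, identical, logical(1), "N")))
  h_t <- tm[types == "H"]
  expect_length(h_t, 1)
  expect_setequal(a$name[match(h_t[[1]]@atoms, a$serial)],
                  c("CB", "CG", "CD"))
})

test_that("a bare short alkane yields no features", {
  # methane-like: one carbon, four hydrogens
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  C1  UNL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  H1  UNL A   1       0.630   0.630   0.630  1.00  0.00           H",
    "HETATM    3  H2  UNL A   1      -0.630  -0.630   0.630  1.00  0.00           H",
    "HETATM    4  H3  UNL A   1      -0.630   0.630  -0.630  1.00  0.00           H",
    "HETATM    5  H4  UNL A   1       0.630  -0.630  -0.630  1.00  0.00           H",
    "END"), f)
  top <- readTopology(f)
  expect_length(perceiveFeatures(top, "ligand"), 0)
  expect_error(perceiveFeatures(top, "resname XYZ") |> suppressWarnings(),
               "empty")
})

test_that("environment classification covers metals, hydroxide, water", {
  top <- toy_top()
  env <- classifyEnvironment(top, "ligand")
  expect_equal(env$pclass[env$resname == "MN"], c("metal", "metal"))
  expect_equal(env$pclass[env$resname == "OH"], "hydroxide")
  expect_true(all(env$pclass[env$resname %in%
                               c("GLY", "SER", "ASP", "ARG", "THR")] ==
                    "protein"))
  expect_false(any(env$resname == "LIG"))  # ligand excluded
  # identity keys are residue-based
  expect_true(all(grepl("^[A-Z]+/[0-9]+/A$", env$key)))
})

test_that("H-bond window and angle gate single events correctly", {
  # donor O-H pointed at an acceptor carbonyl at controlled geometry
  mk <- function(d, hx) {
    f <- tempfile(fileext = ".pdb")
    writeLines(c(
      "ATOM      1  CA  GLY A   1       0.000  -4.000   4.000  1.00  0.00           C",
      "ATOM      2  CA  GLY A   2       4.000  -4.000   0.000  1.00  0.00           C",
      "ATOM      3  CA  GLY A   3      -4.000  -4.000   0.000  1.00  0.00           C",
      "ATOM      4  C   GLY A   1       0.000  -1.300   0.000  1.00  0.00           C",
      sprintf("ATOM      5  O   GLY A   1       0.000   0.000   0.000  1.00  0.00           O"),
      sprintf("HETATM    6  O1  UNL A   9       0.000   %.3f   0.000  1.00  0.00           O", d),
      sprintf("HETATM    7  H1  UNL A   9       %.3f   %.3f   0.000  1.00  0.00           H",
              hx, d - 0.95),
      "CONECT    4    5",
      "CONECT    1    4",
      "CONECT    6    7",
      "END"), f)
    top <- readTopology(f)
    traj <- readTrajectory(top, f)
    tm <- perceiveFeatures(top, "ligand")
    env <- classifyEnvironment(top, "ligand")
    detectFrameInteractions(traj, 0, tm, env)
  }
  ev <- mk(2.9, 0)            # 2.9 A, angle 180
  expect_equal(sum(ev$type == "HBD"), 1)
  expect_equal(ev$distance[ev$type == "HBD"], 2.9, tolerance = 1e-6)
  ev_far <- mk(4.2, 0)        # beyond hbond_dist_max
  expect_equal(sum(ev_far$type == "HBD"), 0)
  ev_bent <- mk(2.9, 1.8)     # H pushed sideways: angle below the gate
  expect_equal(sum(ev_bent$type == "HBD"), 0)
})

test_that("detection equals the all-pairs oracle on seeded random frames", {
  crit <- defaultCriteria()
  for (ligand in c("amino", "boronate")) {
    traj <- random_frames_traj(12, seed = if (ligand == "amino") 101 else 202,
                               ligand = ligand)
    top <- topology(traj)
    tm <- perceiveFeatures(top, "ligand")
    env <- classifyEnvironment(top, "ligand")
    n_events <- 0
    for (f in seq_len(nFrames(traj)) - 1L) {
      cell <- detectFrameInteractions(traj, f, tm, env, crit,
                                      method = "cell")
      brute <- detectFrameInteractions(traj, f, tm, env, crit,
                                       method = "brute")
      expect_identical(event_multiset(cell), event_multiset(brute))
      xyz <- frameCoords(traj, f)
      expect_identical(event_multiset(cell),
                       oracle_events(top, xyz, tm, env, crit))
      n_events <- n_events + nrow(cell)
    }
    expect_gt(n_events, 0)  # random frames must actually exercise events
  }
})

test_that("detection is invariant under a global rigid transform", {
  traj <- random_frames_traj(3, seed = 55)
  top <- topology(traj)
  tm <- perceiveFeatures(top, "ligand")
  env <- classifyEnvironment(top, "ligand")
  ev0 <- detectFrameInteractions(traj, 1, tm, env)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- traj
  moved@coords[, , 2] <- traj@coords[, , 2] %*% t(R) +
    matrix(c(3, -1, 7), nAtoms(traj), 3, byrow = TRUE)
  ev1 <- detectFrameInteractions(moved, 1, tm, env)
  expect_equal(ev0$distance, ev1$distance, tolerance = 1e-6)
  expect_identical(ev0[, c("label", "partner")], ev1[, c("label", "partner")])
})

test_that("criteria files round-trip and reject unknown keys", {
  crit <- defaultCriteria()
  f <- tempfile()
  writeCriteria(crit, f)
  back <- readCriteria(f)
  expect_equal(back@hbondDistMax, crit@hbondDistMax)
  writeLines(c("hbond_dist_max = 4.2", "# comment"), f)
  expect_equal(readCriteria(f)@hbondDistMax, 4.2)
  writeLines("nonsense = 1", f)
  expect_error(readCriteria(f), "unknown key")
  writeLines("hbond_dist_max = abc", f)
  expect_error(readCriteria(f), "non-numeric")
  bad <- defaultCriteria()
  expect_error({bad@hbondDistMin <- 9; validObject(bad)}, "hbondDistMin")
})

test_that("feature taxonomy carries the canonical colors", {
  ft <- featureTypes()
  expect_equal(ft$color[ft$type == "HBA"], "red")
  expect_equal(ft$color[ft$type == "NI"], "orange")
  expect_equal(ft$color[ft$type == "HBD"], "green")
  expect_equal(ft$color[ft$type == "PI"], "blue")
  expect_equal(ft$color[ft$type == "H"], "yellow")
})
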