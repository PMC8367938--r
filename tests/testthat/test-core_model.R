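test_that("united atoms partition a molecule with the hydrogen-count DOF rule", {
  top <- make_water_topology()
  uas <- define_united_atoms(top, "SOL.1")
  expect_length(uas, 1L)
  expect_equal(uas[[1]]$rotational_dof, 3L)      # two hydrogens: non-linear
  expect_setequal(uas[[1]]$atoms, 1:3)

  top <- make_methanol_topology()
  uas <- define_united_atoms(top, "MOL.1")
  expect_length(uas, 2L)
  dofs <- vapply(uas, function(u) u$rotational_dof, 0L)
  expect_equal(dofs, c(3L, 2L))                  # CH3 then OH
  # partition covers every atom exactly once
  all_atoms <- sort(unlist(lapply(uas, `[[`, "atoms")))
  expect_equal(all_atoms, 1:6)

  # carbonyl-like oxygen mimic: heavy atom with no hydrogens is a point
  atoms <- data.frame(id = 1:3, name = c("C1", "O1", "O2"),
                      element = c("C", "O", "O"),
                      mass = c(12.011, 15.999, 15.999), mol = "CO2.1")
  top <- mcc_topology(atoms, rbind(c(1, 2), c(1, 3)),
                      data.frame(name = "CO2.1", role = "other", symmetry = 2))
  uas <- define_united_atoms(top, "CO2.1")
  expect_equal(vapply(uas, function(u) u$rotational_dof, 0L), c(0L, 0L, 0L))
})

test_that("ill-formed hydrogen bonding is rejected", {
  atoms <- data.frame(id = 1:3, name = c("C1", "O1", "H1"),
                      element = c("C", "O", "H"),
                      mass = c(12.011, 15.999, 1.008), mol = "X.1")
  # bridging hydrogen bonded to two heavy atoms
  top <- mcc_topology(atoms, rbind(c(1, 3), c(2, 3)),
                      data.frame(name = "X.1", role = "other", symmetry = 1))
  expect_error(define_united_atoms(top, "X.1"), "multiple heavy")
  # free hydrogen
  top <- mcc_topology(atoms, rbind(c(1, 2)),
                      data.frame(name = "X.1", role = "other", symmetry = 1))
  expect_error(define_united_atoms(top, "X.1"), "free hydrogen")
})

test_that("topology invariants are enforced", {
  atoms <- data.frame(id = 1:2, name = c("C1", "C2"),
                      element = c("C", "C"), mass = c(12, 12),
                      mol = c("A.1", "B.1"))
  mols <- data.frame(name = c("A.1", "B.1"), role = "other", symmetry = 1)
  expect_error(mcc_topology(atoms, rbind(c(1, 2)), mols), "within one molecule")
  atoms_bad <- atoms; atoms_bad$mass[1] <- 0
  expect_error(mcc_topology(atoms_bad, matrix(integer(), ncol = 2), mols),
               "positive")
  mols_bad <- mols; mols_bad$symmetry[1] <- 0.5
  expect_error(mcc_topology(atoms, matrix(integer(), ncol = 2), mols_bad),
               "symmetry")
})

test_that("principal frame: centre of mass, diagonalisation, invariance", {
  coords <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0))
  pf <- principal_frame(coords, rep(1, 3))
  expect_equal(pf$origin, c(0, 1 / 3, 0))

  # random cloud: inertia tensor is diagonal in the returned axes
  set.seed(42)
  coords <- matrix(rnorm(30), 10, 3)
  masses <- runif(10, 1, 16)
  pf <- principal_frame(coords, masses)
  rel <- sweep(coords, 2, pf$origin)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(rel^2)
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- sum(masses * ((a == b) * r2 - rel[, a] * rel[, b]))
  D <- pf$axes %*% I %*% t(pf$axes)
  expect_lt(max(abs(D - diag(diag(D)))), 1e-10 * sum(diag(I)))
  expect_equal(diag(D), pf$moments, tolerance = 1e-10)
  # right-handed
  expect_equal(det(pf$axes), 1, tolerance = 1e-10)

  # moments invariant under rigid rotation + translation
  for (s in 1:5) {
    set.seed(s)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    shifted <- coords %*% Q + matrix(rnorm(3), 10, 3, byrow = TRUE)
    pf2 <- principal_frame(shifted, masses)
    expect_equal(pf2$moments, pf$moments, tolerance = 1e-10)
  }

  expect_error(principal_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                               rep(1, 3)), "collinear|linear")
})

test_that("trajectory round-trips through the text format", {
  set.seed(7)
  coords <- array(rnorm(2 * 3 * 3 * 10), c(10, 3, 3))
  forces <- array(rnorm(2 * 3 * 3 * 10, 0, 100), c(10, 3, 3))
  traj <- mcc_trajectory(coords, forces, times = (0:9) * 100,
                         box = matrix(rep(36, 3), 1))
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
  expect_equal(back$forces, traj$forces, tolerance = 1e-9)
  expect_equal(back$times, traj$times)
  expect_equal(back$box, traj$box)
  # stride
  strided <- read_trajectory(path, stride = 2L)
  expect_equal(n_frames(strided), 5L)
  expect_equal(strided$times, traj$times[c(1, 3, 5, 7, 9)])
})

test_that("a trajectory without force records is refused", {
  path <- withr::local_tempfile(fileext = ".trj")
  writeLines(c("frame 0", "box 30 30 30",
               "0 0 0", "1 0 0", "0 1 0"), path)
  expect_error(read_trajectory(path), "forces required")
  expect_error(mcc_trajectory(array(0, c(2, 3, 3)), NULL), "forces required")
})

test_that("GRO reading converts nm to Angstrom and groups residues", {
  top0 <- make_water_topology()
  geom <- water_geometry()
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro_fixture(path, top0$atoms, geom)
  g <- read_gro(path)
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(g$atoms$element, c("O", "H", "H"))
  expect_equal(g$coords, unname(geom), tolerance = 1e-2)  # %.3f nm = 0.01 A
  expect_equal(g$box, c(30, 30, 30))
  rt <- read_topology(path)
  expect_equal(rt$topology$molecules$role, "water")
  expect_equal(rt$topology$molecules$symmetry, 2)
  expect_equal(nrow(rt$topology$bonds), 2L)  # two O-H bonds inferred
})

test_that("load_system validates atom counts and applies stride", {
  top <- make_water_topology()
  traj <- mcc_trajectory(array(0, c(3, 4, 3)), array(0, c(3, 4, 3)))
  expect_error(load_system(top, traj), "3.*4|mismatch")
})

test_that("synthetic trajectories reload identically from disk", {
  h <- harmonic_trajectory(harmonic_spec(n_frames = 20, seed = 5))
  path <- withr::local_tempfile(fileext = ".trj")
  write_trajectory(h$system$trajectory, path)
  back <- read_trajectory(path)
  expect_equal(back$coords, h$system$trajectory$coords, tolerance = 1e-9)
  expect_equal(back$forces, h$system$trajectory$forces, tolerance = 1e-9)
})

test_that("minimum image and per-molecule unwrapping", {
  box <- c(10, 10, 10)
  expect_equal(minimum_image(c(9, 0, -9), box), c(-1, 0, 1))
  split_mol <- rbind(c(9.8, 5, 5), c(0.3, 5, 5), c(9.3, 5, 5))
  un <- unwrap_coords(split_mol, box)
  expect_equal(un[2, 1], 10.3)
  expect_equal(un[3, 1], 9.3)
})
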