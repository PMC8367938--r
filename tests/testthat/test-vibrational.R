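test_that("constant forces and torques give zero covariance", {
  top <- make_methanol_topology()
  f <- matrix(5, 6, 3)
  sys <- make_system(top, methanol_geometry(), list(f, f, f))
  cv <- weighted_force_covariance(sys, "MOL.1", "molecule")
  expect_equal(max(abs(cv$matrix)), 0)
  cvt <- weighted_torque_covariance(sys, "MOL.1", "molecule")
  expect_lt(max(abs(cvt$matrix)), 1e-16 * .Machine$double.xmax)
  expect_error(frequencies_from_eigenvalues(cv), "degenerate")
})

test_that("a single frame cannot form a covariance", {
  top <- make_methanol_topology()
  sys <- make_system(top, methanol_geometry(), list(matrix(1, 6, 3)))
  expect_error(weighted_force_covariance(sys, "MOL.1"), "2 frames")
  expect_error(weighted_torque_covariance(sys, "MOL.1"), "2 frames")
})

test_that("harmonic Boltzmann sampling reproduces the analytic covariance", {
  spec <- harmonic_spec(k_trans = c(100, 200, 300),
                        kappa_rot = c(80, 160, 240),
                        n_frames = 1e4, seed = 31)
  h <- harmonic_trajectory(spec)
  RT <- mcc_constants$R * spec$temperature           # J/mol
  M <- sum(spec$masses)
  # mean-field halving divides the variance by 4 on top of mass weighting
  cv <- weighted_force_covariance(h$system, "HRM.1", halving = "halved")
  expected <- spec$k_trans * 1e23 * RT / (4 * M * 1e-3)
  expect_equal(diag(cv$matrix), expected, tolerance = 0.05)
  expect_lt(max(abs(cv$matrix[upper.tri(cv$matrix)])) / max(expected), 0.05)

  # rigid-rotor libration: diagonal kappa*kB*T/(4 I) per principal axis
  moments <- principal_frame(
    h$system$trajectory$coords[1, , ], spec$masses)$moments
  cvt <- weighted_torque_covariance(h$system, "HRM.1", halving = "halved")
  expected_r <- spec$kappa_rot * 1e3 * RT / (4 * moments * 1e-23)
  expect_equal(diag(cvt$matrix), expected_r, tolerance = 0.05)
})

test_that("doubling masses at fixed forces halves the weighted covariance", {
  geom <- methanol_geometry()
  frames <- random_force_frames(100, 6, seed = 3)
  top1 <- make_methanol_topology()
  top2 <- make_methanol_topology()
  top2$atoms$mass <- top2$atoms$mass * 2
  s1 <- make_system(top1, geom, frames)
  s2 <- make_system(top2, geom, frames)
  c1 <- weighted_force_covariance(s1, "MOL.1", "molecule")
  c2 <- weighted_force_covariance(s2, "MOL.1", "molecule")
  expect_equal(c2$matrix, c1$matrix / 2, tolerance = 1e-12)
})

test_that("eigenvalue-to-frequency mapping inverts the QHO relation", {
  RT <- mcc_constants$R * 300
  sp <- frequencies_from_eigenvalues(diag(rep(RT * (2 * pi)^2, 3)), 300)
  expect_equal(sp$nu, rep(1, 3))                 # 1 Hz modes
  sp4 <- frequencies_from_eigenvalues(diag(rep(4 * RT * (2 * pi)^2, 3)), 300)
  expect_equal(sp4$nu, 2 * sp$nu)                # square-root law
  expect_error(frequencies_from_eigenvalues(matrix(c(1, 2, 3, 4), 2), 300),
               "symmetric")
})

test_that("QHO entropy: closed form, limits, additivity, monotonicity", {
  nu_star <- mcc_constants$R * 300 / mcc_constants$h_molar  # h nu = kB T
  expect_equal(qho_entropy(nu_star, 300), 8.6525, tolerance = 1e-4)
  expect_lt(qho_entropy(100 * nu_star, 300), 1e-30)         # frozen mode
  expect_equal(qho_entropy(rep(nu_star, 2), 300),
               2 * qho_entropy(nu_star, 300))
  expect_error(qho_entropy(-1, 300), "negative")
  expect_error(qho_entropy(numeric(0), 300), "empty")
  # decreasing in frequency, increasing in temperature
  nus <- nu_star * 10^seq(-2, 2, length.out = 20)
  S_nu <- vapply(nus, qho_entropy, 0, temperature = 300)
  expect_true(all(diff(S_nu) < 0))
  Ts <- seq(100, 600, by = 50)
  S_T <- vapply(Ts, function(T) qho_entropy(nu_star, T), 0)
  expect_true(all(diff(S_T) > 0))
})

test_that("end-to-end harmonic entropy recovery matches the analytic oracle", {
  spec <- harmonic_spec(n_frames = 1e4, seed = 11)
  h <- harmonic_trajectory(spec)
  S_t <- vibrational_entropy(h$system, "HRM.1", "molecule", "translation",
                             halving = "raw")
  S_r <- vibrational_entropy(h$system, "HRM.1", "molecule", "rotation",
                             halving = "raw")
  oracle <- analytic_entropy_oracle(spec)
  expect_equal(S_t + S_r, oracle$entropy, tolerance = 0.02)
})

test_that("halving convention shifts every frequency by exactly a factor 2", {
  h <- harmonic_trajectory(harmonic_spec(n_frames = 500, seed = 9))
  sys <- h$system
  sp_raw <- frequencies_from_eigenvalues(
    weighted_force_covariance(sys, "HRM.1", halving = "raw"), 300)
  sp_half <- frequencies_from_eigenvalues(
    weighted_force_covariance(sys, "HRM.1", halving = "halved"), 300)
  expect_equal(sp_half$nu, sp_raw$nu / 2, tolerance = 1e-12)
  # hence S(halved) equals the QHO sum evaluated at nu/2
  expect_equal(qho_entropy(sp_half, 300), qho_entropy(sp_raw$nu / 2, 300))
})

test_that("covariance eigenvalues are invariant under lab-frame rotation", {
  h <- harmonic_trajectory(harmonic_spec(n_frames = 300, seed = 17))
  sys <- h$system
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rot <- sys
  for (f in seq_len(n_frames(sys$trajectory))) {
    rot$trajectory$coords[f, , ] <- sys$trajectory$coords[f, , ] %*% t(Q)
    rot$trajectory$forces[f, , ] <- sys$trajectory$forces[f, , ] %*% t(Q)
  }
  for (maker in list(weighted_force_covariance, weighted_torque_covariance)) {
    e1 <- eigen(maker(sys, "HRM.1")$matrix, symmetric = TRUE)$values
    e2 <- eigen(maker(rot, "HRM.1")$matrix, symmetric = TRUE)$values
    expect_equal(e2, e1, tolerance = 1e-8)
  }
})

test_that("united-atom translational filtering leaves exactly 3N - 6 modes", {
  top <- make_chain_topology()    # 4 point united atoms
  geom <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.7, 1.4, 0.4))
  sys <- make_system(top, geom, random_force_frames(200, 4, seed = 8))
  res <- vibrational_entropy(sys, "CHN.1", "united_atom", "translation",
                             detail = TRUE)
  expect_equal(res$spectrum$n_vib, 12L)          # 3N raw modes
  expect_equal(res$entropy,
               qho_entropy(res$spectrum, 300, n_drop = 6L))
  expect_lt(res$entropy,
            qho_entropy(res$spectrum, 300, n_drop = 0L))
})

test_that("point united atoms contribute no rotational rows", {
  top <- make_chain_topology()
  geom <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0), c(3.7, 1.4, 0.4))
  sys <- make_system(top, geom, random_force_frames(10, 4, seed = 2))
  expect_error(weighted_torque_covariance(sys, "CHN.1", "united_atom"),
               "no united atoms with rotational DOF")
  uas <- define_united_atoms(top, "CHN.1")
  expect_error(
    weighted_torque_covariance(sys, "CHN.1", "united_atom", units = uas),
    "point united atom")

  # methanol: CH3 (3) + OH (2) span a 5 x 5 torque covariance
  top <- make_methanol_topology()
  sysm <- make_system(top, methanol_geometry(),
                      random_force_frames(50, 6, seed = 4))
  cv <- weighted_torque_covariance(sysm, "MOL.1", "united_atom")
  expect_equal(dim(cv$matrix), c(5L, 5L))
})

test_that("spectrum audit files round-trip the mode table", {
  h <- harmonic_trajectory(harmonic_spec(n_frames = 200, seed = 3))
  sp <- frequencies_from_eigenvalues(
    weighted_force_covariance(h$system, "HRM.1"), 300)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, path, 300)
  tab <- read.table(path, header = TRUE)
  expect_equal(nrow(tab), sp$n_vib)
  expect_equal(tab$nu_hz, sp$nu, tolerance = 1e-8)
  expect_equal(sum(tab$entropy_JKmol), qho_entropy(sp, 300),
               tolerance = 1e-8)
})
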