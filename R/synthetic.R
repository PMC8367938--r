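#' Synthetic fixtures with analytic ground truth
#'
#' Generators for force-bearing trajectories, dihedral series and hydration
#' shell geometries whose exact answers are known in closed form. Sampling
#' is i.i.d. Boltzmann (not dynamics): the entropy estimators use only
#' static covariances and histograms, so time correlation is irrelevant to
#' their ground truth, but users should not expect kinetic realism.

.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, globalenv()))
  expr
}

#' Specification of a harmonic rigid-body fixture
#'
#' A rigid non-linear "molecule" whose net force and net torque fluctuate
#' as independent Boltzmann-distributed harmonic modes along its principal
#' axes.
#'
#' @param k_trans length-3 translational force constants (kJ mol^-1 A^-2)
#' @param kappa_rot length-3 librational stiffnesses (kJ mol^-1 rad^-2)
#' @param masses per-atom masses (amu) of the >= 3 atom scaffold
#' @param temperature temperature (K)
#' @param n_frames number of frames (>= 2)
#' @param seed RNG seed, recorded in the fixture metadata
#' @return object of class `mcc_harmonic_spec`
#' @export
harmonic_spec <- function(k_trans = c(150, 250, 400),
                          kappa_rot = c(120, 200, 320),
                          masses = c(12.011, 15.999, 14.007),
                          temperature = 300, n_frames = 1000, seed = 1) {
  stopifnot(length(k_trans) == 3, all(k_trans > 0),
            length(kappa_rot) == 3, all(kappa_rot > 0),
            length(masses) >= 3, all(masses > 0),
            temperature > 0, n_frames >= 2)
  structure(list(k_trans = k_trans, kappa_rot = kappa_rot, masses = masses,
                 temperature = temperature, n_frames = as.integer(n_frames),
                 seed = seed),
            class = "mcc_harmonic_spec")
}

# fixed non-collinear scaffold for the first three atoms; extras fan out
.harmonic_geometry <- function(n) {
  base <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.4, 1.3, 0.2))
  if (n > 3)
    base <- rbind(base, t(vapply(4:n, function(i)
      c(0.8 * cos(i), 0.8 * sin(i), 0.5 * i), numeric(3))))
  base
}

# exact mode frequencies (s^-1) implied by a harmonic spec and its geometry
.harmonic_frequencies <- function(spec) {
  geom <- .harmonic_geometry(length(spec$masses))
  pf <- principal_frame(geom, spec$masses)
  M <- sum(spec$masses)
  nu_t <- sqrt(spec$k_trans * .u$spring / (M * .u$mass)) / (2 * pi)
  nu_r <- sqrt(spec$kappa_rot * .u$stiff / (pf$moments * .u$moi)) / (2 * pi)
  list(translation = nu_t, rotation = nu_r, moments = pf$moments,
       mass = M, frame = pf)
}

#' Sample a harmonic rigid-body trajectory
#'
#' Mode displacements are drawn from the exact Boltzmann distribution
#' (`x ~ N(0, kB T / k)` per principal axis) with conjugate forces
#' `F = -k x` and torques `tau = -kappa theta`. Net forces and torques are
#' distributed over the atoms by the minimum-norm solution of the
#' force/torque balance, so the sums recovered by the covariance pipeline
#' are exact by construction. Deterministic for a given seed.
#'
#' @param spec an [harmonic_spec()]
#' @return list with `system` (an `mcc_system`), `nu` (exact mode
#'   frequencies, s^-1, translation then rotation) and `spec`
#' @export
harmonic_trajectory <- function(spec) {
  stopifnot(inherits(spec, "mcc_harmonic_spec"))
  n_at <- length(spec$masses)
  geom <- .harmonic_geometry(n_at)
  truth <- .harmonic_frequencies(spec)
  Q <- truth$frame$axes                      # rows are principal axes
  com <- truth$frame$origin
  RT <- mcc_constants$R * spec$temperature / 1000  # kJ mol^-1

  # balance matrix: net force rows then net torque rows about the COM
  A <- matrix(0, 6, 3 * n_at)
  for (j in seq_len(n_at)) {
    cols <- 3 * (j - 1) + 1:3
    A[1:3, cols] <- diag(3)
    r <- geom[j, ] - com
    A[4:6, cols] <- rbind(c(0, -r[3], r[2]),
                          c(r[3], 0, -r[1]),
                          c(-r[2], r[1], 0))
  }
  Apinv <- t(A) %*% solve(A %*% t(A))

  nf <- spec$n_frames
  coords <- array(NA_real_, c(nf, n_at, 3))
  forces <- array(NA_real_, c(nf, n_at, 3))
  .with_seed(spec$seed, {
    x_sd <- sqrt(RT / spec$k_trans)
    th_sd <- sqrt(RT / spec$kappa_rot)
    for (f in seq_len(nf)) {
      x_pa <- rnorm(3, 0, x_sd)
      F_pa <- -spec$k_trans * x_pa
      tau_pa <- -spec$kappa_rot * rnorm(3, 0, th_sd)
      b <- c(drop(t(Q) %*% F_pa), drop(t(Q) %*% tau_pa))
      fat <- matrix(Apinv %*% b, ncol = 3, byrow = TRUE)
      disp <- drop(t(Q) %*% x_pa)
      coords[f, , ] <- sweep(geom, 2, disp, "+")
      forces[f, , ] <- fat
    }
  })

  elements <- rep(c("C", "O", "N"), length.out = n_at)
  atoms <- data.frame(id = seq_len(n_at),
                      name = paste0(elements, seq_len(n_at)),
                      element = elements, mass = spec$masses,
                      mol = "HRM.1", stringsAsFactors = FALSE)
  molecules <- data.frame(name = "HRM.1", role = "other", symmetry = 1)
  top <- mcc_topology(atoms, matrix(integer(), ncol = 2), molecules)
  traj <- mcc_trajectory(coords, forces)
  cfg <- mcc_config(temperature = spec$temperature)
  list(system = load_system(top, traj, cfg),
       nu = c(truth$translation, truth$rotation), spec = spec)
}

#' Analytic vibrational entropy of a harmonic spec
#'
#' Closed-form oracle: mode frequencies `(1/2pi) sqrt(k/m)` and
#' `(1/2pi) sqrt(kappa/I)` (moments of inertia from the fixture geometry),
#' summed through the quantum-harmonic-oscillator entropy.
#'
#' @param spec an [harmonic_spec()]
#' @return list with `nu` (s^-1) and `entropy` (J K^-1 mol^-1)
#' @export
analytic_entropy_oracle <- function(spec) {
  truth <- .harmonic_frequencies(spec)
  nu <- c(truth$translation, truth$rotation)
  list(nu = nu, entropy = qho_entropy(nu, spec$temperature))
}

#' Multi-well dihedral series with known conformer entropy
#'
#' Angles are drawn from a mixture of wrapped normal wells. Ground truth:
#' the conformer entropy of the mixture is `-kB sum w ln w` provided the
#' wells are resolvable, which is enforced by requiring well separations
#' greater than twice the histogram bin width.
#'
#' @param well_centers well centres in degrees
#' @param weights mixture weights (sum to 1)
#' @param spread within-well standard deviation (degrees)
#' @param n number of frames
#' @param seed RNG seed
#' @param bin_width bin width the series is meant to be analysed with
#' @return list with `angles` (degrees on `[0,360)`), `components` (true
#'   well index per frame) and `true_entropy` (J K^-1 mol^-1)
#' @export
dihedral_fixture <- function(well_centers, weights, spread = 10,
                             n = 1000, seed = 1, bin_width = 30) {
  stopifnot(length(well_centers) == length(weights), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (length(well_centers) > 1L) {
    cc <- well_centers %% 360
    sep <- outer(cc, cc, function(a, b) {
      d <- abs(a - b) %% 360
      pmin(d, 360 - d)
    })
    if (min(sep[upper.tri(sep)]) <= 2 * bin_width)
      stop("overlapping wells: separations must exceed twice the bin width")
  }
  .with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    angles <- (rnorm(n, well_centers[comp], spread)) %% 360
  })
  list(angles = angles, components = comp,
       true_entropy = -mcc_constants$R * sum(weights * log(weights)))
}

#' Solute-plus-water-shell geometry with known first shell
#'
#' A single-site solute with `n_contact` waters placed at contact distance,
#' angularly spread so none blocks another's line to the solute, and
#' `n_distant` waters placed directly behind contact waters (blocked by
#' construction). With no contact waters the distant waters are laid on an
#' equidistant arc whose mutual chords are short enough that each arc-mate
#' blocks the solute, so the true first shell is empty.
#'
#' @param n_contact number of first-shell waters (placement fails beyond
#'   the angular packing limit)
#' @param n_distant number of beyond-shell waters
#' @param seed RNG seed (randomises the global orientation)
#' @param r_contact contact distance (Angstrom)
#' @return list with `system` (single-frame `mcc_system`, waters as
#'   one-site molecules), `contact` and `distant` (water molecule names),
#'   `true_shell` (= `contact`)
#' @export
shell_fixture <- function(n_contact, n_distant, seed = 1, r_contact = 3) {
  stopifnot(n_contact >= 0, n_distant >= 0)
  if (n_contact == 0 && n_distant == 1)
    stop("a single isolated water always coordinates the solute; ",
         "an empty shell needs n_distant >= 2 mutual blockers")
  dirs <- NULL
  if (n_contact > 0) {
    i <- seq_len(n_contact)
    golden <- pi * (3 - sqrt(5))
    z <- if (n_contact == 1) 0 else 1 - 2 * (i - 1) / (n_contact - 1)
    rho <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(rho * cos(golden * i), rho * sin(golden * i), z)
    if (n_contact > 1) {
      cosang <- tcrossprod(dirs)
      diag(cosang) <- -1
      if (max(cosang) > cos(35 * pi / 180))
        stop("too many contact waters: mutual angles below the ",
             "non-blocking limit")
    }
  }
  # random global rotation so fixtures differ by seed
  Rot <- .with_seed(seed, {
    M <- matrix(rnorm(9), 3)
    qr.Q(qr(M))
  })
  if (det(Rot) < 0) Rot[, 1] <- -Rot[, 1]

  coords <- matrix(0, 1 + n_contact + n_distant, 3)
  labels <- c("solute", rep("contact", n_contact), rep("distant", n_distant))
  if (n_contact > 0)
    coords[1 + seq_len(n_contact), ] <- r_contact * dirs %*% t(Rot)
  if (n_distant > 0) {
    if (n_contact > 0) {
      behind <- rep(seq_len(n_contact), length.out = n_distant)
      lap <- (seq_len(n_distant) - 1) %/% n_contact
      radii <- r_contact * (2.5 + 0.7 * lap)
      coords[1 + n_contact + seq_len(n_distant), ] <-
        radii * dirs[behind, , drop = FALSE] %*% t(Rot)
    } else {
      D <- 10 * r_contact
      phi <- 2 * asin(1 / 16) * (seq_len(n_distant) - 1)
      arc <- cbind(D * cos(phi), D * sin(phi), 0)
      coords[1 + seq_len(n_distant), ] <- arc %*% t(Rot)
    }
  }

  n_w <- n_contact + n_distant
  w_names <- if (n_w) paste0("WAT.", seq_len(n_w)) else character(0)
  atoms <- data.frame(
    id = seq_len(1 + n_w),
    name = c("C1", rep("OW", n_w)),
    element = c("C", rep("O", n_w)),
    mass = c(12.011, rep(15.999, n_w)),
    mol = c("GST.1", w_names), stringsAsFactors = FALSE)
  molecules <- data.frame(
    name = c("GST.1", w_names),
    role = c("guest", rep("water", n_w)),
    symmetry = c(1, rep(2, n_w)), stringsAsFactors = FALSE)
  top <- mcc_topology(atoms, matrix(integer(), ncol = 2), molecules)
  coords_arr <- array(coords, c(1, nrow(coords), 3))
  traj <- mcc_trajectory(coords_arr, coords_arr * 0)
  contact <- if (n_contact) w_names[seq_len(n_contact)] else character(0)
  list(system = load_system(top, traj),
       contact = contact,
       distant = if (n_distant) w_names[n_contact + seq_len(n_distant)]
                 else character(0),
       true_shell = contact, seed = seed)
}

#' Synthetic solvated system for pipeline integration tests
#'
#' A small box of rigid three-site waters on a jittered grid with
#' Boltzmann-like random forces, optionally around a flexible five-atom
#' chain solute. No force field is emulated; forces are i.i.d. normal with
#' magnitudes chosen to put vibrational frequencies in a liquid-like range,
#' which is all the static covariance estimators consume.
#'
#' @param n_water number of waters (placed on a cubic grid)
#' @param solute include the chain solute at the box centre
#' @param n_frames frames to sample
#' @param temperature temperature (K)
#' @param seed RNG seed
#' @return an `mcc_system`
#' @export
synthetic_solution <- function(n_water = 26, solute = TRUE, n_frames = 10,
                               temperature = 300, seed = 1) {
  RT <- mcc_constants$R * temperature / 1000   # kJ/mol
  f_sd <- sqrt(60 * RT)                        # ~liquid-like stiffness
  .with_seed(seed, {
    ng <- ceiling((2 * (n_water + 4))^(1 / 3))
    spacing <- 3.1
    grid <- as.matrix(expand.grid(seq_len(ng), seq_len(ng), seq_len(ng)))
    grid <- (grid - (ng + 1) / 2) * spacing
    grid <- grid[order(rowSums(grid^2)), ]
    if (solute) grid <- grid[sqrt(rowSums(grid^2)) > 4.2, , drop = FALSE]
    if (nrow(grid) < n_water) stop("too many waters for the grid")
    box <- rep(ng * spacing + 2, 3)
    center <- c(0, 0, 0)

    atoms <- list(); mols <- list(); xyz0 <- list()
    add_mol <- function(name, role, symmetry, elements, pos) {
      id0 <- sum(vapply(xyz0, nrow, 0L))
      atoms[[length(atoms) + 1L]] <<- data.frame(
        id = id0 + seq_along(elements),
        name = paste0(elements, seq_along(elements)),
        element = elements, mass = .element_mass(elements),
        mol = name, stringsAsFactors = FALSE)
      mols[[length(mols) + 1L]] <<- data.frame(
        name = name, role = role, symmetry = symmetry)
      xyz0[[length(xyz0) + 1L]] <<- pos
    }
    if (solute) {
      chain <- cbind(seq(0, 6, length.out = 5) - 3,
                     0.8 * sin(1:5), 0.6 * cos(1:5))
      add_mol("GST.1", "guest", 1, rep("C", 5),
              sweep(chain, 2, center, "+"))
    }
    wgeom <- rbind(c(0, 0, 0), c(0.9572, 0, 0),
                   c(-0.2399872, 0.9266272, 0))
    for (w in seq_len(n_water)) {
      M <- matrix(rnorm(9), 3); Q <- qr.Q(qr(M))
      pos <- sweep(wgeom %*% Q, 2, grid[w, ], "+")
      add_mol(paste0("WAT.", w), "water", 2, c("O", "H", "H"), pos)
    }
    atoms <- do.call(rbind, atoms)
    mols <- do.call(rbind, mols)
    base <- do.call(rbind, xyz0)
    bonds <- .infer_bonds(base, atoms$element)
    intra <- atoms$mol[bonds[, 1]] == atoms$mol[bonds[, 2]]
    bonds <- bonds[intra, , drop = FALSE]
    top <- mcc_topology(atoms, bonds, mols)

    na <- nrow(atoms)
    coords <- array(NA_real_, c(n_frames, na, 3))
    forces <- array(NA_real_, c(n_frames, na, 3))
    for (f in seq_len(n_frames)) {
      coords[f, , ] <- base + matrix(rnorm(na * 3, 0, 0.05), na, 3)
      forces[f, , ] <- matrix(rnorm(na * 3, 0, f_sd), na, 3)
    }
    traj <- mcc_trajectory(coords, forces,
                           box = matrix(box, 1))
    load_system(top, traj, mcc_config(temperature = temperature))
  })
}

#' Named synthetic presets
#'
#' Convenience entry point used by the command-line tool: currently
#' `harmonic-small` (3-atom harmonic rigid body), `dihedral-bimodal`
#' (60/180 degree equal-weight wells) and `shell-3-5` (3 contact plus 5
#' blocked waters).
#'
#' @param name preset name
#' @param seed RNG seed
#' @return the corresponding fixture object
#' @export
synth_preset <- function(name = c("harmonic-small", "dihedral-bimodal",
                                  "shell-3-5"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    "harmonic-small" = harmonic_trajectory(
      harmonic_spec(n_frames = 1000, seed = seed)),
    "dihedral-bimodal" = dihedral_fixture(c(60, 180), c(0.5, 0.5),
                                          n = 1000, seed = seed),
    "shell-3-5" = shell_fixture(3, 5, seed = seed))
}
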