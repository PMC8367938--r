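# Small topologies and trajectories built in code for the test suite.

# water: O with two bonded hydrogens (one united atom, rotational dof 3)
make_water_topology <- function() {
  atoms <- data.frame(
    id = 1:3, name = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
    mass = c(15.999, 1.008, 1.008), mol = "SOL.1",
    stringsAsFactors = FALSE)
  mcc_topology(atoms, rbind(c(1, 2), c(1, 3)),
               data.frame(name = "SOL.1", role = "water", symmetry = 2))
}

water_geometry <- function() {
  rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399872, 0.9266272, 0))
}

# methanol-like CH3-OH: two united atoms (CH3: dof 3, OH: dof 2)
make_methanol_topology <- function() {
  atoms <- data.frame(
    id = 1:6, name = c("C1", "H1", "H2", "H3", "O1", "H4"),
    element = c("C", "H", "H", "H", "O", "H"),
    mass = c(12.011, 1.008, 1.008, 1.008, 15.999, 1.008),
    mol = "MOL.1", stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(5, 6))
  mcc_topology(atoms, bonds,
               data.frame(name = "MOL.1", role = "guest", symmetry = 1))
}

methanol_geometry <- function() {
  rbind(c(0, 0, 0), c(-0.51, 0.89, 0), c(-0.51, -0.45, 0.77),
        c(-0.51, -0.45, -0.77), c(1.43, 0, 0), c(1.76, 0.88, 0.1))
}

# butane-like heavy-atom chain C-C-C-C with one rotatable dihedral and
# hydrogens omitted (conformational machinery works on heavy atoms)
make_chain_topology <- function() {
  atoms <- data.frame(
    id = 1:4, name = paste0("C", 1:4), element = rep("C", 4),
    mass = rep(12.011, 4), mol = "CHN.1", stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4))
  mcc_topology(atoms, bonds,
               data.frame(name = "CHN.1", role = "guest", symmetry = 1))
}

# trajectory with constant geometry and supplied per-frame forces
make_system <- function(topology, geometry, force_frames, box = NULL,
                        config = mcc_config()) {
  nf <- length(force_frames)
  na <- nrow(geometry)
  coords <- array(NA_real_, c(nf, na, 3))
  forces <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- geometry
    forces[f, , ] <- force_frames[[f]]
  }
  bx <- if (!is.null(box)) matrix(box, 1)
  load_system(topology, mcc_trajectory(coords, forces, box = bx), config)
}

random_force_frames <- function(n_frames, n_atoms, sd = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) matrix(rnorm(n_atoms * 3, 0, sd),
                                               n_atoms, 3))
}

# independent brute-force evaluation of the RAD blocking inequality,
# straight from its definition
rad_oracle <- function(center, candidates, box = NULL) {
  d <- sweep(matrix(candidates, ncol = 3), 2, center)
  d <- minimum_image(d, box)
  r <- sqrt(rowSums(d^2))
  accepted <- integer(0)
  for (j in order(r)) {
    blocked <- FALSE
    for (k in accepted) {
      cos_jik <- sum(d[j, ] * d[k, ]) / (r[j] * r[k])
      if (1 / r[j]^2 < (1 / r[k]^2) * cos_jik) blocked <- TRUE
    }
    if (!blocked) accepted <- c(accepted, j)
  }
  sort(accepted)
}

# write a minimal GRO file (positions supplied in Angstrom)
write_gro_fixture <- function(path, atoms, coords, box = c(30, 30, 30)) {
  lines <- c("fixture", sprintf("%5d", nrow(atoms)))
  resid <- as.integer(sub("^.*\\.", "", atoms$mol))
  resname <- sub("\\..*$", "", atoms$mol)
  for (i in seq_len(nrow(atoms))) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              resid[i], resname[i], atoms$name[i], i,
                              coords[i, 1] / 10, coords[i, 2] / 10,
                              coords[i, 3] / 10))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                            box[3] / 10))
  writeLines(lines, path)
  path
}
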