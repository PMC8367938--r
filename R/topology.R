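#' Topologies: atoms, bonds, molecules, united atoms

.water_resnames <- c("SOL", "WAT", "HOH", "TIP3", "T3P", "SPC")

#' Construct a topology
#'
#' @param atoms data.frame with columns `id` (integer, 1..n), `name`
#'   (atom name), `element` (symbol, "H" for hydrogens), `mass` (amu),
#'   `mol` (molecule instance name)
#' @param bonds 2-column integer matrix of atom ids (may have 0 rows)
#' @param molecules data.frame with columns `name` (matching `atoms$mol`),
#'   `role` (one of host, guest, water, other) and `symmetry` (rotational
#'   symmetry number, integer >= 1)
#' @return object of class `mcc_topology`
#' @export
mcc_topology <- function(atoms, bonds, molecules) {
  atoms <- as.data.frame(atoms)
  molecules <- as.data.frame(molecules)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  stopifnot(all(c("id", "name", "element", "mass", "mol") %in% names(atoms)),
            all(c("name", "role", "symmetry") %in% names(molecules)))
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (!identical(atoms$id, seq_len(nrow(atoms))))
    stop("atom ids must be 1..n in order")
  if (anyDuplicated(molecules$name))
    stop("duplicate molecule names")
  if (!all(atoms$mol %in% molecules$name))
    stop("every atom must belong to a declared molecule")
  if (!all(molecules$role %in% c("host", "guest", "water", "other")))
    stop("molecule role must be host, guest, water or other")
  if (any(molecules$symmetry < 1) ||
      any(molecules$symmetry != round(molecules$symmetry)))
    stop("symmetry numbers must be integers >= 1")
  if (nrow(bonds)) {
    if (any(bonds < 1L) || any(bonds > nrow(atoms)))
      stop("bond atom ids out of range")
    same_mol <- atoms$mol[bonds[, 1]] == atoms$mol[bonds[, 2]]
    if (!all(same_mol))
      stop("bonds must connect atoms within one molecule")
  }
  structure(list(atoms = atoms, bonds = bonds, molecules = molecules),
            class = "mcc_topology")
}

#' @export
print.mcc_topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      nrow(x$molecules), "molecules\n")
  print(table(x$molecules$role))
  invisible(x)
}

#' Atom ids belonging to one molecule
#' @param topology an [mcc_topology()]
#' @param molecule molecule instance name
#' @return integer vector of atom ids
#' @export
molecule_atoms <- function(topology, molecule) {
  ids <- topology$atoms$id[topology$atoms$mol == molecule]
  if (!length(ids)) stop("unknown molecule: ", molecule)
  ids
}

#' Molecule names carrying a given role
#' @param topology an [mcc_topology()]
#' @param role one of host, guest, water, other
#' @export
molecules_by_role <- function(topology, role) {
  topology$molecules$name[topology$molecules$role == role]
}

.infer_element <- function(name) {
  core <- gsub("[^A-Za-z]", "", name)
  two <- c("Cl", "Br", "Na", "Mg", "Ca", "Fe", "Zn")
  hit <- two[toupper(two) == toupper(substr(core, 1, 2))]
  if (length(hit)) return(hit[1])
  toupper(substr(core, 1, 1))
}

.element_mass <- function(element) {
  m <- .atomic_masses[element]
  if (any(is.na(m))) stop("unknown element(s): ",
                          paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

# bonds inferred from covalent distance cutoffs; adequate for water and for
# fixtures, real solutes should supply an explicit bond list
.infer_bonds <- function(coords, elements) {
  n <- nrow(coords)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    cutoff <- if (elements[i] == "H" || elements[j] == "H") 1.25 else 1.9
    if (elements[i] == "H" && elements[j] == "H") cutoff <- 0
    if (d < cutoff) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) matrix(integer(), ncol = 2) else do.call(rbind, out)
}

#' Read a GRO coordinate file into atoms + coordinates
#'
#' Fixed-width GROMACS GRO format; positions are converted from nm to
#' Angstrom. Each residue becomes one molecule instance named
#' `<resname>.<resid>`.
#'
#' @param path GRO file
#' @return list with `atoms` (data.frame, no bonds), `coords` (n x 3,
#'   Angstrom), `box` (length 3, Angstrom)
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  if (is.na(n) || length(lines) < n + 3L) stop("malformed GRO file: ", path)
  al <- lines[3:(2 + n)]
  resid <- as.integer(substr(al, 1, 5))
  resname <- trimws(substr(al, 6, 10))
  aname <- trimws(substr(al, 11, 15))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  box <- as.numeric(strsplit(trimws(lines[n + 3L]), "\\s+")[[1]])[1:3] * 10
  element <- vapply(aname, .infer_element, "", USE.NAMES = FALSE)
  atoms <- data.frame(
    id = seq_len(n), name = aname, element = element,
    mass = .element_mass(element),
    mol = paste(resname, resid, sep = "."),
    stringsAsFactors = FALSE
  )
  list(atoms = atoms, coords = unname(cbind(x, y, z)) * 10, box = box)
}

#' Read a topology from a GRO or PDB file
#'
#' @param path coordinate/topology file (`.gro`, or `.pdb` via bio3d)
#' @param bonds optional 2-column matrix of bonded atom-id pairs, or a path
#'   to a two-column whitespace text file of them; if `NULL`, bonds are
#'   inferred from covalent distance cutoffs
#' @param roles named character vector mapping residue names to roles
#'   (host/guest/water/other); common water residue names default to
#'   "water", everything else to "other"
#' @param symmetry named numeric vector mapping residue names to rotational
#'   symmetry numbers (default 1; water defaults to 2)
#' @return list with `topology` ([mcc_topology()]), `coords`, `box`
#' @export
read_topology <- function(path, bonds = NULL, roles = NULL, symmetry = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path)
  } else if (ext == "pdb") {
    if (!requireNamespace("bio3d", quietly = TRUE))
      stop("reading PDB topologies requires the bio3d package")
    pdb <- bio3d::read.pdb(path)
    a <- pdb$atom
    element <- ifelse(is.na(a$elesy) | a$elesy == "",
                      vapply(a$elety, .infer_element, ""),
                      trimws(a$elesy))
    element <- vapply(element, function(e) {
      paste0(toupper(substr(e, 1, 1)), tolower(substr(e, 2, nchar(e))))
    }, "")
    element[nchar(element) == 1] <- toupper(element[nchar(element) == 1])
    atoms <- data.frame(
      id = seq_len(nrow(a)), name = trimws(a$elety), element = element,
      mass = .element_mass(element),
      mol = paste(trimws(a$resid), a$resno, sep = "."),
      stringsAsFactors = FALSE
    )
    g <- list(atoms = atoms, coords = cbind(a$x, a$y, a$z), box = NULL)
  } else stop("unsupported topology format: .", ext)

  if (is.character(bonds)) bonds <- as.matrix(read.table(bonds))
  if (is.null(bonds)) bonds <- .infer_bonds(g$coords, g$atoms$element)

  resname <- sub("\\..*$", "", g$atoms$mol)
  mol_names <- unique(g$atoms$mol)
  mol_res <- resname[match(mol_names, g$atoms$mol)]
  role <- rep("other", length(mol_names))
  role[mol_res %in% .water_resnames] <- "water"
  if (!is.null(roles)) {
    hit <- match(mol_res, names(roles))
    role[!is.na(hit)] <- roles[hit[!is.na(hit)]]
  }
  sym <- rep(1, length(mol_names))
  sym[role == "water"] <- 2
  if (!is.null(symmetry)) {
    hit <- match(mol_res, names(symmetry))
    sym[!is.na(hit)] <- symmetry[hit[!is.na(hit)]]
  }
  molecules <- data.frame(name = mol_names, role = role, symmetry = sym,
                          stringsAsFactors = FALSE)
  list(topology = mcc_topology(g$atoms, bonds, molecules),
       coords = g$coords, box = g$box)
}

#' Partition a molecule into united atoms
#'
#' A united atom is one heavy atom plus its bonded hydrogens. Rotational
#' degrees of freedom: 3 when the unit carries more than one hydrogen
#' (non-linear), 2 with exactly one hydrogen (linear), 0 with none (point).
#'
#' @param topology an [mcc_topology()]
#' @param molecule molecule instance name
#' @return list of `mcc_united_atom` objects, ordered by heavy-atom id;
#'   each holds `heavy` (atom id), `hydrogens` (atom ids), `atoms` (all
#'   ids), `rotational_dof`
#' @export
define_united_atoms <- function(topology, molecule) {
  ids <- molecule_atoms(topology, molecule)
  at <- topology$atoms[ids, ]
  heavy <- at$id[at$element != "H"]
  hydro <- at$id[at$element == "H"]
  b <- topology$bonds
  in_mol <- b[, 1] %in% ids & b[, 2] %in% ids
  b <- b[in_mol, , drop = FALSE]
  h_of <- setNames(vector("list", length(heavy)), as.character(heavy))
  owner <- integer(0)
  for (h in hydro) {
    partners <- c(b[b[, 1] == h, 2], b[b[, 2] == h, 1])
    partners <- partners[topology$atoms$element[partners] != "H"]
    if (length(partners) == 0L)
      stop("free hydrogen (atom ", h, "): ill-formed topology")
    if (length(partners) > 1L)
      stop("hydrogen ", h, " bonded to multiple heavy atoms: ill-formed topology")
    h_of[[as.character(partners)]] <- c(h_of[[as.character(partners)]], h)
    owner[as.character(h)] <- partners
  }
  lapply(heavy, function(hv) {
    hs <- h_of[[as.character(hv)]]
    nh <- length(hs)
    structure(list(
      heavy = hv, hydrogens = hs, atoms = c(hv, hs),
      rotational_dof = if (nh >= 2L) 3L else if (nh == 1L) 2L else 0L
    ), class = "mcc_united_atom")
  })
}

# local axes of a united atom from its bonded-hydrogen directions.
# Rows of the returned matrix are (x, y, z) with z along the mean
# heavy->H direction and x in the plane of the first two H bonds (or an
# arbitrary deterministic perpendicular for a single hydrogen).
.ua_axes <- function(heavy_xyz, h_xyz) {
  nh <- nrow(h_xyz)
  stopifnot(nh >= 1L)
  dirs <- sweep(h_xyz, 2, heavy_xyz)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  z <- .normalize(colSums(dirs))
  if (nh >= 2L) {
    cand <- dirs[1, ]
    perp <- cand - sum(cand * z) * z
    if (sqrt(sum(perp^2)) < 1e-8) {
      cand <- dirs[2, ]
      perp <- cand - sum(cand * z) * z
    }
    x <- .normalize(perp)
  } else {
    e <- diag(3)[, which.min(abs(z))]
    x <- .normalize(e - sum(e * z) * z)
  }
  y <- .cross3(z, x)
  rbind(x = x, y = y, z = z)
}

# moment of inertia (amu A^2) of the UA atoms about an axis through origin
.moment_about_axis <- function(coords, masses, origin, axis) {
  r <- sweep(coords, 2, origin)
  sum(masses * (rowSums(r^2) - (r %*% axis)^2))
}
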