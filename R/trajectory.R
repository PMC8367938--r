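#' Force-bearing trajectories and system containers

#' Construct an in-memory trajectory
#'
#' @param coords numeric array `[frame, atom, xyz]` in Angstrom
#' @param forces numeric array of the same shape in kJ mol^-1 A^-1
#' @param times frame times in ps
#' @param box `n_frames x 3` matrix of orthorhombic box edges (Angstrom) or
#'   `NULL` for non-periodic fixtures
#' @return object of class `mcc_trajectory`
#' @export
mcc_trajectory <- function(coords, forces, times = NULL, box = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (is.null(forces)) stop("forces required: trajectory has no force records")
  stopifnot(identical(dim(coords), dim(forces)))
  nf <- dim(coords)[1]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  stopifnot(length(times) == nf)
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (nrow(box) == 1L) box <- box[rep(1L, nf), , drop = FALSE]
    stopifnot(nrow(box) == nf, all(box > 0))
  }
  structure(list(coords = coords, forces = forces, times = times, box = box),
            class = "mcc_trajectory")
}

#' @export
print.mcc_trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "frames x", dim(x$coords)[2],
      "atoms (coordinates + forces)\n")
  invisible(x)
}

#' Number of frames / atoms
#' @param trajectory an [mcc_trajectory()]
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(trajectory) dim(trajectory$coords)[2]

#' Write a trajectory as plain text
#'
#' One block per frame: a `frame <time_ps>` line, a `box <bx> <by> <bz>`
#' line (Angstrom; omitted when non-periodic), then one row per atom with
#' six columns `x y z fx fy fz` (Angstrom, kJ mol^-1 A^-1).
#'
#' @param trajectory an [mcc_trajectory()]
#' @param path output file
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(trajectory)
  na <- n_atoms(trajectory)
  writeLines(c("# eemcc-trj 1",
               paste("# natoms", na),
               "# columns x y z fx fy fz (Angstrom, kJ/mol/Angstrom)"), con)
  for (f in seq_len(nf)) {
    writeLines(sprintf("frame %.10g", trajectory$times[f]), con)
    if (!is.null(trajectory$box))
      writeLines(paste("box",
                       paste(sprintf("%.10g", trajectory$box[f, ]),
                             collapse = " ")), con)
    block <- cbind(trajectory$coords[f, , ], trajectory$forces[f, , ])
    writeLines(apply(block, 1, function(r)
      paste(sprintf("%.10g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a plain-text trajectory
#'
#' @param path file written by [write_trajectory()] (or by any tool emitting
#'   the same layout)
#' @param stride keep every `stride`-th frame (default every frame)
#' @return an [mcc_trajectory()]
#' @export
read_trajectory <- function(path, stride = 1L) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  starts <- grep("^frame\\b", lines)
  if (!length(starts)) stop("no frames found in trajectory: ", path)
  nf <- length(starts)
  ends <- c(starts[-1] - 1L, length(lines))
  keep <- seq(1L, nf, by = stride)
  first_block <- lines[(starts[1] + 1L):ends[1]]
  has_box <- grepl("^box\\b", first_block[1])
  na <- length(first_block) - has_box
  coords <- array(NA_real_, c(length(keep), na, 3))
  forces <- array(NA_real_, c(length(keep), na, 3))
  times <- numeric(length(keep))
  box <- if (has_box) matrix(NA_real_, length(keep), 3) else NULL
  for (i in seq_along(keep)) {
    f <- keep[i]
    times[i] <- as.numeric(strsplit(trimws(lines[starts[f]]), "\\s+")[[1]][2])
    at <- starts[f] + 1L
    if (has_box) {
      box[i, ] <- as.numeric(strsplit(trimws(lines[at]), "\\s+")[[1]][2:4])
      at <- at + 1L
    }
    block <- lines[at:(at + na - 1L)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                   nrow = na, byrow = TRUE)
    if (ncol(vals) < 6L)
      stop("forces required: trajectory rows carry only coordinates")
    coords[i, , ] <- vals[, 1:3]
    forces[i, , ] <- vals[, 4:6]
  }
  mcc_trajectory(coords, forces, times, box)
}

#' Read a two-column energy time series
#'
#' @param path whitespace text file: time (ps), energy (kJ mol^-1);
#'   lines starting with `#`, `@` or `;` are skipped (xvg-style)
#' @return data.frame with columns `time`, `energy`
#' @export
read_energy_series <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@;]", lines) & nzchar(trimws(lines))]
  vals <- read.table(text = lines)
  if (ncol(vals) < 2L) stop("energy series must have two columns (time, energy)")
  data.frame(time = vals[[1]], energy = vals[[2]])
}

#' Bind a topology and a trajectory into one system
#'
#' @param topology an [mcc_topology()] or a path accepted by
#'   [read_topology()]
#' @param trajectory an [mcc_trajectory()] or a path accepted by
#'   [read_trajectory()]
#' @param config an [mcc_config()]
#' @param ... passed to [read_topology()] when `topology` is a path
#' @return object of class `mcc_system`: list with `topology`,
#'   `trajectory`, `config`
#' @export
load_system <- function(topology, trajectory, config = mcc_config(), ...) {
  if (is.character(topology)) topology <- read_topology(topology, ...)$topology
  if (is.character(trajectory))
    trajectory <- read_trajectory(trajectory, stride = config$stride)
  stopifnot(inherits(topology, "mcc_topology"),
            inherits(trajectory, "mcc_trajectory"))
  if (nrow(topology$atoms) != n_atoms(trajectory))
    stop("atom count mismatch: topology has ", nrow(topology$atoms),
         " atoms, trajectory has ", n_atoms(trajectory))
  structure(list(topology = topology, trajectory = trajectory,
                 config = config), class = "mcc_system")
}

#' @export
print.mcc_system <- function(x, ...) {
  cat("EE-MCC system\n")
  print(x$topology)
  print(x$trajectory)
  invisible(x)
}
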