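#' Geometry helpers: centres of mass, inertia, reference frames, dihedrals

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Minimum-image displacement under an orthorhombic box
#'
#' @param d displacement vector or n x 3 matrix (Angstrom)
#' @param box length-3 box edge vector (Angstrom) or `NULL` for no
#'   periodicity
#' @return displacement wrapped into `[-box/2, box/2)` per component
#' @export
minimum_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Unwrap a molecule across periodic boundaries
#'
#' Rebuilds a molecule that may be split by the periodic box by placing
#' every atom at the minimum-image position relative to the first atom.
#' Valid for molecules smaller than half the box edge, which holds for all
#' solutes and waters considered here.
#'
#' @param coords n x 3 coordinate matrix (Angstrom)
#' @param box length-3 box vector or `NULL`
#' @return unwrapped n x 3 matrix
#' @export
unwrap_coords <- function(coords, box = NULL) {
  if (is.null(box) || nrow(coords) == 1L) return(coords)
  ref <- coords[1, ]
  d <- sweep(coords, 2, ref)
  sweep(minimum_image(d, box), 2, ref, "+")
}

#' Centre of mass
#' @param coords n x 3 matrix (Angstrom)
#' @param masses length-n masses (amu)
#' @return length-3 vector
#' @export
center_of_mass <- function(coords, masses) {
  drop(crossprod(coords, masses)) / sum(masses)
}

# inertia tensor about `origin` (amu A^2)
.inertia_tensor <- function(coords, masses, origin) {
  r <- sweep(coords, 2, origin)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(r^2)
  for (a in 1:3) for (b in 1:3) {
    I[a, b] <- sum(masses * ((a == b) * r2 - r[, a] * r[, b]))
  }
  I
}

#' Principal reference frame of a rigid unit
#'
#' Origin at the centre of mass; axes are the principal axes of the inertia
#' tensor with moments sorted ascending. Sign convention: each axis is
#' flipped so that its largest-magnitude component is positive, then the
#' third axis is replaced by the cross product of the first two so the frame
#' is always right-handed. This makes the frame deterministic and continuous
#' across trajectory frames for a slowly rotating molecule.
#'
#' @param coords n x 3 coordinates (Angstrom), already unwrapped
#' @param masses length-n masses (amu)
#' @return object of class `mcc_frame`: list with `origin` (Angstrom),
#'   `axes` (3 x 3, rows are unit axis vectors), `moments` (amu A^2,
#'   ascending)
#' @export
principal_frame <- function(coords, masses) {
  stopifnot(nrow(coords) == length(masses), all(masses > 0))
  if (nrow(coords) < 3L)
    stop("principal frame needs >= 3 atoms (non-linear rigid body)")
  origin <- center_of_mass(coords, masses)
  I <- .inertia_tensor(coords, masses, origin)
  eig <- eigen(I, symmetric = TRUE)
  ord <- order(eig$values)
  moments <- eig$values[ord]
  axes <- t(eig$vectors[, ord])  # rows are axes
  if (moments[1] < 1e-9 * max(moments))
    stop("degenerate (collinear) geometry: linear molecules are out of scope")
  for (a in 1:3) {
    imax <- which.max(abs(axes[a, ]))
    if (axes[a, imax] < 0) axes[a, ] <- -axes[a, ]
  }
  axes[3, ] <- .cross3(axes[1, ], axes[2, ])
  structure(list(origin = origin, axes = axes, moments = moments),
            class = "mcc_frame")
}

#' @export
print.mcc_frame <- function(x, ...) {
  cat("Principal frame\n  origin (A):", signif(x$origin, 6),
      "\n  moments (amu A^2):", signif(x$moments, 6), "\n")
  invisible(x)
}

#' Dihedral angle of four points
#'
#' Standard IUPAC convention, returned wrapped onto `[0, 360)` degrees.
#'
#' @param p 4 x 3 coordinate matrix, atoms in chain order a-b-c-d
#' @return angle in degrees on `[0, 360)`
#' @export
dihedral_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .normalize(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  ang %% 360
}
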