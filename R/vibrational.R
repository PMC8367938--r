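#' Vibrational entropy from force/torque covariance matrices
#'
#' The transvibrational and rovibrational entropies are obtained by mapping
#' the eigenvalues of mass-weighted force (translation) and
#' moment-of-inertia-weighted torque (rotation) covariance matrices onto
#' quantum-harmonic-oscillator frequencies. Matrices are built at the
#' molecule level (3 x 3 per motion, mean-field) or the united-atom level
#' (3N x 3N for translation, sum-of-rotational-DOF square for rotation).

# resolve the (possibly per-frame) reference frame used to express unit
# forces/torques; frame_atoms defaults to the molecule itself
.system_mol_data <- function(system, molecule) {
  top <- system$topology
  ids <- molecule_atoms(top, molecule)
  list(top = top, ids = ids, masses = top$atoms$mass[ids])
}

.frame_for <- function(system, frame_atoms, f) {
  xyz <- system$trajectory$coords[f, frame_atoms, , drop = TRUE]
  xyz <- matrix(xyz, ncol = 3)
  box <- if (!is.null(system$trajectory$box)) system$trajectory$box[f, ]
  principal_frame(unwrap_coords(xyz, box),
                  system$topology$atoms$mass[frame_atoms])
}

.check_frames <- function(system) {
  if (n_frames(system$trajectory) < 2L)
    stop("need at least 2 frames to form a covariance (no variance in one)")
}

#' Mass-weighted force covariance matrix
#'
#' Per frame, the net force on each unit (whole molecule, or each united
#' atom) is the sum of its atomic forces, expressed in the reference frame,
#' optionally halved (mean-field), and weighted by `1/sqrt(mass)`. The
#' covariance is taken over frames after mean subtraction. Entries are in
#' molar SI, `(J mol^-1 m^-1)^2 / (kg mol^-1)`, so that
#' `eigenvalue / (R T)` is an angular frequency squared.
#'
#' @param system an `mcc_system` from [load_system()]
#' @param molecule molecule instance name
#' @param level `"molecule"` (one 3 x 3 matrix) or `"united_atom"`
#'   (3N x 3N over the molecule's N united atoms)
#' @param units optional list of [define_united_atoms()] units (united-atom
#'   level only); defaults to the molecule's own partition
#' @param frame_atoms atom ids whose principal frame is used to express
#'   forces; defaults to the molecule itself. Pass the union of host and
#'   guest atoms to evaluate a bound host in the complex frame.
#' @param halving `"halved"` or `"raw"`; defaults to the system config
#' @return object of class `mcc_covariance`
#' @export
weighted_force_covariance <- function(system, molecule,
                                      level = c("molecule", "united_atom"),
                                      units = NULL, frame_atoms = NULL,
                                      halving = NULL) {
  level <- match.arg(level)
  .check_frames(system)
  halving <- halving %||% system$config$halving
  md <- .system_mol_data(system, molecule)
  if (is.null(frame_atoms)) frame_atoms <- md$ids
  nf <- n_frames(system$trajectory)
  half <- if (halving == "halved") 0.5 else 1

  if (level == "molecule") {
    M <- sum(md$masses)
    if (M <= 0) stop("zero-mass unit")
    W <- matrix(NA_real_, nf, 3)
    for (f in seq_len(nf)) {
      pf <- .frame_for(system, frame_atoms, f)
      Fnet <- colSums(matrix(system$trajectory$forces[f, md$ids, ], ncol = 3))
      W[f, ] <- drop(pf$axes %*% Fnet) * half / sqrt(M)
    }
    dof <- 3L
  } else {
    if (is.null(units)) units <- define_united_atoms(md$top, molecule)
    ms <- vapply(units, function(u) sum(md$top$atoms$mass[u$atoms]), 0)
    if (any(ms <= 0)) stop("zero-mass unit")
    dof <- 3L * length(units)
    W <- matrix(NA_real_, nf, dof)
    for (f in seq_len(nf)) {
      pf <- .frame_for(system, frame_atoms, f)
      row <- numeric(dof)
      for (i in seq_along(units)) {
        Fnet <- colSums(matrix(
          system$trajectory$forces[f, units[[i]]$atoms, ], ncol = 3))
        row[3L * (i - 1L) + 1:3] <- drop(pf$axes %*% Fnet) * half / sqrt(ms[i])
      }
      W[f, ] <- row
    }
  }
  W <- W * .u$force / sqrt(.u$mass)
  structure(list(matrix = cov(W), level = level, motion = "translation",
                 n_frames = nf, dof = dof, halving = halving),
            class = "mcc_covariance")
}

#' Moment-of-inertia-weighted torque covariance matrix
#'
#' Torques are taken about each unit's origin (molecular centre of mass, or
#' the heavy atom of a united atom), expressed along the unit's axes
#' (principal axes, or hydrogen-bond-derived local axes), optionally halved,
#' and each component weighted by `1/sqrt(I_axis)`. Point united atoms (no
#' hydrogens) carry no rotational degrees of freedom and must not be
#' included. Entries are in molar SI, `(J mol^-1)^2 / (kg m^2 mol^-1)`.
#'
#' @inheritParams weighted_force_covariance
#' @return object of class `mcc_covariance`
#' @export
weighted_torque_covariance <- function(system, molecule,
                                       level = c("molecule", "united_atom"),
                                       units = NULL, frame_atoms = NULL,
                                       halving = NULL) {
  level <- match.arg(level)
  .check_frames(system)
  halving <- halving %||% system$config$halving
  md <- .system_mol_data(system, molecule)
  nf <- n_frames(system$trajectory)
  half <- if (halving == "halved") 0.5 else 1
  traj <- system$trajectory

  if (level == "molecule") {
    W <- matrix(NA_real_, nf, 3)
    for (f in seq_len(nf)) {
      box <- if (!is.null(traj$box)) traj$box[f, ]
      xyz <- unwrap_coords(matrix(traj$coords[f, md$ids, ], ncol = 3), box)
      pf <- principal_frame(xyz, md$masses)
      if (any(pf$moments < 1e-9 * max(pf$moments)))
        stop("vanishing principal moment: cannot weight torques")
      rel <- sweep(xyz, 2, pf$origin)
      Fat <- matrix(traj$forces[f, md$ids, ], ncol = 3)
      tau <- c(sum(rel[, 2] * Fat[, 3] - rel[, 3] * Fat[, 2]),
               sum(rel[, 3] * Fat[, 1] - rel[, 1] * Fat[, 3]),
               sum(rel[, 1] * Fat[, 2] - rel[, 2] * Fat[, 1]))
      W[f, ] <- drop(pf$axes %*% tau) * half / sqrt(pf$moments)
    }
    dof <- 3L
  } else {
    if (is.null(units)) {
      units <- define_united_atoms(md$top, molecule)
      units <- Filter(function(u) u$rotational_dof > 0L, units)
    }
    if (any(vapply(units, function(u) u$rotational_dof, 0L) == 0L))
      stop("point united atom (no hydrogens) has no rotational DOF")
    if (!length(units)) stop("no united atoms with rotational DOF")
    dofs <- vapply(units, function(u) u$rotational_dof, 0L)
    dof <- sum(dofs)
    offs <- cumsum(c(0L, dofs[-length(dofs)]))
    W <- matrix(NA_real_, nf, dof)
    for (f in seq_len(nf)) {
      box <- if (!is.null(traj$box)) traj$box[f, ]
      row <- numeric(dof)
      for (i in seq_along(units)) {
        u <- units[[i]]
        xyz <- unwrap_coords(matrix(traj$coords[f, u$atoms, ], ncol = 3), box)
        origin <- xyz[1, ]
        axes <- .ua_axes(origin, xyz[-1, , drop = FALSE])
        nax <- u$rotational_dof
        use <- seq_len(nax)          # x,y for linear; x,y,z for non-linear
        m_at <- md$top$atoms$mass[u$atoms]
        rel <- sweep(xyz, 2, origin)
        Fat <- matrix(traj$forces[f, u$atoms, ], ncol = 3)
        tau <- c(sum(rel[, 2] * Fat[, 3] - rel[, 3] * Fat[, 2]),
                 sum(rel[, 3] * Fat[, 1] - rel[, 1] * Fat[, 3]),
                 sum(rel[, 1] * Fat[, 2] - rel[, 2] * Fat[, 1]))
        for (a in use) {
          I_ax <- .moment_about_axis(xyz, m_at, origin, axes[a, ])
          if (I_ax < 1e-10)
            stop("vanishing united-atom moment of inertia on a used axis")
          row[offs[i] + a] <- sum(tau * axes[a, ]) * half / sqrt(I_ax)
        }
      }
      W[f, ] <- row
    }
  }
  W <- W * .u$torque / sqrt(.u$moi)
  structure(list(matrix = cov(W), level = level, motion = "rotation",
                 n_frames = nf, dof = dof, halving = halving),
            class = "mcc_covariance")
}

#' @export
print.mcc_covariance <- function(x, ...) {
  cat("Weighted ", x$motion, " covariance (", x$level, " level): ",
      x$dof, " x ", x$dof, " over ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' Vibrational frequencies from covariance eigenvalues
#'
#' `nu_i = (1/2pi) sqrt(lambda_i / (kB T))` per eigenvalue `lambda_i` of the
#' weighted covariance matrix. Eigenvalues below `1e-12` of the largest are
#' treated as numerically null and excluded with a warning.
#'
#' @param covariance an `mcc_covariance`, or a plain symmetric matrix in
#'   molar SI units
#' @param temperature temperature (K)
#' @return object of class `mcc_spectrum`: list with `lambda`, `nu` (s^-1,
#'   ascending) and `n_vib`
#' @export
frequencies_from_eigenvalues <- function(covariance, temperature = 300) {
  m <- if (inherits(covariance, "mcc_covariance")) covariance$matrix
       else covariance
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop("covariance matrix must be symmetric")
  lam <- sort(eigen((m + t(m)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
  floor_ <- 1e-12 * max(lam, 0)
  keep <- lam > floor_
  if (!any(keep)) stop("degenerate covariance: all eigenvalues below tolerance")
  if (any(!keep))
    warning(sum(!keep), " eigenvalue(s) below numerical floor excluded")
  lam <- lam[keep]
  nu <- sqrt(lam / (mcc_constants$R * temperature)) / (2 * pi)
  structure(list(lambda = lam, nu = nu, n_vib = length(nu)),
            class = "mcc_spectrum")
}

#' @export
print.mcc_spectrum <- function(x, ...) {
  cat("Vibrational spectrum:", x$n_vib, "modes,",
      "nu =", paste(signif(x$nu, 4), collapse = " "), "s^-1\n")
  invisible(x)
}

#' Quantum-harmonic-oscillator entropy of a mode spectrum
#'
#' `S = kB * sum_i [ (h nu_i / kB T) / (exp(h nu_i / kB T) - 1)
#'                   - ln(1 - exp(-h nu_i / kB T)) ]`
#' in molar form (kB -> R). For united-atom translation the six
#' lowest-frequency modes are dropped first (`n_drop = 6`) so the count is
#' 3N - 6, avoiding duplication of the molecule-level rigid-body motions.
#'
#' @param spectrum an `mcc_spectrum` or a numeric vector of frequencies
#'   (s^-1)
#' @param temperature temperature (K)
#' @param n_drop number of lowest-frequency modes to discard before summing
#' @return entropy in J K^-1 mol^-1
#' @export
qho_entropy <- function(spectrum, temperature = 300, n_drop = 0L) {
  nu <- if (inherits(spectrum, "mcc_spectrum")) spectrum$nu else spectrum
  if (!length(nu)) stop("empty spectrum")
  if (any(nu < 0)) stop("negative frequency")
  nu <- sort(nu)
  if (n_drop >= length(nu)) return(0)
  if (n_drop > 0L) nu <- nu[-seq_len(n_drop)]
  x <- mcc_constants$h_molar * nu / (mcc_constants$R * temperature)
  term <- ifelse(x > 700, 0, x / expm1(x) - log1p(-exp(-x)))
  mcc_constants$R * sum(term)
}

#' Vibrational entropy of one molecule at one level and motion
#'
#' Convenience wrapper: builds the weighted covariance matrix, maps its
#' eigenvalues to frequencies and sums the quantum-harmonic-oscillator
#' entropy, applying the united-atom translational 3N - 6 filter.
#'
#' @inheritParams weighted_force_covariance
#' @param motion `"translation"` or `"rotation"`
#' @param detail return the spectrum alongside the entropy
#' @return entropy (J K^-1 mol^-1), or a list with `entropy`, `spectrum`
#'   when `detail = TRUE`
#' @export
vibrational_entropy <- function(system, molecule,
                                level = c("molecule", "united_atom"),
                                motion = c("translation", "rotation"),
                                units = NULL, frame_atoms = NULL,
                                halving = NULL, detail = FALSE) {
  level <- match.arg(level)
  motion <- match.arg(motion)
  cv <- if (motion == "translation")
    weighted_force_covariance(system, molecule, level, units, frame_atoms,
                              halving)
  else
    weighted_torque_covariance(system, molecule, level, units, frame_atoms,
                               halving)
  sp <- frequencies_from_eigenvalues(cv, system$config$temperature)
  n_drop <- if (level == "united_atom" && motion == "translation") 6L else 0L
  S <- qho_entropy(sp, system$config$temperature, n_drop = n_drop)
  if (detail) list(entropy = S, spectrum = sp, covariance = cv) else S
}

#' Write a spectrum audit file
#'
#' Plain-text table (mode index, eigenvalue, frequency, per-mode entropy
#' contribution) for inspection of a vibrational calculation.
#'
#' @param spectrum an `mcc_spectrum`
#' @param path output file
#' @param temperature temperature (K)
#' @export
write_spectrum <- function(spectrum, path, temperature = 300) {
  x <- mcc_constants$h_molar * spectrum$nu / (mcc_constants$R * temperature)
  s_i <- mcc_constants$R *
    ifelse(x > 700, 0, x / expm1(x) - log1p(-exp(-x)))
  df <- data.frame(mode = seq_along(spectrum$nu),
                   lambda = spectrum$lambda, nu_hz = spectrum$nu,
                   entropy_JKmol = s_i)
  write.table(format(df, digits = 10), path, quote = FALSE,
              row.names = FALSE, sep = "\t")
  invisible(path)
}
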