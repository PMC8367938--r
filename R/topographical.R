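#' Topographical (minima-counting) entropy terms
#'
#' Positional entropy from the standard-state mole fraction, orientational
#' entropy from the coordination geometry and symmetry number, and
#' conformational entropy from adaptively binned heavy-atom dihedral
#' distributions.

#' Positional entropy at a given mole fraction
#'
#' `S = kB ln(1 / x_aq)`. For a dilute solute at 1 M, `x_aq = 1/55.5`
#' (55.5 water molecules occupy the 1661 A^3 standard volume), giving
#' 33 J K^-1 mol^-1; for the solvent itself `x_aq ~ 1` and the term
#' vanishes.
#'
#' @param x_aq mole fraction in `(0, 1]`
#' @return entropy, J K^-1 mol^-1
#' @export
positional_entropy <- function(x_aq) {
  if (any(x_aq <= 0) || any(x_aq > 1)) stop("mole fraction must be in (0, 1]")
  mcc_constants$R * log(1 / x_aq)
}

#' Orientational entropy of a molecule in solution
#'
#' `S = kB ln( Nc^(3/2) sqrt(pi) p_corr / sigma )` with `Nc` the first-shell
#' coordination number (a trajectory mean, fractional), `sigma` the
#' rotational symmetry number and `p_corr` the orientational correlation
#' factor (1 for solutes, 0.25 for water to account for hydrogen-bond
#' correlation).
#'
#' @param n_c coordination number (> 0)
#' @param sigma symmetry number (>= 1)
#' @param p_corr correlation factor in `(0, 1]`
#' @return entropy, J K^-1 mol^-1
#' @export
orientational_entropy_solution <- function(n_c, sigma = 1, p_corr = 1) {
  if (any(n_c <= 0)) stop("coordination number must be positive")
  if (any(sigma < 1)) stop("symmetry number must be >= 1")
  if (any(p_corr <= 0) || any(p_corr > 1)) stop("p_corr must be in (0, 1]")
  mcc_constants$R * log(n_c^1.5 * sqrt(pi) * p_corr / sigma)
}

#' Orientational entropy of a bound guest
#'
#' A guest locked inside the host samples the host's symmetry-equivalent
#' orientations only: `S = kB ln(sigma_host / sigma_guest)`. The
#' cucurbit[8]uril host has sigma = 16 (8-fold plus 2-fold axes), giving
#' 23 J K^-1 mol^-1 for an asymmetric guest.
#'
#' @param sigma_host,sigma_guest symmetry numbers (>= 1)
#' @return entropy, J K^-1 mol^-1
#' @export
orientational_entropy_bound <- function(sigma_host, sigma_guest = 1) {
  if (any(sigma_host < 1) || any(sigma_guest < 1))
    stop("symmetry numbers must be >= 1")
  mcc_constants$R * log(sigma_host / sigma_guest)
}

#' Assign dihedral frames to adaptive conformer states
#'
#' Builds a periodic histogram of the angle series with the given bin width
#' and takes local maxima (strict against both circular neighbours) as
#' conformer peaks; plateaus collapse to their lowest-angle bin, and a flat
#' histogram yields a single peak at the lowest-angle maximum-count bin.
#' Each frame is assigned to the nearest peak by circular distance (ties go
#' to the lower-angle peak).
#'
#' @param angles numeric vector of dihedral angles (degrees, any wrap)
#' @param bin_width histogram bin width in degrees; must divide 360
#' @return list with `labels` (integer peak index per frame), `peaks`
#'   (peak bin centres, degrees) and `counts` (histogram)
#' @export
assign_conformers <- function(angles, bin_width = 30) {
  if (!length(angles)) stop("empty dihedral series")
  if (360 %% bin_width != 0) stop("bin width must divide 360 degrees")
  nb <- as.integer(360 / bin_width)
  a <- angles %% 360
  bin <- pmin(floor(a / bin_width) + 1L, nb)
  counts <- tabulate(bin, nbins = nb)

  # collapse circular runs of equal counts, then mark runs that beat both
  # neighbouring runs; degenerate all-equal histogram -> single peak
  if (length(unique(counts)) == 1L) {
    peak_bins <- 1L
  } else {
    # rotate so the sequence starts at a change point: no run wraps
    prev_of <- c(nb, seq_len(nb - 1L))
    b0 <- which(counts != counts[prev_of])[1]
    rot <- counts[((b0 - 1L) + seq_len(nb) - 1L) %% nb + 1L]
    r <- rle(rot)
    nr <- length(r$values)
    starts <- cumsum(c(1L, r$lengths[-nr]))
    peak_bins <- integer(0)
    for (i in seq_len(nr)) {
      prev <- r$values[if (i == 1L) nr else i - 1L]
      nxt <- r$values[if (i == nr) 1L else i + 1L]
      if (r$values[i] > prev && r$values[i] > nxt) {
        run_bins <- ((b0 - 1L) + (starts[i] - 1L) + seq_len(r$lengths[i]) -
                       1L) %% nb + 1L
        peak_bins <- c(peak_bins, min(run_bins))
      }
    }
    if (!length(peak_bins))
      peak_bins <- min(which(counts == max(counts)))
  }
  peak_bins <- sort(unique(peak_bins))
  peaks <- (peak_bins - 0.5) * bin_width

  dmat <- outer(a, peaks, function(x, p) {
    d <- abs(x - p) %% 360
    pmin(d, 360 - d)
  })
  labels <- max.col(-dmat, ties.method = "first")
  list(labels = labels, peaks = peaks, counts = counts)
}

#' Conformational entropy from joint dihedral states
#'
#' Each frame's conformer is the tuple of per-dihedral peak labels; the
#' Gibbs-Shannon entropy `S = -kB sum p_i ln p_i` is evaluated on the
#' empirical joint distribution. A per-dihedral marginal sum is available
#' as a diagnostic upper bound.
#'
#' @param label_series list of equal-length integer label vectors (one per
#'   heavy-atom dihedral), e.g. the `labels` from [assign_conformers()];
#'   a single vector is treated as one dihedral
#' @param marginal if `TRUE`, return the sum of per-dihedral marginal
#'   entropies instead of the joint entropy
#' @return entropy, J K^-1 mol^-1 (0 for a molecule with no dihedrals)
#' @export
conformational_entropy <- function(label_series, marginal = FALSE) {
  if (is.numeric(label_series) || is.integer(label_series))
    label_series <- list(label_series)
  if (!length(label_series)) return(0)
  lens <- lengths(label_series)
  if (length(unique(lens)) != 1L)
    stop("dihedral label series have mismatched frame counts")
  shannon <- function(labels) {
    p <- table(labels) / length(labels)
    -mcc_constants$R * sum(p * log(p))
  }
  if (marginal) return(sum(vapply(label_series, shannon, 0)))
  joint <- do.call(paste, c(label_series, sep = "|"))
  shannon(joint)
}

#' Empirical conformer distribution
#'
#' @inheritParams conformational_entropy
#' @return data.frame with `conformer` (joint label) and `p` (probability,
#'   summing to 1)
#' @export
conformer_distribution <- function(label_series) {
  if (is.numeric(label_series) || is.integer(label_series))
    label_series <- list(label_series)
  joint <- do.call(paste, c(label_series, sep = "|"))
  tab <- table(joint)
  data.frame(conformer = names(tab), p = as.numeric(tab) / length(joint),
             row.names = NULL)
}

#' Protonation-state entropy correction to binding
#'
#' A guest that is half protonated free in solution but fully protonated
#' when bound contributes an entropy change of `-0.5 kB ln 2` on binding
#' (half the population gives up its two-state freedom). Only the
#' half-to-full shift and the no-shift cases are supported; a general
#' mixture formula is deliberately not attempted.
#'
#' @param fraction_unbound,fraction_bound protonated fractions in `[0, 1]`
#' @return entropy change on binding, J K^-1 mol^-1
#' @export
protonation_correction <- function(fraction_unbound, fraction_bound) {
  if (fraction_unbound < 0 || fraction_unbound > 1 ||
      fraction_bound < 0 || fraction_bound > 1)
    stop("protonated fractions must be in [0, 1]")
  if (fraction_unbound == fraction_bound) return(0)
  if (fraction_unbound == 0.5 && fraction_bound == 1)
    return(-0.5 * mcc_constants$R * log(2))
  stop("unsupported protonation shift: only the half-to-full case ",
       "(0.5 -> 1.0) and the null case are defined")
}

#' Heavy-atom dihedral definitions of a molecule
#'
#' Enumerates rotatable heavy-atom bonds b-c (both ends bonded to at least
#' one further heavy atom) and forms one quadruple a-b-c-d per bond, taking
#' the lowest-id heavy neighbour at each end.
#'
#' @param topology an [mcc_topology()]
#' @param molecule molecule instance name
#' @return list of length-4 integer atom-id vectors (possibly empty)
#' @export
dihedral_definitions <- function(topology, molecule) {
  ids <- molecule_atoms(topology, molecule)
  heavy <- ids[topology$atoms$element[ids] != "H"]
  b <- topology$bonds
  hb <- b[b[, 1] %in% heavy & b[, 2] %in% heavy, , drop = FALSE]
  nbrs <- function(x) sort(c(hb[hb[, 1] == x, 2], hb[hb[, 2] == x, 1]))
  out <- list()
  for (k in seq_len(nrow(hb))) {
    bb <- hb[k, 1]; cc <- hb[k, 2]
    a <- setdiff(nbrs(bb), cc)
    d <- setdiff(nbrs(cc), bb)
    if (length(a) && length(d))
      out[[length(out) + 1L]] <- c(min(a), bb, cc, min(d))
  }
  out
}

#' Dihedral angle time series for a molecule
#'
#' @param system an `mcc_system`
#' @param molecule molecule instance name
#' @param quadruples optional list of length-4 atom-id vectors overriding
#'   [dihedral_definitions()]
#' @return list of numeric angle vectors (degrees on `[0, 360)`), one per
#'   dihedral; empty list when the molecule has no rotatable heavy-atom
#'   dihedral
#' @export
dihedral_series <- function(system, molecule, quadruples = NULL) {
  quadruples <- quadruples %||%
    dihedral_definitions(system$topology, molecule)
  nf <- n_frames(system$trajectory)
  lapply(quadruples, function(q) {
    vapply(seq_len(nf), function(f) {
      box <- if (!is.null(system$trajectory$box)) system$trajectory$box[f, ]
      p <- unwrap_coords(matrix(system$trajectory$coords[f, q, ], ncol = 3),
                         box)
      dihedral_angle(p)
    }, 0)
  })
}
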