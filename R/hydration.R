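#' First hydration shells by relative angular distance and Eq.-of-balance
#' water bookkeeping

#' RAD neighbour set of one site
#'
#' Parameter-free coordination criterion: candidates are sorted by
#' (minimum-image) distance from the centre and accepted greedily; a
#' candidate j is blocked when some closer accepted neighbour k satisfies
#' `(1/r_ij)^2 < (1/r_ik)^2 cos(theta_jik)`, with `theta_jik` the angle at
#' the centre between j and k. Being a pure inequality between distances
#' and angles, the shell is invariant under uniform rescaling of all
#' coordinates.
#'
#' @param center length-3 coordinates of the central site (Angstrom)
#' @param candidates m x 3 matrix of candidate site coordinates
#' @param box length-3 orthorhombic box (Angstrom) or `NULL`
#' @return integer vector of accepted candidate row indices, in order of
#'   increasing distance
#' @export
rad_neighbors <- function(center, candidates, box = NULL) {
  candidates <- matrix(candidates, ncol = 3)
  if (!nrow(candidates)) stop("need at least one candidate site")
  d <- minimum_image(sweep(candidates, 2, center), box)
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-8)) stop("coincident positions")
  ord <- order(r)
  accepted <- integer(0)
  for (j in ord) {
    blocked <- FALSE
    for (k in accepted) {
      cos_jik <- sum(d[j, ] * d[k, ]) / (r[j] * r[k])
      if (1 / r[j]^2 < cos_jik / r[k]^2) { blocked <- TRUE; break }
    }
    if (!blocked) accepted <- c(accepted, j)
  }
  accepted
}

# water oxygen site (heaviest atom of the molecule) and solute heavy sites
.water_oxygens <- function(topology) {
  waters <- molecules_by_role(topology, "water")
  vapply(waters, function(w) {
    ids <- molecule_atoms(topology, w)
    ids[which.max(topology$atoms$mass[ids])]
  }, 0L)
}

#' First-shell waters of a solute over a trajectory
#'
#' Sites are water oxygens and solute heavy atoms. A water belongs to the
#' first shell when at least one solute site appears in the water's RAD
#' neighbour set. Shell membership fluctuates per frame; the reported
#' `n_ws` is the trajectory mean (fractional). When several solute
#' molecules are given (a host-guest complex), each shell water is
#' attributed to the solute owning its nearest heavy atom, ties going to
#' the first solute listed (the host).
#'
#' @param system an `mcc_system` containing water molecules
#' @param solutes character vector of solute molecule names (host first for
#'   a complex)
#' @param frames frame indices to analyse (default all)
#' @return object of class `mcc_shell`: list with `per_frame` (list of
#'   shell water names), `n_ws` (mean count), `n_ws_by_solute` (named mean
#'   counts), `mean_coordination` (mean RAD coordination of shell waters),
#'   `coordination_by_water` (named means)
#' @export
first_shell_waters <- function(system, solutes, frames = NULL) {
  top <- system$topology
  traj <- system$trajectory
  waters <- molecules_by_role(top, "water")
  if (!length(waters)) stop("no water molecules in system")
  stopifnot(all(solutes %in% top$molecules$name))
  frames <- frames %||% seq_len(n_frames(traj))
  w_ox <- .water_oxygens(top)
  solute_sites <- lapply(solutes, function(s) {
    ids <- molecule_atoms(top, s)
    ids[top$atoms$element[ids] != "H"]
  })
  sol_ids <- unlist(solute_sites)
  sol_owner <- rep(solutes, lengths(solute_sites))

  per_frame <- vector("list", length(frames))
  split_counts <- matrix(0, length(frames), length(solutes),
                         dimnames = list(NULL, solutes))
  coord_sum <- setNames(numeric(length(waters)), waters)
  coord_n <- setNames(numeric(length(waters)), waters)
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    box <- if (!is.null(traj$box)) traj$box[f, ]
    ox_xyz <- matrix(traj$coords[f, w_ox, ], ncol = 3)
    sol_xyz <- matrix(traj$coords[f, sol_ids, ], ncol = 3)
    shell <- character(0)
    for (wi in seq_along(waters)) {
      cand <- rbind(ox_xyz[-wi, , drop = FALSE], sol_xyz)
      acc <- rad_neighbors(ox_xyz[wi, ], cand, box)
      n_other_w <- length(waters) - 1L
      sol_hit <- acc[acc > n_other_w]
      coord_sum[wi] <- coord_sum[wi] + length(acc)
      coord_n[wi] <- coord_n[wi] + 1
      if (length(sol_hit)) {
        shell <- c(shell, waters[wi])
        dsol <- minimum_image(sweep(sol_xyz, 2, ox_xyz[wi, ]), box)
        owner <- sol_owner[which.min(rowSums(dsol^2))]
        split_counts[fi, owner] <- split_counts[fi, owner] + 1
      }
    }
    per_frame[[fi]] <- shell
  }
  shell_waters <- unique(unlist(per_frame))
  shell_coord <- coord_sum[shell_waters] / pmax(coord_n[shell_waters], 1)
  structure(list(
    per_frame = per_frame,
    n_ws = mean(lengths(per_frame)),
    n_ws_by_solute = colMeans(split_counts),
    mean_coordination = if (length(shell_waters)) mean(shell_coord) else NA_real_,
    coordination_by_water = coord_sum / pmax(coord_n, 1),
    solutes = solutes, frames = frames
  ), class = "mcc_shell")
}

#' @export
print.mcc_shell <- function(x, ...) {
  cat("First hydration shell of", paste(x$solutes, collapse = "+"),
      ": mean N_WS =", round(x$n_ws, 2), "over", length(x$per_frame),
      "frames\n")
  invisible(x)
}

#' Stoichiometric water bookkeeping for binding
#'
#' The released-to-bulk count balances the shells exactly:
#' `N_WB = N_WS,H + N_WS,G - N_WS,H-G`, partitioned into host-released
#' `N_WS,H - (host part of the complex shell)` and guest-released
#' `N_WS,G - (guest part)`. A negative partition (shell growth on binding)
#' is flagged with a warning and clamped to zero in the report fields while
#' the raw values are retained.
#'
#' @param n_ws_host,n_ws_guest mean first-shell counts of the unbound host
#'   and guest
#' @param n_ws_complex_host,n_ws_complex_guest host/guest parts of the
#'   complex's first shell
#' @return object of class `mcc_bookkeeping` with fields `n_ws_host`,
#'   `n_ws_guest`, `n_ws_complex`, `n_wb`, `released_host`,
#'   `released_guest`
#' @export
water_bookkeeping <- function(n_ws_host, n_ws_guest,
                              n_ws_complex_host, n_ws_complex_guest) {
  vals <- c(n_ws_host, n_ws_guest, n_ws_complex_host, n_ws_complex_guest)
  if (any(vals < 0)) stop("shell counts must be non-negative")
  rel_h <- n_ws_host - n_ws_complex_host
  rel_g <- n_ws_guest - n_ws_complex_guest
  if (rel_h < 0 || rel_g < 0) {
    warning("negative released-water count (shell grows on binding); clamped")
    rel_h <- max(rel_h, 0)
    rel_g <- max(rel_g, 0)
  }
  structure(list(
    n_ws_host = n_ws_host, n_ws_guest = n_ws_guest,
    n_ws_complex = n_ws_complex_host + n_ws_complex_guest,
    n_ws_complex_host = n_ws_complex_host,
    n_ws_complex_guest = n_ws_complex_guest,
    n_wb = rel_h + rel_g,
    released_host = rel_h, released_guest = rel_g
  ), class = "mcc_bookkeeping")
}

#' @export
print.mcc_bookkeeping <- function(x, ...) {
  cat(sprintf(
    "Water bookkeeping: N_WS,H=%.1f N_WS,G=%.1f N_WS,H-G=%.1f -> N_WB=%.1f (host %.1f, guest %.1f)\n",
    x$n_ws_host, x$n_ws_guest, x$n_ws_complex, x$n_wb,
    x$released_host, x$released_guest))
  invisible(x)
}

# pooled molecule-level weighted force/torque rows over (water, frame)
# samples; each sample is expressed in that water's own principal frame
.water_mlevel_rows <- function(system, include) {
  top <- system$topology
  traj <- system$trajectory
  waters <- molecules_by_role(top, "water")
  half <- if (system$config$halving == "halved") 0.5 else 1
  trans <- list(); rot <- list()
  for (f in seq_len(n_frames(traj))) {
    box <- if (!is.null(traj$box)) traj$box[f, ]
    for (w in waters) {
      if (!include(w, f)) next
      ids <- molecule_atoms(top, w)
      m <- top$atoms$mass[ids]
      xyz <- unwrap_coords(matrix(traj$coords[f, ids, ], ncol = 3), box)
      pf <- principal_frame(xyz, m)
      Fat <- matrix(traj$forces[f, ids, ], ncol = 3)
      Fnet <- colSums(Fat)
      trans[[length(trans) + 1L]] <-
        drop(pf$axes %*% Fnet) * half / sqrt(sum(m))
      rel <- sweep(xyz, 2, pf$origin)
      tau <- c(sum(rel[, 2] * Fat[, 3] - rel[, 3] * Fat[, 2]),
               sum(rel[, 3] * Fat[, 1] - rel[, 1] * Fat[, 3]),
               sum(rel[, 1] * Fat[, 2] - rel[, 2] * Fat[, 1]))
      rot[[length(rot) + 1L]] <-
        drop(pf$axes %*% tau) * half / sqrt(pf$moments)
    }
  }
  if (length(trans) < 2L)
    stop("need at least 2 (water, frame) samples for water covariance")
  list(trans = do.call(rbind, trans) * .u$force / sqrt(.u$mass),
       rot = do.call(rbind, rot) * .u$torque / sqrt(.u$moi))
}

#' Per-water entropy components of a water population
#'
#' Pools molecule-level weighted forces and torques over all (water, frame)
#' samples of the selected population (shell-resident waters of a solute,
#' or every water of a bulk simulation) into 3 x 3 covariance matrices, and
#' evaluates the orientational term from the mean RAD coordination with the
#' water symmetry number (2) and hydrogen-bond correlation factor.
#'
#' @param system an `mcc_system`
#' @param shell an `mcc_shell` restricting the population to shell-resident
#'   (water, frame) pairs, or `NULL` for all waters (bulk reference)
#' @return list with per-water `transvib`, `rovib`, `orientational`
#'   (J K^-1 mol^-1) and `n_c` (mean coordination used)
#' @export
water_entropy_components <- function(system, shell = NULL) {
  T_ <- system$config$temperature
  if (is.null(shell)) {
    include <- function(w, f) TRUE
    # bulk coordination: mean RAD count over all waters
    sh <- first_shell_waters_bulk(system)
    n_c <- sh
  } else {
    frames <- shell$frames
    include <- function(w, f) {
      fi <- match(f, frames)
      !is.na(fi) && w %in% shell$per_frame[[fi]]
    }
    n_c <- shell$mean_coordination
  }
  rows <- .water_mlevel_rows(system, include)
  s_t <- qho_entropy(frequencies_from_eigenvalues(cov(rows$trans), T_), T_)
  s_r <- qho_entropy(frequencies_from_eigenvalues(cov(rows$rot), T_), T_)
  s_o <- orientational_entropy_solution(n_c, sigma = 2,
                                        p_corr = system$config$p_corr_water)
  list(transvib = s_t, rovib = s_r, orientational = s_o, n_c = n_c)
}

# mean RAD coordination over all waters of a (pure-water) system
first_shell_waters_bulk <- function(system) {
  top <- system$topology
  traj <- system$trajectory
  waters <- molecules_by_role(top, "water")
  if (length(waters) < 2L) stop("bulk coordination needs >= 2 waters")
  w_ox <- .water_oxygens(top)
  total <- 0; n <- 0
  for (f in seq_len(n_frames(traj))) {
    box <- if (!is.null(traj$box)) traj$box[f, ]
    ox_xyz <- matrix(traj$coords[f, w_ox, ], ncol = 3)
    for (wi in seq_along(waters)) {
      acc <- rad_neighbors(ox_xyz[wi, ], ox_xyz[-wi, , drop = FALSE], box)
      total <- total + length(acc)
      n <- n + 1
    }
  }
  total / n
}

#' Water entropy totals by category (shell vs released)
#'
#' Multiplies per-water entropy components by the category water counts:
#' shell-water (WS) totals use the shell population of this system's
#' trajectory, released-to-bulk (WB) totals use the bulk-water reference
#' components from the pure-water simulation.
#'
#' @param shell_components per-water components of the shell population
#'   (list with `transvib`, `rovib`, `orientational`), from
#'   [water_entropy_components()]
#' @param bulk_components per-water components of the bulk reference; must
#'   be supplied whenever `n_wb > 0`
#' @param n_ws,n_wb mean shell and released water counts
#' @return data.frame with columns `category` (WS/WB), `component`,
#'   `per_water`, `n_water`, `total` (J K^-1 mol^-1)
#' @export
water_entropy_by_category <- function(shell_components, bulk_components,
                                      n_ws, n_wb) {
  stopifnot(n_ws >= 0, n_wb >= 0)
  if (n_wb > 0 && is.null(bulk_components))
    stop("missing bulk-water reference components")
  comp_names <- c("transvib", "rovib", "orientational")
  rows <- list()
  for (cn in comp_names) {
    rows[[length(rows) + 1L]] <- data.frame(
      category = "WS", component = cn,
      per_water = shell_components[[cn]], n_water = n_ws,
      total = shell_components[[cn]] * n_ws)
  }
  if (n_wb > 0) {
    for (cn in comp_names) {
      rows[[length(rows) + 1L]] <- data.frame(
        category = "WB", component = cn,
        per_water = bulk_components[[cn]], n_water = n_wb,
        total = bulk_components[[cn]] * n_wb)
    }
  }
  do.call(rbind, rows)
}
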