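#' Assembly of entropies and energies into binding free energies

#' Build an entropy ledger
#'
#' One row per entropy component, keyed by species (host, guest, waterWS,
#' waterWB), level (molecule, united_atom), motion (translation, rotation)
#' and minima term (vibrational, topographical). The system entropy is the
#' plain sum of all components.
#'
#' @param species,level,motion,minima character vectors (recycled)
#' @param value entropy values, J K^-1 mol^-1
#' @return data.frame of class `mcc_ledger`
#' @export
entropy_ledger <- function(species, level, motion, minima, value) {
  df <- data.frame(species = species, level = level, motion = motion,
                   minima = minima, value = value,
                   stringsAsFactors = FALSE)
  ok <- list(species = c("host", "guest", "waterWS", "waterWB", "water"),
             level = c("molecule", "united_atom"),
             motion = c("translation", "rotation"),
             minima = c("vibrational", "topographical"))
  for (col in names(ok))
    if (!all(df[[col]] %in% ok[[col]]))
      stop("invalid ", col, " label in ledger")
  key <- do.call(paste, df[c("species", "level", "motion", "minima")])
  if (anyDuplicated(key))
    stop("duplicate (species, level, motion, minima) key in ledger")
  class(df) <- c("mcc_ledger", "data.frame")
  df
}

#' Total entropy of a ledger
#'
#' @param ledger an [entropy_ledger()] (an empty ledger sums to 0)
#' @return entropy, J K^-1 mol^-1
#' @export
total_entropy <- function(ledger) {
  if (!nrow(ledger)) return(0)
  key <- do.call(paste, ledger[c("species", "level", "motion", "minima")])
  if (anyDuplicated(key)) stop("duplicate key in ledger")
  sum(ledger$value)
}

#' Per-replicate system free energy
#'
#' `G = E - T S` with the enthalpy approximated by the mean system energy
#' (pressure-volume work omitted, H ~ E).
#'
#' @param energy mean system energy, kcal mol^-1
#' @param entropy total entropy, J K^-1 mol^-1
#' @param temperature temperature, K
#' @param replicate replicate label
#' @return object of class `mcc_free_energy`: list with `E`, `S`, `T`,
#'   `TS` and `G` (kcal mol^-1)
#' @export
system_free_energy <- function(energy, entropy, temperature = 300,
                               replicate = NA_character_) {
  TS <- temperature * entropy / mcc_constants$kcal
  structure(list(E = energy, S = entropy, T = temperature, TS = TS,
                 G = energy - TS, replicate = replicate),
            class = "mcc_free_energy")
}

#' @export
print.mcc_free_energy <- function(x, ...) {
  cat(sprintf("G = %.2f kcal/mol (E = %.2f, TS = %.2f, T = %g K)\n",
              x$G, x$E, x$TS, x$T))
  invisible(x)
}

#' Standard binding free energy from four simulations
#'
#' `dG_bind = (G_complex + G_water) - (G_host + G_guest)`, with the guest
#' at standard state and `G_water` counting the released bulk waters. The
#' same combination of the energy and entropy fields yields `dH` and
#' `T dS`.
#'
#' @param complex,water,host,guest [system_free_energy()] objects from the
#'   same replicate group
#' @return list with `dG`, `dH`, `TdS` (kcal mol^-1)
#' @export
binding_free_energy <- function(complex, water, host, guest) {
  comps <- list(complex, water, host, guest)
  stopifnot(all(vapply(comps, inherits, TRUE, "mcc_free_energy")))
  dG <- (complex$G + water$G) - (host$G + guest$G)
  dH <- (complex$E + water$E) - (host$E + guest$E)
  TdS <- (complex$TS + water$TS) - (host$TS + guest$TS)
  list(dG = dG, dH = dH, TdS = TdS)
}

#' Standard error of the mean over replicates
#'
#' Sample standard deviation divided by `sqrt(n)`; simulations here are run
#' in triplicate so typically `n = 3`.
#'
#' @param values per-replicate values (n >= 2)
#' @return SEM
#' @export
sem <- function(values) {
  if (length(values) < 2L) stop("SEM needs at least 2 replicates")
  sd(values) / sqrt(length(values))
}

#' Mean absolute error versus experiment
#'
#' @param predicted,experimental equal-length paired numeric vectors
#' @return mean of `|predicted - experimental|`
#' @export
mae <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental lists differ in length")
  mean(abs(predicted - experimental))
}

#' Energy drift of a simulation
#'
#' Ordinary least-squares line of energy versus time, as a convergence
#' diagnostic. The slope is reported per ns (input times in ps).
#'
#' @param series data.frame with `time` (ps) and `energy` columns, or a
#'   path readable by [read_energy_series()]
#' @return list with `slope` (energy per ns), `intercept`, `slope_se`
#'   (per ns)
#' @export
energy_drift <- function(series) {
  if (is.character(series)) series <- read_energy_series(series)
  if (nrow(series) < 3L) stop("energy drift needs at least 3 points")
  if (sd(series$time) == 0) stop("constant time column")
  fit <- lm(energy ~ time, data = series)
  co <- summary(fit)$coefficients
  list(slope = co["time", "Estimate"] * 1000,
       intercept = co["(Intercept)", "Estimate"],
       slope_se = co["time", "Std. Error"] * 1000)
}

#' Pool replicate binding samples into a binding result
#'
#' Pairs replicate r of each of the four systems into one binding sample
#' and reports means with SEMs over the replicates.
#'
#' @param samples list of [binding_free_energy()] outputs (one per
#'   replicate)
#' @param guest guest label
#' @param expt optional list/vector with experimental `dG`, `dH`, `TdS`
#' @param protonation_TdS optional additive `T dS` correction in
#'   kcal mol^-1 (e.g. a protonation-state shift); applied to `TdS` and
#'   `dG`
#' @return object of class `mcc_binding_result`
#' @export
binding_result <- function(samples, guest = "guest", expt = NULL,
                           protonation_TdS = 0) {
  dH <- vapply(samples, `[[`, 0, "dH")
  TdS <- vapply(samples, `[[`, 0, "TdS") + protonation_TdS
  dG <- dH - TdS
  out <- list(
    guest = guest,
    dG = mean(dG), dG_sem = if (length(dG) > 1) sem(dG) else NA_real_,
    dH = mean(dH), dH_sem = if (length(dH) > 1) sem(dH) else NA_real_,
    TdS = mean(TdS), TdS_sem = if (length(TdS) > 1) sem(TdS) else NA_real_,
    expt = expt, n_replicates = length(samples)
  )
  structure(out, class = "mcc_binding_result")
}

#' @export
print.mcc_binding_result <- function(x, ...) {
  cat(sprintf("%s: dG = %.1f +/- %.1f, dH = %.1f, TdS = %.1f kcal/mol\n",
              x$guest, x$dG, x$dG_sem, x$dH, x$TdS))
  invisible(x)
}

#' Entropy ledger of one solute molecule in one simulation
#'
#' Runs the full multiscale decomposition for a host or guest molecule:
#' molecule-level and united-atom-level vibrational terms (translation and
#' rotation), the positional term from the standard-state mole fraction,
#' the orientational term (first-shell coordination for an unbound solute,
#' symmetry-number ratio for a bound guest), and the conformational term
#' from joint dihedral states.
#'
#' @param system an `mcc_system`
#' @param molecule solute molecule name
#' @param species ledger species label ("host" or "guest")
#' @param bound `TRUE` for a solute inside a complex
#' @param shell optional precomputed [first_shell_waters()] result for the
#'   orientational coordination number (computed on demand when waters are
#'   present)
#' @param sigma_host host symmetry number (bound orientational term)
#' @param frame_atoms optional atom ids defining the united-atom reference
#'   frame (the whole complex for a bound host)
#' @param x_aq mole fraction for the positional term; defaults to the
#'   config standard-state value for an unbound solute. Positional and
#'   orientational molecule terms of a bound guest use the complex
#'   reference (positional 0, orientational from symmetry numbers); for a
#'   host both are taken as unchanged by binding (it defines the reference
#'   frame) and reported only for the unbound state.
#' @return an [entropy_ledger()]
#' @export
solute_entropy_ledger <- function(system, molecule, species = "guest",
                                  bound = FALSE, shell = NULL,
                                  sigma_host = NULL, frame_atoms = NULL,
                                  x_aq = NULL) {
  cfg <- system$config
  top <- system$topology
  sigma <- top$molecules$symmetry[top$molecules$name == molecule]

  s_mt <- vibrational_entropy(system, molecule, "molecule", "translation",
                              frame_atoms = NULL)
  s_mr <- vibrational_entropy(system, molecule, "molecule", "rotation")
  s_ut <- vibrational_entropy(system, molecule, "united_atom", "translation",
                              frame_atoms = frame_atoms)
  uas <- define_united_atoms(top, molecule)
  rot_uas <- Filter(function(u) u$rotational_dof > 0L, uas)
  s_ur <- if (length(rot_uas))
    vibrational_entropy(system, molecule, "united_atom", "rotation",
                        units = rot_uas, frame_atoms = frame_atoms)
  else 0

  if (species == "host") {
    # the host defines the reference frame of binding: its positional and
    # orientational entropy is taken as unchanged and carried in neither
    # state's ledger
    s_pos <- NA_real_
    s_or <- NA_real_
  } else if (bound) {
    s_pos <- 0
    s_or <- orientational_entropy_bound(sigma_host %||% 1, sigma)
  } else {
    s_pos <- positional_entropy(x_aq %||% cfg$x_standard)
    n_c <- if (!is.null(shell)) shell$n_ws
    else if (length(molecules_by_role(top, "water")) > 0)
      first_shell_waters(system, molecule)$n_ws
    else NA_real_
    s_or <- if (is.na(n_c) || n_c <= 0) NA_real_
    else orientational_entropy_solution(n_c, sigma = sigma, p_corr = 1)
  }

  dh <- dihedral_series(system, molecule)
  s_conf <- if (length(dh))
    conformational_entropy(lapply(dh, function(a) assign_conformers(a)$labels))
  else 0

  led <- entropy_ledger(
    species = species,
    level = c("molecule", "molecule", "united_atom", "united_atom",
              "molecule", "molecule", "united_atom"),
    motion = c("translation", "rotation", "translation", "rotation",
               "translation", "rotation", "translation"),
    minima = c(rep("vibrational", 4), rep("topographical", 3)),
    value = c(s_mt, s_mr, s_ut, s_ur, s_pos, s_or, s_conf)
  )
  led[!is.na(led$value), ]
}

.comp_key <- c(transvib = "vibrational translation",
               rovib = "vibrational rotation")

#' Write report tables
#'
#' Emits three delimited text files mirroring the standard presentation:
#' `binding.tsv` (per guest dG/dH/TdS with SEMs and experiment, one decimal
#' kcal mol^-1), `entropy_components.tsv` (ledger rows, integer
#' J K^-1 mol^-1) and `water_bookkeeping.tsv` (shell/released counts, one
#' decimal).
#'
#' @param binding_results list of [binding_result()] objects
#' @param ledgers named list of [entropy_ledger()] objects (one per system)
#' @param bookkeeping named list of [water_bookkeeping()] objects
#' @param dir output directory (created if needed)
#' @return invisible character vector of the files written
#' @export
report <- function(binding_results, ledgers = NULL, bookkeeping = NULL,
                   dir = ".") {
  if (!length(binding_results)) stop("no binding results to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  b <- do.call(rbind, lapply(binding_results, function(x) {
    data.frame(guest = x$guest,
               dG = round(x$dG, 1), dG_sem = round(x$dG_sem, 1),
               dH = round(x$dH, 1), dH_sem = round(x$dH_sem, 1),
               TdS = round(x$TdS, 1), TdS_sem = round(x$TdS_sem, 1),
               dG_expt = round(x$expt$dG %||% NA_real_, 1),
               dH_expt = round(x$expt$dH %||% NA_real_, 1),
               TdS_expt = round(x$expt$TdS %||% NA_real_, 1))
  }))
  if (all(!is.na(b$dG_expt))) {
    attr(b, "mae_dG") <- mae(b$dG, b$dG_expt)
  } else {
    message("experimental values missing for some guests; MAE omitted")
  }
  f <- file.path(dir, "binding.tsv")
  write.table(b, f, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(attr(b, "mae_dG")))
    cat(sprintf("# MAE_dG\t%.1f\n", attr(b, "mae_dG")),
        file = f, append = TRUE)
  files <- c(files, f)

  if (!is.null(ledgers)) {
    led <- do.call(rbind, lapply(names(ledgers), function(nm) {
      l <- ledgers[[nm]]
      data.frame(system = nm, l[, c("species", "level", "motion", "minima")],
                 value = round(l$value))
    }))
    f <- file.path(dir, "entropy_components.tsv")
    write.table(led, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  if (!is.null(bookkeeping)) {
    bk <- do.call(rbind, lapply(names(bookkeeping), function(nm) {
      x <- bookkeeping[[nm]]
      data.frame(guest = nm,
                 n_ws_host = round(x$n_ws_host, 1),
                 n_ws_guest = round(x$n_ws_guest, 1),
                 n_ws_complex = round(x$n_ws_complex, 1),
                 n_wb = round(x$n_wb, 1),
                 released_host = round(x$released_host, 1),
                 released_guest = round(x$released_guest, 1))
    }))
    f <- file.path(dir, "water_bookkeeping.tsv")
    write.table(bk, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
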