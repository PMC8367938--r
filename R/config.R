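#' Analysis configuration

#' Construct an analysis configuration
#'
#' @param temperature simulation temperature (K)
#' @param x_standard standard-state aqueous mole fraction of a dilute
#'   solute; 1/55.5 corresponds to 1 M in the 1661 A^3 standard volume
#' @param stride keep every `stride`-th trajectory frame
#' @param halving `"halved"` divides instantaneous forces and torques by two
#'   (mean-field treatment of a unit among weakly correlated neighbours,
#'   the method's default); `"raw"` uses them unmodified, which recovers the
#'   physical frequency of an isolated harmonic unit
#' @param frame_source `"self"` evaluates united-atom terms in the
#'   molecule's own principal frame; `"complex"` uses the frame of the whole
#'   host-guest complex (needed for the bound host so host and guest stay
#'   consistently aligned)
#' @param p_corr_water orientational correlation factor for water
#'   (hydrogen-bond correlation)
#' @param replicates optional character vector of replicate labels
#' @return object of class `mcc_config`
#' @export
mcc_config <- function(temperature = 300, x_standard = 1 / 55.5,
                       stride = 1L, halving = c("halved", "raw"),
                       frame_source = c("self", "complex"),
                       p_corr_water = 0.25, replicates = NULL) {
  halving <- match.arg(halving)
  frame_source <- match.arg(frame_source)
  stopifnot(temperature > 0, x_standard > 0, x_standard <= 1, stride >= 1)
  structure(list(temperature = temperature, x_standard = x_standard,
                 stride = as.integer(stride), halving = halving,
                 frame_source = frame_source, p_corr_water = p_corr_water,
                 replicates = replicates),
            class = "mcc_config")
}

#' Read a configuration (plus molecule roles) from YAML
#'
#' Recognised keys: `temperature`, `stride`, `halving`, `frame_source`,
#' `x_standard`, `replicates`, and `molecules`, a list of
#' `{name, role, symmetry_number}` records mapping residue names to roles
#' and symmetry numbers.
#'
#' @param path YAML file
#' @return list with `config` ([mcc_config()]), `roles` (named character),
#'   `symmetry` (named numeric)
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("temperature", "x_standard", "stride", "halving",
                        "frame_source", "p_corr_water", "replicates"))]
  config <- do.call(mcc_config, args)
  roles <- symmetry <- NULL
  if (!is.null(y$molecules)) {
    roles <- vapply(y$molecules, function(m) m$role %||% "other", "")
    names(roles) <- vapply(y$molecules, `[[`, "", "name")
    symmetry <- vapply(y$molecules,
                       function(m) as.numeric(m$symmetry_number %||% 1), 0)
    names(symmetry) <- names(roles)
  }
  list(config = config, roles = roles, symmetry = symmetry)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
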