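#' Reference data for the SAMPL8 CB8 "Drugs of Abuse" host-guest series
#'
#' Published EE-MCC and experimental binding thermodynamics (kcal mol^-1)
#' and the per-system entropy component tables (J K^-1 mol^-1, integer
#' precision; water counts fractional) for cucurbit[8]uril with guests
#' G1-G7. These serve as worked-example inputs and as consistency fixtures:
#' the binding table satisfies `dG = dH - T dS` to its printed precision
#' and the water counts satisfy the shell stoichiometry identity exactly.
#'
#' @param which `"binding"` (per-guest dG/dH/TdS, calculated and
#'   experimental), `"host"` (entropy components of the unbound host and of
#'   each complex, plus shell/released water counts) or `"guest"` (entropy
#'   components of each guest, unbound and bound)
#' @return data.frame
#' @export
cb8_reference <- function(which = c("binding", "host", "guest")) {
  which <- match.arg(which)
  file <- switch(which,
                 binding = "cb8_binding.tsv",
                 host = "cb8_host_entropy.tsv",
                 guest = "cb8_guest_entropy.tsv")
  path <- system.file("extdata", file, package = "eemcc", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Host-system entropy subtotals from a component table
#'
#' Helper over the [cb8_reference()] host table: sums the host-molecule
#' components (molecule + united-atom + conformational) and the associated
#' water components of one column, and reports the united-atom share of the
#' host entropy and the host share of the whole-system entropy.
#'
#' @param column column name, e.g. `"H"` for the unbound host system
#' @return list with `host_total`, `water_total`, `system_total`,
#'   `ua_fraction`, `host_fraction` (fractions in 0..1)
#' @export
cb8_host_subtotals <- function(column = "H") {
  tab <- cb8_reference("host")
  val <- function(comp) tab[tab$component == comp, column]
  host_rows <- c("S_HM_transvib", "S_HM_rovib", "S_HUA_transvib",
                 "S_HUA_rovib", "S_H_conf")
  water_rows <- c("S_WS_transvib", "S_WS_rovib", "S_WS_or",
                  "S_WB_transvib", "S_WB_rovib", "S_WB_or")
  host_total <- sum(vapply(host_rows, val, 0))
  water_vals <- vapply(water_rows, val, 0)
  water_total <- sum(water_vals, na.rm = TRUE)
  ua <- val("S_HUA_transvib") + val("S_HUA_rovib")
  list(host_total = host_total, water_total = water_total,
       system_total = host_total + water_total,
       ua_fraction = ua / host_total,
       host_fraction = host_total / (host_total + water_total))
}
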