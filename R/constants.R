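#' Physical constants (CODATA, molar convention)
#'
#' All internal spectroscopy is done in molar SI units: forces in
#' J mol^-1 m^-1, masses in kg mol^-1, torques in J mol^-1, moments of
#' inertia in kg m^2 mol^-1. Entropies come out in J K^-1 mol^-1 directly.
#'
#' @format A list with elements:
#' \describe{
#'   \item{R}{molar gas constant, J K^-1 mol^-1}
#'   \item{NA_}{Avogadro constant, mol^-1}
#'   \item{h}{Planck constant, J s}
#'   \item{h_molar}{`h * NA_`, J s mol^-1 (so `h_molar * nu / (R * T)` is
#'     the dimensionless quantum ratio `h nu / kB T`)}
#'   \item{kcal}{J per kcal (thermochemical, 4184)}
#' }
#' @export
mcc_constants <- list(
  R       = 8.31446261815324,
  NA_     = 6.02214076e23,
  h       = 6.62607015e-34,
  h_molar = 6.62607015e-34 * 6.02214076e23,
  kcal    = 4184
)

# unit conversions from the package's I/O units (Angstrom, kJ mol^-1,
# amu, ps) into molar SI
.u <- list(
  force  = 1e3 * 1e10,   # kJ mol^-1 A^-1  -> J mol^-1 m^-1
  torque = 1e3,          # kJ mol^-1       -> J mol^-1
  mass   = 1e-3,         # amu (g mol^-1)  -> kg mol^-1
  moi    = 1e-3 * 1e-20, # amu A^2         -> kg m^2 mol^-1
  spring = 1e3 * 1e20,   # kJ mol^-1 A^-2  -> J mol^-1 m^-2
  stiff  = 1e3           # kJ mol^-1 rad^-2-> J mol^-1 rad^-2
)

# standard atomic masses (amu) for element inference from coordinate files
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078, Fe = 55.845,
  Zn = 65.38
)
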