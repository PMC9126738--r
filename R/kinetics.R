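#' Rubisco kinetic constant sets
#'
#' A `kinetic_constants` object holds Rubisco kinetics at 25 degC together
#' with Arrhenius activation energies and the chloroplastic O2 partial
#' pressure. All CO2 pressures are in Pa and O2 in kPa; activation energies
#' in J mol-1.
#'
#' @param Kc25 Michaelis constant for carboxylation at 25 degC (Pa).
#' @param Ko25 Michaelis constant for oxygenation at 25 degC (kPa).
#' @param GammaStar25 photorespiratory CO2 compensation point at 25 degC (Pa).
#' @param O chloroplastic O2 partial pressure (kPa), default 21.
#' @param Ea_Kc,Ea_Ko,Ea_GammaStar,Ea_Vcmax,Ea_J,Ea_Rd activation energies
#'   (J mol-1).
#' @param source_label provenance string carried into every numeric output.
#'
#' @return An object of class `kinetic_constants`.
#' @export
kinetic_constants <- function(Kc25, Ko25, GammaStar25, O = 21,
                              Ea_Kc, Ea_Ko, Ea_GammaStar,
                              Ea_Vcmax, Ea_J, Ea_Rd,
                              source_label = "custom") {
  vals <- c(Kc25 = Kc25, Ko25 = Ko25, GammaStar25 = GammaStar25, O = O,
            Ea_Kc = Ea_Kc, Ea_Ko = Ea_Ko, Ea_GammaStar = Ea_GammaStar,
            Ea_Vcmax = Ea_Vcmax, Ea_J = Ea_J, Ea_Rd = Ea_Rd)
  if (any(!is.finite(vals))) stop("all kinetic constants must be finite")
  if (any(vals <= 0)) stop("all pressures and activation energies must be > 0")
  structure(c(as.list(vals), list(source_label = source_label)),
            class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("Rubisco kinetic constant set:", x$source_label, "\n")
  cat(sprintf("  Kc25 = %.3f Pa  Ko25 = %.3f kPa  GammaStar25 = %.4f Pa  O = %.1f kPa\n",
              x$Kc25, x$Ko25, x$GammaStar25, x$O))
  cat(sprintf("  Ea (J/mol): Kc %.0f, Ko %.0f, GammaStar %.0f, Vcmax %.0f, J %.0f, Rd %.0f\n",
              x$Ea_Kc, x$Ea_Ko, x$Ea_GammaStar, x$Ea_Vcmax, x$Ea_J, x$Ea_Rd))
  invisible(x)
}

#' Named kinetic constant sets
#'
#' `wheat_constants()` returns the wheat-derived in vivo set used by default
#' throughout the package (a reconstruction from published wheat
#' temperature-response work; the `source_label` records this).
#' `tobacco_constants()` returns the widely used tobacco-derived in vivo set
#' (Bernacchi-type values, expressed as partial pressures at 101.325 kPa) as
#' an explicit fallback.
#'
#' @param O chloroplastic O2 partial pressure (kPa).
#' @return A `kinetic_constants` object.
#' @export
wheat_constants <- function(O = 21) {
  kinetic_constants(
    Kc25 = 27.0, Ko25 = 16.6, GammaStar25 = 3.66, O = O,
    Ea_Kc = 59356, Ea_Ko = 35948, Ea_GammaStar = 24460,
    Ea_Vcmax = 58550, Ea_J = 29680, Ea_Rd = 66400,
    source_label = "wheat-invivo-reconstruction")
}

#' @rdname wheat_constants
#' @export
tobacco_constants <- function(O = 21) {
  kinetic_constants(
    Kc25 = 40.49, Ko25 = 27.84, GammaStar25 = 4.275, O = O,
    Ea_Kc = 79430, Ea_Ko = 36380, Ea_GammaStar = 37830,
    Ea_Vcmax = 65330, Ea_J = 43540, Ea_Rd = 46390,
    source_label = "tobacco-invivo")
}

#' Load a kinetic constant set from JSON
#'
#' Reads a plain-text JSON object with the fields of [kinetic_constants()].
#'
#' @param path path to a JSON file.
#' @return A `kinetic_constants` object.
#' @export
read_constants <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(kinetic_constants, x)
}

#' Resolve a constant set by name or object
#' @param constants a `kinetic_constants` object or one of "wheat", "tobacco".
#' @keywords internal
resolve_constants <- function(constants) {
  if (inherits(constants, "kinetic_constants")) return(constants)
  switch(match.arg(constants, c("wheat", "tobacco")),
         wheat = wheat_constants(), tobacco = tobacco_constants())
}

GAS_CONSTANT <- 8.314  # J mol-1 K-1

#' Arrhenius temperature correction
#'
#' Scales a rate or kinetic constant from its 25 degC value to a leaf
#' temperature, k(T) = k25 * exp(Ea * (T - 25) / (R * 298.15 * (T + 273.15))).
#' `normalize_to_25()` is the exact inverse (divides by the same factor).
#'
#' @param k25 value at 25 degC (> 0).
#' @param Ea activation energy (J mol-1).
#' @param T_leaf leaf temperature (degC), in (-10, 50).
#' @return The value at `T_leaf` (or at 25 degC for `normalize_to_25`).
#' @export
arrhenius_correct <- function(k25, Ea, T_leaf) {
  if (any(!is.finite(k25)) || any(!is.finite(Ea)) || any(!is.finite(T_leaf)))
    stop("non-finite inputs to arrhenius_correct")
  if (any(k25 <= 0)) stop("k25 must be > 0")
  if (any(T_leaf <= -10 | T_leaf >= 50)) stop("T_leaf outside (-10, 50) degC")
  k25 * exp(Ea * (T_leaf - 25) / (GAS_CONSTANT * 298.15 * (T_leaf + 273.15)))
}

#' @rdname arrhenius_correct
#' @param kT value at `T_leaf`.
#' @export
normalize_to_25 <- function(kT, Ea, T_leaf) {
  kT / arrhenius_correct(1, Ea, T_leaf)
}

#' Temperature-adjusted kinetics
#'
#' Evaluates Kc, Ko, GammaStar and the effective Michaelis constant
#' Km = Kc * (1 + O/Ko) at a leaf temperature.
#'
#' @param k a `kinetic_constants` object.
#' @param T_leaf leaf temperature (degC).
#' @return A list with `Kc` (Pa), `Ko` (kPa), `GammaStar` (Pa), `Km` (Pa).
#' @export
kinetics_at <- function(k, T_leaf) {
  Kc <- arrhenius_correct(k$Kc25, k$Ea_Kc, T_leaf)
  Ko <- arrhenius_correct(k$Ko25, k$Ea_Ko, T_leaf)
  GammaStar <- arrhenius_correct(k$GammaStar25, k$Ea_GammaStar, T_leaf)
  list(Kc = Kc, Ko = Ko, GammaStar = GammaStar, Km = Kc * (1 + k$O / Ko))
}
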