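# Physical constants and unit conventions.
#
# Internal units: length Angstrom, energy kcal/mol, mass g/mol (amu),
# charge elementary charge.  The derived time unit is
# sqrt(amu * A^2 / (kcal/mol)) = 48.8882 fs, the usual Amber-class
# convention; MD configs take femtoseconds and convert internally.

#' @keywords internal
KB_KCAL <- 0.0019872041 # Boltzmann constant, kcal/mol/K

#' @keywords internal
COULOMB_KCAL <- 332.0637128 # kcal*A/(mol*e^2)

#' @keywords internal
TIME_UNIT_FS <- 48.8882129 # fs per internal time unit

# number density of liquid water at 0.997 g/cm^3, molecules per A^3
#' @keywords internal
WATER_NUMBER_DENSITY <- 0.997 / 18.01528 * 6.02214076e23 * 1e-24
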