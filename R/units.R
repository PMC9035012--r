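#' Unit conventions
#'
#' All quantities in this package use the GROMOS unit system: length in nm,
#' time in ps, energy in kJ/mol, mass in u (g/mol), temperature in K.
#' Velocities are nm/ps, forces kJ mol^-1 nm^-1.
#'
#' @return A named list describing the unit system, including the Boltzmann
#'   constant `kB` = 0.00831451 kJ mol^-1 K^-1.
#' @export
#' @examples
#' unit_system()$kB
unit_system <- function() {
  list(length = "nm", time = "ps", energy = "kJ/mol", mass = "u",
       temperature = "K", kB = 0.00831451)
}

#' Boltzmann constant in kJ mol^-1 K^-1
#' @export
KB <- 0.00831451

# standard masses (u) by element / united-atom type
.element_mass <- c(H = 1.008, C = 12.011, N = 14.0067, O = 15.9994,
                   S = 32.06, P = 30.9738)

.united_mass <- c(CH1 = 13.019, CR1 = 13.019, CH2 = 14.027, CH2r = 14.027,
                  CH3 = 15.035, CH4 = 16.043)

#' Default atomic mass for a SASA atom-type code
#'
#' United-atom CHn types carry the aggregate mass of the carbon plus its
#' implicit hydrogens; all other types use the standard mass of their element.
#'
#' @param sasa_type character vector of type names (e.g. "N", "CH2", "OM")
#' @return numeric vector of masses in u
#' @export
mass_for_type <- function(sasa_type) {
  m <- .united_mass[sasa_type]
  elem <- element_for_type(sasa_type)
  m[is.na(m)] <- .element_mass[elem[is.na(m)]]
  unname(m)
}

#' Element symbol for a SASA atom-type code
#' @param sasa_type character vector of type names
#' @return character vector of element symbols ("X" for dummies)
#' @export
element_for_type <- function(sasa_type) {
  first <- substr(sasa_type, 1, 1)
  elem <- ifelse(sasa_type == "DUM", "X",
          ifelse(first %in% c("O"), "O",
          ifelse(first == "N", "N",
          ifelse(first == "C", "C",
          ifelse(first == "H", "H",
          ifelse(first == "S", "S", "X"))))))
  unname(elem)
}
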