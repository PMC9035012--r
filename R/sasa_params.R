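.implisolv_cache <- new.env(parent = emptyenv())

#' Raw SASA parameter table
#'
#' The packaged table of the 23 GROMOS atom-type codes with Hasel radii
#' `R_i`, reduction parameters `p_i`, and the two solvation weight sets
#' (per-type and three-class sigma, kJ mol^-1 nm^-2).
#'
#' @return data.frame with one row per atom-type code
#' @export
sasa_parameter_table <- function() {
  if (is.null(.implisolv_cache$sasa_table)) {
    path <- system.file("extdata", "sasa_params.tsv", package = "implisolv")
    if (path == "") path <- file.path("inst", "extdata", "sasa_params.tsv")
    .implisolv_cache$sasa_table <- utils::read.delim(
      path, comment.char = "#", stringsAsFactors = FALSE)
  }
  .implisolv_cache$sasa_table
}

#' SASA implicit-solvation parameter set
#'
#' Assembles a parameter set for the implicit-solvation energy term. Two
#' sigma sets ship with the package: `"per-type"` (one weight per atom type;
#' the set used by the implicit-solvation simulations this package models)
#' and `"three-class"` (charged/polar/hydrophobic classes only).
#'
#' @param set `"per-type"` or `"three-class"`
#' @param R_solv solvent probe radius in nm (default 0.14)
#' @param p_first pair reduction factor for covalently bound first neighbours
#' @param p_next pair reduction factor for second covalent neighbours
#' @return object of class `"sasa_params"` with named vectors `R`, `p`,
#'   `sigma` (indexed by type name) and the global probe/pair parameters
#' @export
sasa_params <- function(set = c("per-type", "three-class"),
                        R_solv = 0.14, p_first = 0.8875, p_next = 0.3516) {
  set <- match.arg(set)
  tab <- sasa_parameter_table()
  sigma <- if (set == "per-type") tab$sigma_per_type else tab$sigma_three_class
  stopifnot(R_solv >= 0, p_first > 0, p_first <= 1, p_next > 0, p_next <= 1)
  structure(list(
    set_id = set,
    R = stats::setNames(tab$radius_nm, tab$name),
    p = stats::setNames(tab$p_i, tab$name),
    sigma = stats::setNames(sigma, tab$name),
    surface_class = stats::setNames(tab$surface_class, tab$name),
    R_solv = R_solv, p_first = p_first, p_next = p_next),
    class = "sasa_params")
}

#' @export
print.sasa_params <- function(x, ...) {
  cat(sprintf("SASA parameter set '%s': R_solv = %g nm, p_1 = %g, p_2 = %g\n",
              x$set_id, x$R_solv, x$p_first, x$p_next))
  cat(sprintf("  %d atom types, %d with defined sigma\n",
              length(x$R), sum(!is.na(x$sigma))))
  invisible(x)
}

#' Surface area of an isolated atom
#'
#' The sphere traced by the probe centre: `4 * pi * (R_i + R_solv)^2`.
#'
#' @param type_code atom type name(s), e.g. "O", "CH3"
#' @param params a [sasa_params()] object
#' @return area(s) in nm^2
#' @export
isolated_area <- function(type_code, params = sasa_params()) {
  R <- params$R[type_code]
  if (any(is.na(R)))
    stop("atom type(s) with undefined radius: ",
         paste(unique(type_code[is.na(R)]), collapse = ", "))
  unname(4 * pi * (R + params$R_solv)^2)
}

#' Pairwise overlap reduction factor
#'
#' Area removed from atom i's accessible sphere by an overlapping atom j.
#' Note the expression is asymmetric in (i, j). Zero at and beyond the
#' contact cutoff `R_i + R_j + 2 R_solv`, continuously.
#'
#' @param r_ij interatomic distance(s) in nm, > 0
#' @param type_i,type_j atom type names
#' @param params a [sasa_params()] object
#' @return overlap area(s) in nm^2
#' @export
overlap_reduction <- function(r_ij, type_i, type_j, params = sasa_params()) {
  if (any(r_ij <= 0)) stop("coincident atoms: r_ij must be > 0")
  Ri <- params$R[type_i]; Rj <- params$R[type_j]
  if (any(is.na(Ri)) || any(is.na(Rj)))
    stop("overlap_reduction: atom type with undefined radius")
  cutoff <- Ri + Rj + 2 * params$R_solv
  b <- pi * (Ri + params$R_solv) * (cutoff - r_ij) * (1 + (Rj - Ri) / r_ij)
  unname(ifelse(r_ij >= cutoff, 0, b))
}

# derivative db_ij/dr at distance r (zero at/beyond cutoff)
overlap_reduction_deriv <- function(r_ij, Ri, Rj, R_solv) {
  cutoff <- Ri + Rj + 2 * R_solv
  db <- -pi * (Ri + R_solv) * (1 + (Rj - Ri) / r_ij) +
    pi * (Ri + R_solv) * (-(Rj - Ri) / r_ij^2) * (cutoff - r_ij)
  ifelse(r_ij >= cutoff, 0, db)
}
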