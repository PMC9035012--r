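#' Molecular topology
#'
#' A topology holds the static description of a molecule: atom names,
#' elements, masses, SASA atom-type codes, residue numbering, covalent bonds
#' and the list of constrained bond lengths. Coordinates live separately in a
#' conformation (an n x 3 matrix in nm) or a [trajectory()].
#'
#' @param atoms data.frame with columns `name`, `sasa_type`, `resid`,
#'   `resname`, and optionally `element` and `mass` (filled from the type code
#'   when absent).
#' @param bonds two-column integer matrix of 1-based atom indices (may have
#'   zero rows).
#' @param constraints data.frame with columns `i`, `j`, `length_nm` giving
#'   constrained bond lengths, or NULL.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, bonds = matrix(integer(0), ncol = 2),
                     constraints = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "sasa_type", "resid", "resname")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- element_for_type(atoms$sasa_type)
  if (is.null(atoms$mass)) atoms$mass <- mass_for_type(atoms$sasa_type)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(constraints))
    constraints <- data.frame(i = integer(0), j = integer(0),
                              length_nm = numeric(0))
  top <- structure(list(atoms = atoms, bonds = bonds,
                        constraints = constraints),
                   class = "topology")
  validate_topology(top)
  top
}

#' Validate a topology's invariants
#'
#' Checks positive masses, bond indices referencing existing atoms, and SASA
#' type codes drawn from the packaged parameter table.
#' @param top a topology
#' @return the topology, invisibly; errors on violation
#' @export
validate_topology <- function(top) {
  n <- nrow(top$atoms)
  if (n < 1) stop("topology has no atoms")
  if (any(!is.finite(top$atoms$mass)) || any(top$atoms$mass <= 0))
    stop("all atomic masses must be positive")
  if (nrow(top$bonds) > 0) {
    if (any(top$bonds < 1) || any(top$bonds > n))
      stop("bond references a non-existent atom index")
    if (any(top$bonds[, 1] == top$bonds[, 2]))
      stop("bond connects an atom to itself")
  }
  known <- sasa_parameter_table()$name
  bad <- setdiff(unique(top$atoms$sasa_type), known)
  if (length(bad) > 0)
    stop("unknown SASA atom type code(s): ", paste(bad, collapse = ", "))
  if (nrow(top$constraints) > 0) {
    if (any(top$constraints$i < 1) || any(top$constraints$j > n))
      stop("constraint references a non-existent atom index")
    if (any(top$constraints$length_nm <= 0))
      stop("constraint target lengths must be positive")
  }
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds, %d constraints\n",
              nrow(x$atoms), length(unique(x$atoms$resid)),
              nrow(x$bonds), nrow(x$constraints)))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a topology
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Select atoms with a small selection language
#'
#' The selection mini-language supports `all`, `name <list>` (comma- or
#' space-separated atom names), `resid <a>-<b>` (also single numbers and
#' comma-separated ranges), combinable with `and`. Examples:
#' `"name CA and resid 3-126"`, `"name N,CA,C"`, `"all"`.
#'
#' @param top a topology
#' @param selection selection string
#' @param strict if TRUE (default), an atom name that matches nothing in the
#'   topology is an error naming the offending atom.
#' @return ordered, duplicate-free integer vector of atom indices (possibly
#'   empty)
#' @export
select_atoms <- function(top, selection, strict = TRUE) {
  stopifnot(is.character(selection), length(selection) == 1)
  clauses <- strsplit(trimws(selection), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, n_atoms(top))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (cl == "all") next
    if (grepl("^name\\s+", cl)) {
      nm <- strsplit(sub("^name\\s+", "", cl), "[,\\s]+")[[1]]
      nm <- nm[nzchar(nm)]
      if (strict) {
        absent <- setdiff(nm, top$atoms$name)
        if (length(absent) > 0)
          stop("selection names unknown atom(s): ",
               paste(absent, collapse = ", "))
      }
      keep <- keep & (top$atoms$name %in% nm)
    } else if (grepl("^resid\\s+", cl)) {
      spec <- strsplit(sub("^resid\\s+", "", cl), "[,\\s]+")[[1]]
      ids <- integer(0)
      for (s in spec[nzchar(spec)]) {
        if (grepl("^-?\\d+--?\\d+$", s) || grepl("^\\d+-\\d+$", s)) {
          ab <- as.integer(strsplit(s, "(?<=\\d)-", perl = TRUE)[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else {
          ids <- c(ids, as.integer(s))
        }
      }
      keep <- keep & (top$atoms$resid %in% ids)
    } else {
      stop("cannot parse selection clause: '", cl, "'")
    }
  }
  which(keep)
}

#' Mass-weighted centre of mass
#'
#' @param xyz n x 3 coordinate matrix (nm)
#' @param top topology supplying masses, or a numeric mass vector
#' @param indices optional atom subset
#' @return length-3 numeric vector (nm)
#' @export
center_of_mass <- function(xyz, top, indices = NULL) {
  m <- if (is.numeric(top)) top else top$atoms$mass
  xyz <- as_xyz(xyz)
  if (!is.null(indices)) {
    xyz <- xyz[indices, , drop = FALSE]
    m <- m[indices]
  }
  if (length(m) != nrow(xyz)) stop("mass vector does not match coordinates")
  M <- sum(m)
  if (M <= 0) stop("total mass is zero")
  colSums(xyz * m) / M
}

# coerce to an n x 3 numeric matrix with finiteness check
as_xyz <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("coordinates must be an n x 3 matrix")
  if (!all(is.finite(xyz))) stop("coordinates contain non-finite values")
  storage.mode(xyz) <- "double"
  xyz
}

#' Trajectory container
#'
#' Ordered conformations sharing a topology, with strictly increasing time
#' stamps in ps and free-form metadata (temperature, seed, provenance).
#'
#' @param frames list of n x 3 coordinate matrices (nm)
#' @param times numeric vector of ps time stamps, strictly increasing
#' @param metadata named list
#' @return object of class `"trajectory"`
#' @export
trajectory <- function(frames, times = NULL, metadata = list()) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, as_xyz)
  if (length(frames) > 0) {
    nr <- vapply(frames, nrow, integer(1))
    if (length(unique(nr)) > 1) stop("all frames must have the same atom count")
  }
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames))
    stop("times must match the number of frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(frames = frames, times = as.numeric(times),
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  natm <- if (length(x$frames) > 0) nrow(x$frames[[1]]) else 0
  cat(sprintf("trajectory: %d frames, %d atoms", length(x$frames), natm))
  if (length(x$times) > 1)
    cat(sprintf(", t = %g..%g ps", x$times[1], x$times[length(x$times)]))
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)
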