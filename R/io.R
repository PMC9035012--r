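# default mapping from PDB atom names to SASA type codes; element-based
# fallback for anything not listed. User-extensible via the type_map
# argument of read_pdb().
.default_type_map <- c(N = "N", CA = "CH1", C = "C", O = "O", CB = "CH3",
                       OXT = "OM", SG = "S", SD = "S")

.fallback_type_by_element <- c(O = "O", N = "N", C = "CH2", S = "S",
                               H = "H", X = "DUM")

#' Read a PDB structure
#'
#' Parses a (possibly multi-model) PDB file via bio3d, resolves alternate
#' locations by policy, converts coordinates to nm, and assigns SASA atom
#' types from atom names (overridable). Covalent bonds are inferred from
#' interatomic distances (heavy-heavy < 0.17 nm, X-H < 0.115 nm) unless
#' disabled.
#'
#' @param path PDB file
#' @param altloc `"highest-occupancy"` (default), `"first"`, or `"error"`
#' @param chain optional chain filter
#' @param keep_hydrogens retain explicit hydrogens
#' @param type_map named character vector atom-name -> SASA type, merged
#'   over the package default
#' @param infer_bonds infer covalent bonds from distances
#' @return list with `top` (topology) and `traj` (a [trajectory()]; one
#'   frame per MODEL)
#' @export
read_pdb <- function(path, altloc = c("highest-occupancy", "first", "error"),
                     chain = NULL, keep_hydrogens = TRUE,
                     type_map = NULL, infer_bonds = TRUE) {
  altloc <- match.arg(altloc)
  if (!file.exists(path)) stop("no such file: ", path)
  check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!keep_hydrogens) keep <- keep & !grepl("^[0-9]*H", at$elety)
  # altLoc resolution within groups of (chain, resno, insert, name)
  altv <- at$alt
  altv[is.na(altv)] <- ""
  gkey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  for (g in unique(gkey[keep & altv != ""])) {
    rows <- which(keep & gkey == g)
    if (length(rows) < 2) next
    if (altloc == "error")
      stop("unresolved alternate locations for atom group ", g)
    pick <- if (altloc == "highest-occupancy")
      rows[which.max(occ[rows])] else rows[1]
    keep[setdiff(rows, pick)] <- FALSE
  }
  rows <- which(keep)
  at <- at[rows, , drop = FALSE]
  tm <- .default_type_map
  if (!is.null(type_map)) tm[names(type_map)] <- type_map
  sasa_type <- unname(tm[at$elety])
  elem_guess <- toupper(substr(sub("^[0-9]+", "", at$elety), 1, 1))
  elem_guess[!elem_guess %in% c("O", "N", "C", "S", "H")] <- "X"
  sasa_type[is.na(sasa_type)] <-
    .fallback_type_by_element[elem_guess[is.na(sasa_type)]]
  atoms <- data.frame(name = at$elety, sasa_type = sasa_type,
                      resid = at$resno, resname = at$resid,
                      stringsAsFactors = FALSE)
  # frames: bio3d xyz has one row per MODEL, columns x1 y1 z1 x2 ...
  xyzm <- pdb$xyz
  if (is.null(dim(xyzm))) xyzm <- matrix(xyzm, nrow = 1)
  cols <- as.vector(rbind(3 * rows - 2, 3 * rows - 1, 3 * rows))
  frames <- lapply(seq_len(nrow(xyzm)), function(mdl)
    matrix(xyzm[mdl, cols], ncol = 3, byrow = TRUE) / 10)  # A -> nm
  bonds <- matrix(integer(0), ncol = 2)
  if (infer_bonds && nrow(atoms) > 1) {
    x1 <- frames[[1]]
    d <- as.matrix(stats::dist(x1))
    ish <- element_for_type(atoms$sasa_type) == "H"
    cut <- matrix(0.17, nrow(atoms), nrow(atoms))
    cut[ish, ] <- 0.115; cut[, ish] <- 0.115
    cut[ish, ish] <- 0          # no H-H bonds
    sel <- which(d < cut & upper.tri(d), arr.ind = TRUE)
    bonds <- matrix(as.integer(sel), ncol = 2)
  }
  top <- topology(atoms, bonds)
  list(top = top, traj = trajectory(frames, seq_along(frames) - 1,
                                    metadata = list(source = path)))
}

# minimal well-formedness scan so parse errors name a line
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM  |HETATM)", lines)
  for (ln in rec) {
    l <- lines[ln]
    if (nchar(l) < 54)
      stop("malformed ATOM record at line ", ln, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                         substr(l, 39, 46),
                                         substr(l, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", ln,
           ": non-numeric coordinates")
  }
  invisible(TRUE)
}

#' Write a PDB file
#'
#' Coordinates are written in Angstrom at standard PDB precision (10^-3 nm);
#' multi-frame input produces MODEL/ENDMDL blocks.
#'
#' @param top topology
#' @param x n x 3 conformation (nm) or a [trajectory()]
#' @param path output file
#' @return path, invisibly
#' @export
write_pdb_file <- function(top, x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(as_xyz(x))
  multi <- length(frames) > 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   generated by implisolv", con)
  for (f in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frames[[f]] * 10    # nm -> A
    for (i in seq_len(n_atoms(top))) {
      nm <- top$atoms$name[i]
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      writeLines(sprintf(
        "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, nmf, substr(top$atoms$resname[i], 1, 3), "A",
        top$atoms$resid[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0,
        top$atoms$element[i]), con)
    }
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# required columns per observable table kind
.table_schema <- list(
  noe = c("resid_i", "atom_i", "resid_j", "atom_j", "bound_nm"),
  jcoupling = c("resid", "type", "value_hz"),
  s2 = c("resid", "atom_a", "atom_b", "value"))

#' Read a validated observable table
#'
#' Tab-separated with a mandatory header; `#` comment lines are skipped.
#' Rows violating the schema (missing columns, non-positive NOE bounds,
#' non-numeric values) raise row-numbered diagnostics.
#'
#' @param path file path
#' @param kind `"noe"`, `"jcoupling"` or `"s2"`
#' @return typed data.frame
#' @export
read_obs_table <- function(path, kind = c("noe", "jcoupling", "s2")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- .table_schema[[kind]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("table is missing required column(s): ",
         paste(miss, collapse = ", "))
  numcol <- switch(kind, noe = "bound_nm", jcoupling = "value_hz",
                   s2 = "value")
  vals <- suppressWarnings(as.numeric(df[[numcol]]))
  bad <- which(is.na(vals))
  if (length(bad) > 0)
    stop("non-numeric ", numcol, " in row(s): ",
         paste(bad, collapse = ", "))
  df[[numcol]] <- vals
  if (kind == "noe") {
    bad <- which(vals <= 0)
    if (length(bad) > 0)
      stop("non-positive NOE bound in row(s): ",
           paste(bad, collapse = ", "))
  }
  if (kind == "jcoupling" && !is.null(df$cap_flag))
    df$cap_flag <- as.logical(df$cap_flag)
  df
}

#' Write an observable table
#' @param df data.frame
#' @param path output file
#' @return path, invisibly
#' @export
write_obs_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a trajectory
#'
#' The plain-text format round-trips losslessly (17 significant digits):
#' a header, `natoms N`, then `frame <time_ps>` blocks of one `x y z` line
#' per atom. PDB output goes through [write_pdb_file()] at PDB precision.
#'
#' @param traj a [trajectory()]
#' @param path output file
#' @param format `"text"` or `"pdb"`
#' @param top topology (required for PDB output)
#' @param every keep every `every`-th frame (thinning)
#' @return path, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("text", "pdb"),
                             top = NULL, every = 1) {
  format <- match.arg(format)
  if (every > 1) {
    keep <- seq(1, n_frames(traj), by = every)
    traj <- trajectory(traj$frames[keep], traj$times[keep], traj$metadata)
  }
  if (format == "pdb") {
    if (is.null(top)) stop("PDB trajectory output needs a topology")
    return(write_pdb_file(top, traj, path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  natm <- if (n_frames(traj) > 0) nrow(traj$frames[[1]]) else 0
  writeLines(c("# implisolv-traj v1", paste("natoms", natm)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("frame %.17g", traj$times[f]), con)
    xyz <- traj$frames[[f]]
    writeLines(sprintf("%.17g %.17g %.17g",
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text trajectory
#'
#' @param path file written by [write_trajectory()] (text format)
#' @return a [trajectory()] (possibly empty)
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0 || !grepl("^natoms ", lines[1]))
    stop("not an implisolv trajectory file (missing natoms header): ", path)
  natm <- as.integer(sub("^natoms ", "", lines[1]))
  lines <- lines[-1]
  frames <- list(); times <- numeric(0)
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^frame ", lines[i]))
      stop("expected 'frame' at data line ", i)
    times <- c(times, as.numeric(sub("^frame ", "", lines[i])))
    block <- lines[(i + 1):(i + natm)]
    xyz <- matrix(as.numeric(unlist(strsplit(block, " +"))),
                  ncol = 3, byrow = TRUE)
    frames[[length(frames) + 1]] <- xyz
    i <- i + natm + 1
  }
  trajectory(frames, times)
}
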