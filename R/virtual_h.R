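#' Virtual and pseudo hydrogen construction
#'
#' United-atom topologies carry no aliphatic hydrogens; observable
#' calculations reconstruct them geometrically from the heavy-atom frame:
#' \itemize{
#'   \item CH (type CH1): one virtual H on the negative sum of the unit
#'     vectors to the three heavy neighbours, at `d_ch` from the carbon.
#'   \item aromatic CH (CR1): in-plane H opposite the bisector of the two
#'     ring neighbours.
#'   \item prochiral CH2 (CH2/CH2r): a symmetric pair about the
#'     heavy-neighbour plane at the tetrahedral half-angle; the "2" proton
#'     lies along +(u_A x u_B) with A the lower-index neighbour.
#'   \item CH3: a single pseudo-site at the methyl carbon (the distance
#'     bound corrections compensate).
#'   \item polar N-H (amide): taken from the topology when explicit,
#'     otherwise a planar construction opposite the two heavy neighbours.
#' }
#'
#' @param xyz n x 3 heavy-atom coordinates (nm)
#' @param top topology
#' @param d_ch carbon-hydrogen construction distance (nm, default 0.1)
#' @return list with `xyz` (original atoms with the constructed sites
#'   appended), `sites` data.frame(name, resid, resname, parent, kind,
#'   index) where `index` points into the augmented coordinates, and
#'   `n_orig` (the original atom count)
#' @export
build_virtual_hydrogens <- function(xyz, top, d_ch = 0.1) {
  xyz <- as_xyz(xyz)
  n <- n_atoms(top)
  elem <- top$atoms$element
  adj <- vector("list", n)
  if (nrow(top$bonds) > 0) {
    for (r in seq_len(nrow(top$bonds))) {
      a <- top$bonds[r, 1]; b <- top$bonds[r, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  unit <- function(v) v / sqrt(sum(v^2))
  h_suffix <- function(nm) {
    suf <- sub("^[A-Z]", "", nm)
    paste0("H", suf)
  }
  sites <- list()
  coords <- list()
  add_site <- function(name, at, parent, kind) {
    sites[[length(sites) + 1]] <<- data.frame(
      name = name, resid = top$atoms$resid[parent],
      resname = top$atoms$resname[parent], parent = parent, kind = kind)
    coords[[length(coords) + 1]] <<- at
  }
  for (i in seq_len(n)) {
    ty <- top$atoms$sasa_type[i]
    heavy <- adj[[i]][elem[adj[[i]]] != "H"]
    expl_h <- adj[[i]][elem[adj[[i]]] == "H"]
    if (ty == "CH1") {
      if (length(heavy) < 3)
        stop("cannot construct virtual H: CH1 atom ", top$atoms$name[i],
             " of residue ", top$atoms$resid[i],
             " has fewer than 3 heavy neighbours")
      u <- lapply(heavy[1:3], function(j) unit(xyz[j, ] - xyz[i, ]))
      dir <- unit(-(u[[1]] + u[[2]] + u[[3]]))
      add_site(h_suffix(top$atoms$name[i]), xyz[i, ] + d_ch * dir, i, "CH1")
    } else if (ty == "CR1") {
      if (length(heavy) < 2)
        stop("cannot construct virtual H: CR1 atom ", top$atoms$name[i],
             " of residue ", top$atoms$resid[i],
             " has fewer than 2 heavy neighbours")
      u <- lapply(heavy[1:2], function(j) unit(xyz[j, ] - xyz[i, ]))
      dir <- unit(-(u[[1]] + u[[2]]))
      add_site(h_suffix(top$atoms$name[i]), xyz[i, ] + d_ch * dir, i, "CR1")
    } else if (ty %in% c("CH2", "CH2r")) {
      if (length(heavy) < 2)
        stop("cannot construct virtual H pair: CH2 atom ",
             top$atoms$name[i], " of residue ", top$atoms$resid[i],
             " has fewer than 2 heavy neighbours")
      hv <- sort(heavy)[1:2]
      uA <- unit(xyz[hv[1], ] - xyz[i, ])
      uB <- unit(xyz[hv[2], ] - xyz[i, ])
      e1 <- unit(-(uA + uB))
      e2 <- unit(c(uA[2] * uB[3] - uA[3] * uB[2],
                   uA[3] * uB[1] - uA[1] * uB[3],
                   uA[1] * uB[2] - uA[2] * uB[1]))
      alpha <- (109.47 / 2) * pi / 180
      base <- h_suffix(top$atoms$name[i])
      add_site(paste0(base, "2"),
               xyz[i, ] + d_ch * (cos(alpha) * e1 + sin(alpha) * e2), i, "CH2")
      add_site(paste0(base, "3"),
               xyz[i, ] + d_ch * (cos(alpha) * e1 - sin(alpha) * e2), i, "CH2")
    } else if (ty == "CH3") {
      add_site(h_suffix(top$atoms$name[i]), xyz[i, ], i, "CH3")
    } else if (elem[i] == "N" && length(expl_h) == 0 &&
               length(heavy) == 2) {
      u <- lapply(heavy[1:2], function(j) unit(xyz[j, ] - xyz[i, ]))
      dir <- unit(-(u[[1]] + u[[2]]))
      nm <- if (top$atoms$name[i] == "N") "HN" else
        h_suffix(top$atoms$name[i])
      add_site(nm, xyz[i, ] + d_ch * dir, i, "polar")
    }
  }
  if (length(sites) == 0) {
    sdf <- data.frame(name = character(0), resid = integer(0),
                      resname = character(0), parent = integer(0),
                      kind = character(0), index = integer(0))
    return(list(xyz = xyz, sites = sdf, n_orig = n))
  }
  sdf <- do.call(rbind, sites)
  sdf$index <- n + seq_len(nrow(sdf))
  list(xyz = rbind(xyz, do.call(rbind, coords)), sites = sdf, n_orig = n)
}

#' Resolve a proton atom specification
#'
#' Matches a (possibly wildcarded) proton name within a residue against the
#' explicit hydrogens of the topology and the constructed virtual/pseudo
#' sites. A trailing `*` matches any suffix (`HD*` matches HD1, HD2 and a
#' methyl pseudo-site HD).
#'
#' @param spec atom name, e.g. "HA", "HB2", "HD*"
#' @param resid residue number
#' @param vh result of [build_virtual_hydrogens()]
#' @param top topology
#' @return list with `indices` (into the augmented coordinates; empty when
#'   unresolvable) and `kinds` (site kinds for correction lookup)
#' @export
resolve_proton_spec <- function(spec, resid, vh, top) {
  wild <- grepl("\\*$", spec)
  stem <- sub("\\*$", "", spec)
  match_name <- function(nm) if (wild) startsWith(nm, stem) else nm == spec
  idx <- integer(0); kinds <- character(0)
  expl <- which(top$atoms$element == "H" & top$atoms$resid == resid &
                  match_name(top$atoms$name))
  if (length(expl) > 0) {
    idx <- c(idx, expl)
    kinds <- c(kinds, rep("explicit", length(expl)))
  }
  srows <- which(vh$sites$resid == resid &
                   vapply(vh$sites$name, match_name, logical(1)))
  if (length(srows) > 0) {
    idx <- c(idx, vh$sites$index[srows])
    kinds <- c(kinds, vh$sites$kind[srows])
  }
  list(indices = idx, kinds = kinds, wildcard = wild)
}
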