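# Atomic-structure and trajectory containers, atom selections, and PDB/XYZ
# text I/O (PDB through bio3d; plain multi-frame XYZ by hand).

.ELEMENT_RADIUS <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                     P = 1.80, X = 1.70)
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, X = 12.011)

.elem_lookup <- function(table, elem) {
  v <- table[match(elem, names(table))]
  v[is.na(v)] <- table[["X"]]
  unname(v)
}

#' Atomic structure
#'
#' Per-atom records of a (reference) structure: atom name, element, 1-based
#' residue id, residue name, chain id, Cartesian coordinates in Angstrom,
#' mass in Da and van der Waals radius in Angstrom. Missing masses/radii are
#' filled from the element.
#'
#' @param atoms data.frame with columns \code{name}, \code{elem},
#'   \code{resid}, \code{resname}, \code{chain}, \code{x}, \code{y},
#'   \code{z}, and optionally \code{mass}, \code{radius}.
#' @return an object of class \code{md_structure}.
#' @export
md_structure <- function(atoms) {
  need <- c("name", "elem", "resid", "resname", "chain", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) < 1) stop("a structure needs at least one atom")
  if (is.null(atoms$mass)) atoms$mass <- .elem_lookup(.ELEMENT_MASS, atoms$elem)
  if (is.null(atoms$radius))
    atoms$radius <- .elem_lookup(.ELEMENT_RADIUS, atoms$elem)
  if (any(atoms$radius <= 0)) stop("van der Waals radii must be positive")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (any(diff(r) < 0)) stop("residue ids must be non-decreasing within a chain")
  }
  structure(list(atoms = atoms), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chain(s)\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix
#' @param s an [md_structure()].
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "md_structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Select atom indices of a structure
#'
#' Named selections follow PDB atom-name conventions: \code{"CA"} picks the
#' alpha carbons, \code{"backbone"} the N, CA, C, O atoms, \code{"all"}
#' everything. \code{resid} further restricts to the given residue ids.
#'
#' @param s an [md_structure()].
#' @param selection "all", "CA", "backbone", or a character vector of atom
#'   names.
#' @param resid optional residue ids to restrict to.
#' @return integer atom indices.
#' @export
select_atoms <- function(s, selection = "all", resid = NULL) {
  stopifnot(inherits(s, "md_structure"))
  idx <- seq_len(nrow(s$atoms))
  if (length(selection) == 1 && selection == "backbone")
    idx <- idx[s$atoms$name %in% c("N", "CA", "C", "O")]
  else if (length(selection) == 1 && selection == "CA")
    idx <- idx[s$atoms$name == "CA"]
  else if (!(length(selection) == 1 && selection == "all"))
    idx <- idx[s$atoms$name %in% selection]
  if (!is.null(resid)) idx <- idx[s$atoms$resid[idx] %in% resid]
  if (length(idx) == 0) stop("empty atom selection")
  idx
}

#' Molecular-dynamics trajectory
#'
#' Frames of coordinates congruent with a reference structure, optionally
#' with cosolvent coordinates per frame (cosolvent atoms grouped into
#' molecules) and a cubic periodic box.
#'
#' @param reference an [md_structure()].
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param frame_times frame times, arbitrary units.
#' @param cosolvent optional list (one per frame) of m x 3 cosolvent
#'   coordinate matrices, same m in every frame.
#' @param cosolvent_group integer vector of length m assigning cosolvent
#'   atoms to molecules; defaults to one molecule per atom.
#' @param box cubic box edge in Angstrom (NA if non-periodic).
#' @return an object of class \code{md_trajectory}.
#' @export
md_trajectory <- function(reference, frames, frame_times = NULL,
                          cosolvent = NULL, cosolvent_group = NULL,
                          box = NA_real_) {
  stopifnot(inherits(reference, "md_structure"))
  n_at <- nrow(reference$atoms)
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == n_at &&
                 ncol(f) == 3, TRUE)
  if (!all(ok)) stop("every frame must be an n_atoms x 3 matrix congruent with the reference")
  if (is.null(frame_times)) frame_times <- seq_along(frames)
  if (!is.null(cosolvent)) {
    if (length(cosolvent) != length(frames))
      stop("cosolvent must have one coordinate set per frame")
    m <- nrow(cosolvent[[1]])
    if (is.null(cosolvent_group)) cosolvent_group <- seq_len(m)
    if (length(cosolvent_group) != m)
      stop("cosolvent_group must assign every cosolvent atom")
  }
  structure(list(reference = reference, frames = frames,
                 frame_times = frame_times, cosolvent = cosolvent,
                 cosolvent_group = cosolvent_group, box = box),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d atoms%s%s\n",
              length(x$frames), nrow(x$reference$atoms),
              if (!is.null(x$cosolvent))
                sprintf(", %d cosolvent atoms", nrow(x$cosolvent[[1]])) else "",
              if (!is.na(x$box)) sprintf(", box %.4g A", x$box) else ""))
  invisible(x)
}

# ---- PDB I/O (bio3d) --------------------------------------------------------

.structure_from_bio3d <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(a$elety), 1, 1)
  md_structure(data.frame(
    name = trimws(a$elety), elem = trimws(elem), resid = a$resno,
    resname = trimws(a$resid), chain = ifelse(is.na(a$chain), "A", a$chain),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE))
}

#' Read a structure from a PDB file
#'
#' @param path PDB file path (ATOM and HETATM records are kept).
#' @return an [md_structure()].
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  .structure_from_bio3d(bio3d::read.pdb(path, verbose = FALSE))
}

#' Read a multi-MODEL PDB file as a trajectory
#'
#' All MODEL records must contain the same atoms. Atoms whose residue name is
#' in \code{cosolvent_resnames} become the cosolvent component, grouped into
#' molecules by residue id.
#'
#' @param path PDB file path.
#' @param cosolvent_resnames residue names treated as cosolvent (e.g. "SUC").
#' @param box cubic box edge in Angstrom, if known.
#' @return an [md_trajectory()].
#' @export
read_trajectory_pdb <- function(path, cosolvent_resnames = character(0),
                                box = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  s <- .structure_from_bio3d(pdb)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  is_cos <- s$atoms$resname %in% cosolvent_resnames
  to_frames <- function(keep) {
    lapply(seq_len(n_frames), function(i) {
      m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
      m[keep, , drop = FALSE]
    })
  }
  solute <- md_structure(s$atoms[!is_cos, , drop = FALSE])
  frames <- to_frames(!is_cos)
  cosolvent <- NULL; grp <- NULL
  if (any(is_cos)) {
    cosolvent <- to_frames(is_cos)
    grp <- as.integer(factor(paste(s$atoms$chain[is_cos],
                                   s$atoms$resid[is_cos])))
  }
  md_trajectory(solute, frames, cosolvent = cosolvent,
                cosolvent_group = grp, box = box)
}

#' Write a trajectory (or single structure) as a multi-MODEL PDB file
#'
#' Cosolvent atoms, when present, are appended to each MODEL with residue
#' name \code{cosolvent_resname}.
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @param cosolvent_resname residue name for cosolvent atoms.
#' @return the path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path, cosolvent_resname = "SUC") {
  stopifnot(inherits(traj, "md_trajectory"))
  a <- traj$reference$atoms
  has_cos <- !is.null(traj$cosolvent)
  n_cos <- if (has_cos) nrow(traj$cosolvent[[1]]) else 0L
  resno <- c(a$resid, if (has_cos) max(a$resid) + traj$cosolvent_group)
  resid <- c(a$resname, rep(cosolvent_resname, n_cos))
  elety <- c(a$name, rep("C1", n_cos))
  chain <- c(a$chain, rep("X", n_cos))
  elesy <- c(a$elem, rep("C", n_cos))
  xyz <- do.call(rbind, lapply(seq_along(traj$frames), function(i) {
    m <- traj$frames[[i]]
    if (has_cos) m <- rbind(m, traj$cosolvent[[i]])
    as.numeric(t(m))
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = chain, elesy = elesy)
  invisible(path)
}

# ---- multi-frame XYZ I/O ----------------------------------------------------

#' Write a trajectory in multi-frame XYZ format
#'
#' Standard XYZ blocks: atom count, a comment line carrying the frame time
#' and box edge, then "element x y z" rows. Cosolvent atoms are appended with
#' element label "Su".
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  elem <- traj$reference$atoms$elem
  has_cos <- !is.null(traj$cosolvent)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    m <- traj$frames[[i]]
    lab <- elem
    if (has_cos) {
      m <- rbind(m, traj$cosolvent[[i]])
      lab <- c(elem, rep("Su", nrow(traj$cosolvent[[i]])))
    }
    writeLines(as.character(nrow(m)), con)
    writeLines(sprintf("frame %d time %.6g box %.6g", i,
                       traj$frame_times[i], traj$box), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", lab, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Atoms labelled "Su" are read back as cosolvent (one molecule per atom);
#' everything else becomes a single-chain solute with one residue per atom
#' unless a \code{reference} structure supplies the topology.
#'
#' @param path XYZ file path.
#' @param reference optional [md_structure()] giving names/residues for the
#'   solute atoms (coordinate count must match).
#' @return an [md_trajectory()].
#' @export
read_trajectory_xyz <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  i <- 1L; frames <- list(); cosolvent <- list(); times <- numeric(0)
  box <- NA_real_; labels <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected an atom count at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment, regexec("time ([-0-9.eE+]+)", comment))[[1]]
    bx <- regmatches(comment, regexec("box ([-0-9.eE+]+)", comment))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else length(times) + 1)
    if (length(bx) == 2) box <- as.numeric(bx[2])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    lab <- vapply(parts, `[`, "", 1)
    m <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(labels)) labels <- lab
    else if (!identical(lab, labels)) stop("inconsistent atoms across XYZ frames")
    is_cos <- lab == "Su"
    frames[[length(frames) + 1L]] <- m[!is_cos, , drop = FALSE]
    cosolvent[[length(cosolvent) + 1L]] <- m[is_cos, , drop = FALSE]
    i <- i + 2L + n
  }
  is_cos <- labels == "Su"
  if (is.null(reference)) {
    ns <- sum(!is_cos)
    reference <- md_structure(data.frame(
      name = "CA", elem = labels[!is_cos], resid = seq_len(ns),
      resname = "GLY", chain = "A",
      x = frames[[1]][, 1], y = frames[[1]][, 2], z = frames[[1]][, 3],
      stringsAsFactors = FALSE))
  } else if (nrow(reference$atoms) != sum(!is_cos)) {
    stop("reference atom count does not match XYZ solute atoms")
  }
  md_trajectory(reference, frames, frame_times = times,
                cosolvent = if (any(is_cos)) cosolvent else NULL,
                box = box)
}
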