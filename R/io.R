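#' Construct a single trajectory frame
#'
#' @param positions n x 3 numeric matrix of coordinates in nm.
#' @param box Orthorhombic box lengths in nm (length 3, all > 0).
#' @param time Frame time in ps.
#' @return Object of class `tag_frame`.
#' @export
frame_snapshot <- function(positions, box, time = 0) {
  positions <- to_xyz(positions)
  dimnames(positions) <- NULL
  box <- check_box(box)
  if (!is.numeric(time) || length(time) != 1L) stop("`time` must be a single number (ps)")
  structure(list(positions = positions, box = box, time = as.numeric(time)),
            class = "tag_frame")
}

#' Construct a trajectory from frames and a selection
#'
#' @param frames List of `tag_frame` objects with strictly increasing times
#'   and a common atom count.
#' @param selection A `tag_selection` (see [selection_spec()]); may be `NULL`
#'   for raw coordinate handling.
#' @return Object of class `tag_trajectory`.
#' @export
trajectory <- function(frames, selection = NULL) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "tag_frame"))) {
    stop("`frames` must be a list of tag_frame objects")
  }
  nat <- vapply(frames, function(f) nrow(f$positions), integer(1))
  if (length(unique(nat)) != 1L) {
    stop("format error: frames disagree on atom count (",
         paste(unique(nat), collapse = ", "), ")")
  }
  tm <- vapply(frames, function(f) f$time, numeric(1))
  if (length(tm) > 1L && any(diff(tm) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(selection)) validate_selection(selection, n_atoms = nat[1])
  structure(list(frames = frames, selection = selection),
            class = "tag_trajectory")
}

#' @export
print.tag_trajectory <- function(x, ...) {
  cat("TAG trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1]]$positions), "atoms")
  if (!is.null(x$selection)) cat(",", nrow(x$selection), "molecules")
  cat("\n  time ", x$frames[[1]]$time, "..",
      x$frames[[length(x$frames)]]$time, "ps\n")
  invisible(x)
}

#' Define which atoms carry each metric role
#'
#' Each TAG molecule contributes seven atoms to the metrics: two on the
#' palmitic (sn-1) chain, two on the stearic (sn-3) chain, and the first,
#' middle and last atoms of the oleic (sn-2) chain. For sn-POSt these are
#' the 9th and 16th palmitic atoms, the 11th and 18th stearic atoms, and
#' the oleic chain ends plus the atom at the cis-double-bond kink.
#'
#' @param molecule_id Integer vector of molecule labels; must be unique and
#'   contiguous starting at 1.
#' @param palmitic_mid,palmitic_tail,stearic_mid,stearic_tail,oleic_first,oleic_mid,oleic_last
#'   Integer vectors of global 1-based atom indices, one entry per molecule.
#' @return `data.frame` of class `tag_selection`.
#' @export
selection_spec <- function(molecule_id, palmitic_mid, palmitic_tail,
                           stearic_mid, stearic_tail,
                           oleic_first, oleic_mid, oleic_last) {
  sel <- data.frame(molecule_id = as.integer(molecule_id),
                    palmitic_mid = as.integer(palmitic_mid),
                    palmitic_tail = as.integer(palmitic_tail),
                    stearic_mid = as.integer(stearic_mid),
                    stearic_tail = as.integer(stearic_tail),
                    oleic_first = as.integer(oleic_first),
                    oleic_mid = as.integer(oleic_mid),
                    oleic_last = as.integer(oleic_last))
  class(sel) <- c("tag_selection", "data.frame")
  validate_selection(sel)
  sel
}

#' @keywords internal
#' @noRd
role_names <- function() {
  c("palmitic_mid", "palmitic_tail", "stearic_mid", "stearic_tail",
    "oleic_first", "oleic_mid", "oleic_last")
}

#' @keywords internal
#' @noRd
validate_selection <- function(sel, n_atoms = NULL) {
  roles <- role_names()
  if (!all(c("molecule_id", roles) %in% names(sel))) {
    stop("configuration error: selection must provide molecule_id and the 7 atom roles")
  }
  ids <- sel$molecule_id
  if (anyDuplicated(ids) || !identical(sort(ids), seq_along(ids))) {
    stop("configuration error: molecule_id values must be unique and contiguous from 1")
  }
  idx <- as.matrix(sel[, roles])
  dup <- apply(idx, 1L, anyDuplicated) > 0L
  if (any(dup)) {
    stop("configuration error: molecule ", ids[which(dup)[1]],
         " repeats an atom index across roles")
  }
  if (!is.null(n_atoms)) {
    bad <- apply(idx, 1L, function(r) any(r < 1L | r > n_atoms))
    if (any(bad)) {
      stop("configuration error: molecule ", ids[which(bad)[1]],
           " has an atom index outside 1..", n_atoms)
    }
  }
  invisible(sel)
}

#' Build a uniform selection for systems with identical molecules
#'
#' Convenience for systems where every molecule has the same number of atoms
#' in the same order, so role indices repeat with a fixed offset.
#'
#' @param n_molecules Number of molecules.
#' @param roles Named integer vector of within-molecule 1-based indices for
#'   the seven roles.
#' @param atoms_per_molecule Atoms per molecule.
#' @param offset Index of the atom preceding molecule 1 (default 0).
#' @return `tag_selection`.
#' @export
uniform_selection <- function(n_molecules, roles, atoms_per_molecule,
                              offset = 0L) {
  need <- role_names()
  if (!all(need %in% names(roles))) {
    stop("`roles` must name all of: ", paste(need, collapse = ", "))
  }
  base <- offset + (seq_len(n_molecules) - 1L) * atoms_per_molecule
  args <- c(list(molecule_id = seq_len(n_molecules)),
            lapply(need, function(r) base + as.integer(roles[[r]])))
  names(args)[-1] <- need
  do.call(selection_spec, args)
}

#' Read a selection specification from a YAML file
#'
#' Two layouts are accepted: a `pattern:` block
#' (`n_molecules`, `atoms_per_molecule`, optional `offset`, and a `roles:`
#' map of within-molecule indices) for uniform systems, or a `molecules:`
#' list where each entry gives `molecule_id` and the seven roles as global
#' atom indices. All indices are 1-based, matching chemical numbering.
#'
#' @param path Path to the YAML file.
#' @return `tag_selection`.
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) stop("I/O error: selection file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$pattern)) {
    p <- y$pattern
    return(uniform_selection(n_molecules = p$n_molecules,
                             roles = unlist(p$roles),
                             atoms_per_molecule = p$atoms_per_molecule,
                             offset = if (is.null(p$offset)) 0L else p$offset))
  }
  if (!is.null(y$molecules)) {
    rows <- lapply(y$molecules, as.data.frame)
    sel <- do.call(rbind, rows)
    sel <- sel[order(sel$molecule_id), , drop = FALSE]
    rownames(sel) <- NULL
    args <- as.list(sel[, c("molecule_id", role_names())])
    return(do.call(selection_spec, args))
  }
  stop("configuration error: selection YAML needs a `pattern:` or `molecules:` block")
}

#' Write a selection specification to YAML
#'
#' @param sel `tag_selection`.
#' @param path Output path.
#' @export
write_selection <- function(sel, path) {
  validate_selection(sel)
  mols <- lapply(seq_len(nrow(sel)), function(i) as.list(sel[i, ]))
  yaml::write_yaml(list(molecules = mols), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GRO format (GROMACS coordinates, nm). Fixed columns:
#   title (may carry "t= <ps>")
#   natoms
#   %5d%-5s%5s%5d%8.3f%8.3f%8.3f  (+ optional velocities, ignored)
#   box: 3 lengths (orthorhombic) or 9 components (triclinic -> rejected)
# Multiple concatenated blocks form a multi-frame trajectory.
# ---------------------------------------------------------------------------

#' Read a (possibly multi-frame) GROMACS GRO file
#'
#' Coordinates are returned in nm. Triclinic boxes are rejected. Frame times
#' are taken from `t=` markers on title lines when present, otherwise
#' consecutive integers (ps) are assigned.
#'
#' @param path Path to the `.gro` file.
#' @return List with `frames` (list of [frame_snapshot()]), `resid`,
#'   `resname` and `atom_name` vectors from the first frame.
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  lines <- readLines(path)
  frames <- list()
  meta <- NULL
  pos0 <- 1L
  frame_i <- 0L
  while (pos0 <= length(lines)) {
    if (!nzchar(trimws(lines[pos0]))) { pos0 <- pos0 + 1L; next }
    title <- lines[pos0]
    nat <- suppressWarnings(as.integer(trimws(lines[pos0 + 1L])))
    if (is.na(nat) || nat < 1L) stop("format error: bad atom count at line ", pos0 + 1L)
    if (pos0 + 1L + nat + 1L > length(lines)) {
      stop("format error: truncated GRO frame starting at line ", pos0)
    }
    atom_lines <- lines[(pos0 + 2L):(pos0 + 1L + nat)]
    resid <- as.integer(substr(atom_lines, 1L, 5L))
    resname <- trimws(substr(atom_lines, 6L, 10L))
    atom_name <- trimws(substr(atom_lines, 11L, 15L))
    tail_num <- strsplit(trimws(substr(atom_lines, 21L, 1000L)), "\\s+")
    xyz <- t(vapply(tail_num, function(v) as.numeric(v[1:3]), numeric(3)))
    if (anyNA(xyz)) stop("format error: unparseable coordinates in GRO frame ", frame_i + 1L)
    boxv <- as.numeric(strsplit(trimws(lines[pos0 + 1L + nat + 1L]), "\\s+")[[1]])
    if (length(boxv) >= 9L && any(boxv[4:9] != 0)) {
      stop("triclinic boxes are not supported; only orthorhombic boxes are accepted")
    }
    frame_i <- frame_i + 1L
    tm <- gro_title_time(title)
    if (is.na(tm)) tm <- frame_i - 1
    frames[[frame_i]] <- frame_snapshot(xyz, boxv[1:3], tm)
    if (is.null(meta)) meta <- list(resid = resid, resname = resname, atom_name = atom_name)
    if (nat != nrow(frames[[1]]$positions)) {
      stop("format error: frame ", frame_i, " has ", nat, " atoms but frame 1 has ",
           nrow(frames[[1]]$positions))
    }
    pos0 <- pos0 + 1L + nat + 2L
  }
  if (!length(frames)) stop("format error: no frames found in ", path)
  c(list(frames = frames), meta)
}

#' @keywords internal
#' @noRd
gro_title_time <- function(title) {
  m <- regmatches(title, regexec("t=\\s*([-+0-9.eE]+)", title))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NA_real_
}

#' Write frames to a (multi-frame) GRO file
#'
#' @param frames A `tag_trajectory`, a list of `tag_frame`s, or one frame.
#' @param path Output path.
#' @param resid,resname,atom_name Optional per-atom metadata; defaults
#'   number every atom as its own residue `MOL`.
#' @export
write_gro <- function(frames, path, resid = NULL, resname = NULL,
                      atom_name = NULL) {
  if (inherits(frames, "tag_trajectory")) frames <- frames$frames
  if (inherits(frames, "tag_frame")) frames <- list(frames)
  nat <- nrow(frames[[1]]$positions)
  if (is.null(resid)) resid <- seq_len(nat)
  if (is.null(resname)) resname <- rep("MOL", nat)
  if (is.null(atom_name)) atom_name <- rep("C", nat)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    writeLines(sprintf("tagcryst frame t= %.4f", f$time), con)
    writeLines(sprintf("%5d", nat), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       resid %% 100000L, substr(resname, 1, 5),
                       substr(atom_name, 1, 5), seq_len(nat) %% 100000L,
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]),
               con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", f$box[1], f$box[2], f$box[3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Plain fallback trajectory format: per frame a header
#   natoms time box_x box_y box_z
# followed by natoms "x y z" lines; whitespace-delimited, '#' comments.
# ---------------------------------------------------------------------------

#' Read the plain whitespace-delimited trajectory format
#'
#' @param path Path to the file.
#' @return List of [frame_snapshot()] objects.
#' @export
read_plain_trajectory <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  frames <- list()
  k <- 1L
  while (k <= length(lines)) {
    hdr <- as.numeric(strsplit(trimws(lines[k]), "\\s+")[[1]])
    if (length(hdr) != 5L || anyNA(hdr)) {
      stop("format error: expected header `natoms time box_x box_y box_z`, got: ",
           lines[k])
    }
    nat <- as.integer(hdr[1])
    if (k + nat > length(lines)) stop("format error: truncated frame at line ", k)
    xyz <- do.call(rbind, lapply(lines[(k + 1L):(k + nat)], function(l) {
      v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
      if (length(v) < 3L || anyNA(v[1:3])) stop("format error: bad coordinate line: ", l)
      v[1:3]
    }))
    frames[[length(frames) + 1L]] <- frame_snapshot(xyz, hdr[3:5], hdr[2])
    k <- k + nat + 1L
  }
  if (!length(frames)) stop("format error: no frames in ", path)
  frames
}

#' Write frames in the plain fallback trajectory format
#'
#' @param frames `tag_trajectory`, list of frames, or a single frame.
#' @param path Output path.
#' @export
write_plain_trajectory <- function(frames, path) {
  if (inherits(frames, "tag_trajectory")) frames <- frames$frames
  if (inherits(frames, "tag_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# tagcryst plain trajectory: `natoms time box_x box_y box_z` then x y z per atom (nm, ps)", con)
  for (f in frames) {
    writeLines(sprintf("%d %.6f %.6f %.6f %.6f", nrow(f$positions), f$time,
                       f$box[1], f$box[2], f$box[3]), con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       f$positions[, 1], f$positions[, 2], f$positions[, 3]), con)
  }
  invisible(path)
}

#' Load a trajectory from disk
#'
#' Reads a GRO topology (which may itself contain multiple frames) and an
#' optional separate trajectory file (multi-frame GRO or the plain fallback
#' format), attaches the selection, and optionally re-joins molecules that
#' were wrapped across the periodic boundary.
#'
#' Binary GROMACS trajectories (XTC/TRR) are not supported; convert to
#' multi-frame GRO (e.g. `gmx trjconv`) or the plain format first.
#'
#' @param topology_path Path to a GRO file.
#' @param trajectory_path Optional path to a trajectory file; its frames
#'   replace the topology frames.
#' @param selection A `tag_selection`, or a path to a selection YAML file.
#' @param make_whole If `TRUE` (default) each molecule's selected atoms are
#'   unwrapped to the periodic image nearest its first role atom, so that
#'   intramolecular distances are meaningful for boundary-crossing molecules.
#' @return `tag_trajectory`.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL, selection,
                            make_whole = TRUE) {
  if (is.character(selection)) selection <- read_selection(selection)
  top <- read_gro(topology_path)
  frames <- top$frames
  if (!is.null(trajectory_path)) {
    ext <- tolower(tools::file_ext(trajectory_path))
    if (ext %in% c("xtc", "trr")) {
      stop("format error: binary ", toupper(ext), " trajectories are not supported; ",
           "supply a multi-frame GRO or plain-format trajectory")
    }
    frames <- if (ext == "gro") read_gro(trajectory_path)$frames
              else read_plain_trajectory(trajectory_path)
    if (nrow(frames[[1]]$positions) != nrow(top$frames[[1]]$positions)) {
      stop("format error: trajectory atom count (", nrow(frames[[1]]$positions),
           ") differs from topology (", nrow(top$frames[[1]]$positions), ")")
    }
  }
  validate_selection(selection, n_atoms = nrow(frames[[1]]$positions))
  if (make_whole) frames <- lapply(frames, make_molecules_whole, selection = selection)
  trajectory(frames, selection)
}

#' Re-join molecules split across the periodic boundary
#'
#' For each molecule, every selected atom is moved to the periodic image
#' nearest the molecule's first role atom. Only the selected (metric) atoms
#' are touched.
#'
#' @param frame `tag_frame`.
#' @param selection `tag_selection`.
#' @return `tag_frame` with unwrapped coordinates.
#' @export
make_molecules_whole <- function(frame, selection) {
  roles <- role_names()
  pos <- frame$positions
  anchor_idx <- selection[[roles[1]]]
  for (r in roles[-1]) {
    idx <- selection[[r]]
    disp <- min_image_displacement(pos[anchor_idx, , drop = FALSE],
                                   pos[idx, , drop = FALSE], frame$box)
    pos[idx, ] <- pos[anchor_idx, , drop = FALSE] + disp
  }
  frame$positions <- pos
  frame
}

#' Resolve the seven metric atoms of every molecule in one frame
#'
#' @param frame `tag_frame`.
#' @param selection `tag_selection`.
#' @return Object of class `tag_keypos`: list with `molecule_id`, `box`,
#'   `time`, and one n x 3 coordinate matrix per role.
#' @export
extract_key_positions <- function(frame, selection) {
  validate_selection(selection, n_atoms = nrow(frame$positions))
  ord <- order(selection$molecule_id)
  sel <- selection[ord, , drop = FALSE]
  out <- list(molecule_id = sel$molecule_id, box = frame$box, time = frame$time)
  for (r in role_names()) {
    out[[r]] <- frame$positions[sel[[r]], , drop = FALSE]
  }
  structure(out, class = "tag_keypos")
}
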