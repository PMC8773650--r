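# Multi-model PDB I/O and the atomic data model.
#
# A trajectory is stored column-wise: one atom table shared by all frames
# (uniform topology is an invariant, checked on read) plus a coordinate array
# of dimension n_atoms x 3 x n_frames.  Residue numbering is the author
# numbering from the PDB file; no renumbering is ever performed.

STANDARD_RESIDUES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

new_frame <- function(atoms, xyz) {
  structure(list(atoms = atoms, xyz = xyz), class = "sc_frame")
}

new_trajectory <- function(atoms, coords, frame_interval_ps = 10) {
  if (frame_interval_ps <= 0)
    stop_sctraj("sctraj_invalid", "frame_interval_ps must be positive")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "sc_trajectory")
}

#' Number of frames in a trajectory
#' @param traj A trajectory from [read_pdb()] or [plant_and_roll()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract a single frame from a trajectory
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @return A frame object (atom table plus coordinate matrix).
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1 || i > nf)
    stop_sctraj("sctraj_invalid", "frame index %d out of range 1..%d", i, nf)
  new_frame(traj$atoms, frame_xyz(traj, i))
}

# coordinate matrix of frame i (robust to 1-atom structures)
frame_xyz <- function(traj, i) {
  matrix(traj$coords[, , i], ncol = 3)
}

#' @export
print.sc_trajectory <- function(x, ...) {
  cat(sprintf("<sc_trajectory> %d frames, %d atoms, %d chains, interval %g ps\n",
              n_frames(x), nrow(x$atoms),
              length(unique(x$atoms$chain)), x$frame_interval_ps))
  invisible(x)
}

#' @export
print.sc_frame <- function(x, ...) {
  cat(sprintf("<sc_frame> %d atoms, %d residues, %d chains\n",
              nrow(x$atoms),
              length(unique(residue_uid(x$atoms$chain, x$atoms$res_seq,
                                        x$atoms$icode))),
              length(unique(x$atoms$chain))))
  invisible(x)
}

# Element inference: PDB columns 77-78 when present, otherwise the leading
# letters of the atom name after stripping digits.  Two-letter symbols are
# only accepted from the element column (atom-name inference on standard
# residues is single-letter: CA is a carbon, not calcium).
infer_element <- function(element_col, atom_name) {
  el <- toupper(trimws(element_col))
  need <- el == ""
  if (any(need)) {
    nm <- gsub("[0-9']", "", toupper(trimws(atom_name[need])))
    el[need] <- substr(nm, 1, 1)
  }
  el
}

# Parse ATOM/HETATM lines (fixed columns) into an atom table.
parse_atom_lines <- function(lines) {
  data.frame(
    serial    = suppressWarnings(as.integer(substr(lines, 7, 11))),
    atom_name = trimws(substr(lines, 13, 16)),
    alt_loc   = trimws(substr(lines, 17, 17)),
    res_name  = trimws(substr(lines, 18, 20)),
    chain     = substr(lines, 22, 22),
    res_seq   = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode     = trimws(substr(lines, 27, 27)),
    x         = as.numeric(substr(lines, 31, 38)),
    y         = as.numeric(substr(lines, 39, 46)),
    z         = as.numeric(substr(lines, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element   = substr(lines, 77, 78),
    stringsAsFactors = FALSE
  )
}

# Alt-loc resolution: per (residue, atom name) keep the highest-occupancy
# location; ties broken in favour of 'A' (then alphabetically).  Deterministic.
resolve_altloc <- function(at) {
  if (all(at$alt_loc == "")) return(at)
  key <- paste(at$chain, at$res_seq, at$icode, at$atom_name, sep = "\r")
  occ <- ifelse(is.na(at$occupancy), 1, at$occupancy)
  ord <- order(key, -occ, at$alt_loc)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at[order(at$serial), , drop = FALSE]
}

order_atoms <- function(at) {
  at[order(at$chain, at$res_seq, at$icode), , drop = FALSE]
}

#' Read a multi-model PDB file as a trajectory
#'
#' MODEL/ENDMDL records delimit frames; a file without MODEL records yields a
#' single-frame trajectory.  Hydrogens are parsed and flagged (`is_heavy =
#' FALSE`); all downstream contact computations use heavy atoms only.  HETATM
#' records are kept only for standard amino-acid residue names.  Alternate
#' locations are resolved to the highest-occupancy conformer (ties break to
#' 'A').  All frames must share the same chains, residues and atoms; a
#' mismatch raises a topology error naming the first offending residue.
#'
#' @param path Path to a PDB file.
#' @param frame_interval_ps Time between consecutive frames in picoseconds
#'   (metadata only; default 10).
#' @return A trajectory object.
#' @export
read_pdb <- function(path, frame_interval_ps = 10) {
  if (!file.exists(path))
    stop_sctraj("sctraj_io", "cannot read PDB file: %s", path)
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_starts <- which(substr(lines, 1, 5) == "MODEL")
  if (!any(is_atom))
    stop_sctraj("sctraj_empty", "no ATOM records in %s", path)

  atom_idx <- which(is_atom)
  if (length(model_starts) == 0) {
    model_of <- rep(1L, length(atom_idx))
  } else {
    model_of <- findInterval(atom_idx, model_starts)
    # atoms before the first MODEL record would be orphaned
    if (any(model_of == 0))
      stop_sctraj("sctraj_io", "ATOM records before first MODEL in %s", path)
  }

  at <- parse_atom_lines(lines[atom_idx])
  at$record <- rec[atom_idx]
  at$model <- model_of

  keep <- at$record == "ATOM  " | at$res_name %in% STANDARD_RESIDUES
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop_sctraj("sctraj_empty", "no usable ATOM records in %s", path)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop_sctraj("sctraj_io", "non-finite coordinates in %s", path)

  at$element <- infer_element(at$element, at$atom_name)
  at$is_heavy <- !(at$element %in% c("H", "D"))

  models <- split(at, at$model)
  models <- lapply(models, resolve_altloc)
  models <- lapply(models, order_atoms)

  ref <- models[[1]]
  ref_uid <- residue_uid(ref$chain, ref$res_seq, ref$icode)
  ref_sig <- paste(ref_uid, ref$res_name, ref$atom_name, sep = "|")
  if (length(models) > 1) {
    for (m in seq_along(models)[-1]) {
      cur <- models[[m]]
      cur_uid <- residue_uid(cur$chain, cur$res_seq, cur$icode)
      miss <- setdiff(unique(ref_uid), unique(cur_uid))
      extra <- setdiff(unique(cur_uid), unique(ref_uid))
      if (length(miss) || length(extra)) {
        off <- if (length(miss)) miss[1] else extra[1]
        stop_sctraj("sctraj_topology",
                    "topology mismatch in model %d: residue %s", m, off)
      }
      cur_sig <- paste(cur_uid, cur$res_name, cur$atom_name, sep = "|")
      if (nrow(cur) != nrow(ref) || any(cur_sig != ref_sig)) {
        off <- cur_uid[which(cur_sig != ref_sig)[1]] %||% cur_uid[1]
        stop_sctraj("sctraj_topology",
                    "topology mismatch in model %d: residue %s", m, off)
      }
    }
  }

  # residues made only of hydrogens cannot enter any contact computation
  heavy_per_res <- tapply(ref$is_heavy, ref_uid, any)
  if (any(!heavy_per_res))
    stop_sctraj("sctraj_topology", "residue %s has no heavy atom",
                names(heavy_per_res)[!heavy_per_res][1])

  n <- nrow(ref)
  coords <- array(NA_real_, dim = c(n, 3, length(models)))
  for (m in seq_along(models))
    coords[, , m] <- as.matrix(models[[m]][, c("x", "y", "z")])

  atoms <- ref[, c("atom_name", "alt_loc", "res_name", "chain",
                   "res_seq", "icode", "element", "is_heavy")]
  atoms$serial <- seq_len(n)
  rownames(atoms) <- NULL
  new_trajectory(atoms, coords, frame_interval_ps)
}

#' Write a trajectory (or single frame) as a multi-model PDB file
#'
#' Multi-frame trajectories are wrapped in MODEL/ENDMDL records; a single
#' frame is written without them.  Coordinates are serialized at 3 decimals
#' (PDB fixed width), so a read/write round trip reproduces chain IDs,
#' residue keys, atom names and coordinates to 3 decimals.
#'
#' @param traj A trajectory or frame object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(traj, path) {
  if (inherits(traj, "sc_frame"))
    traj <- new_trajectory(traj$atoms,
                           array(traj$xyz, dim = c(nrow(traj$atoms), 3, 1)))
  at <- traj$atoms
  nf <- n_frames(traj)
  # atom names of <= 3 characters start at column 14 by PDB convention
  nm <- ifelse(nchar(at$atom_name) <= 3,
               formatC(paste0(" ", at$atom_name), width = -4),
               at$atom_name)
  el <- formatC(substr(at$element, 1, 2), width = 2)
  fixed <- sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   ",
                   at$serial %% 100000L, nm,
                   substr(at$alt_loc %||% "", 1, 1),
                   at$res_name, at$chain, at$res_seq, at$icode)
  out <- character(0)
  con <- file(path, "w")
  on.exit(close(con))
  ok <- tryCatch({
    for (f in seq_len(nf)) {
      xyz <- frame_xyz(traj, f)
      body <- paste0(fixed,
                     sprintf("%8.3f%8.3f%8.3f%6.2f%6.2f          %s",
                             xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, el))
      if (nf > 1) body <- c(sprintf("MODEL %8d", f), body, "ENDMDL")
      writeLines(body, con)
    }
    writeLines("END", con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_sctraj("sctraj_io", "cannot write PDB file: %s", path)
  invisible(path)
}

# Residue-level view of a frame: one row per residue in chain order, with the
# atom index ranges needed by the contact machinery.
frame_residues <- function(frame) {
  at <- frame$atoms
  uid <- residue_uid(at$chain, at$res_seq, at$icode)
  first <- !duplicated(uid)
  res <- data.frame(
    uid = uid[first],
    chain = at$chain[first],
    res_seq = at$res_seq[first],
    icode = at$icode[first],
    res_name = at$res_name[first],
    stringsAsFactors = FALSE
  )
  res$idx <- unname(split(seq_len(nrow(at)), factor(uid, levels = res$uid)))
  # position of each residue within its chain, in (res_seq, icode) order
  res$chain_pos <- stats::ave(seq_len(nrow(res)), res$chain,
                              FUN = seq_along)
  res
}

# Validate trajectory invariants (used on synthetic output and after reads).
validate_trajectory <- function(traj) {
  at <- traj$atoms
  stopifnot(is.array(traj$coords), dim(traj$coords)[1] == nrow(at),
            dim(traj$coords)[2] == 3)
  if (anyDuplicated(at$serial))
    stop_sctraj("sctraj_invalid", "duplicate atom serials")
  if (any(!is.finite(traj$coords)))
    stop_sctraj("sctraj_invalid", "non-finite coordinates")
  uid <- residue_uid(at$chain, at$res_seq, at$icode)
  heavy <- tapply(at$is_heavy, uid, any)
  if (any(!heavy))
    stop_sctraj("sctraj_invalid", "residue %s has no heavy atom",
                names(heavy)[!heavy][1])
  # per-chain residue order ascending in (res_seq, icode)
  res <- frame_residues(get_frame(traj, 1))
  for (ch in unique(res$chain)) {
    r <- res[res$chain == ch, ]
    o <- order(r$res_seq, r$icode)
    if (any(o != seq_len(nrow(r))))
      stop_sctraj("sctraj_invalid", "chain %s residues not in order", ch)
  }
  invisible(TRUE)
}
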