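# Structure and trajectory I/O: fixed-column PDB parsing, backbone amide
# donor/acceptor topology, geometric amide-hydrogen placement, and annotated
# PDB output. The multi-model PDB dialect is the package's interchange format
# for trajectories so that every pipeline stage is testable with text fixtures.

.BACKBONE_H_NAMES <- c("H", "HN")

#' Parse a PDB-format structure
#'
#' Reads fixed-column `ATOM`/`HETATM` records. For multi-model files only the
#' first model is returned; the total model count is recorded in `n_models`.
#' `HETATM` atoms (ligands, ions) are retained but flagged non-protein and
#' never contribute hydrogen-bond donors or acceptors.
#'
#' @param text PDB content: a single string (possibly with embedded newlines)
#'   or a character vector of lines.
#' @return An object of class `hdx_structure`: a list with `atoms` (data frame
#'   with columns `serial`, `name`, `element`, `res_index`, `res_name`,
#'   `chain`, `x`, `y`, `z`, `is_protein`), `n_residues` (protein residues in
#'   the first model) and `n_models`.
#' @examples
#' s <- parse_pdb(c(
#'   "ATOM      1  N   GLY A   1       0.000   0.000   0.000           N",
#'   "ATOM      2  CA  GLY A   1       1.458   0.000   0.000           C"
#' ))
#' s$n_residues
#' @export
parse_pdb <- function(text) {
  lines <- .as_lines(text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  n_models <- if (length(model_starts) > 0L) length(model_starts) else 1L
  keep <- is_atom
  if (length(model_ends) > 0L) {
    # atoms of the first model only
    keep <- is_atom & seq_along(lines) < model_ends[1L]
  }
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop("empty structure: no ATOM/HETATM records found", call. = FALSE)
  }
  atoms <- .parse_atom_lines(lines[idx], idx)
  new_structure(atoms, n_models = n_models)
}

#' @rdname parse_pdb
#' @param path Path to a PDB file.
#' @export
read_structure <- function(path) {
  parse_pdb(readLines(path, warn = FALSE))
}

# Internal constructor; counts protein residues as unique (chain, res_index).
new_structure <- function(atoms, n_models = 1L) {
  prot <- atoms[atoms$is_protein, , drop = FALSE]
  n_res <- nrow(unique(prot[, c("chain", "res_index")]))
  structure(
    list(atoms = atoms, n_residues = n_res, n_models = as.integer(n_models)),
    class = "hdx_structure"
  )
}

#' @export
print.hdx_structure <- function(x, ...) {
  cat(sprintf(
    "<hdx_structure> %d atoms, %d protein residues, %d model(s) in source\n",
    nrow(x$atoms), x$n_residues, x$n_models
  ))
  invisible(x)
}

.as_lines <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  text
}

.parse_atom_lines <- function(lines, line_numbers) {
  f <- function(from, to) substr(lines, from, to)
  num <- function(s, what, from) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)))
    if (length(bad) > 0L) {
      stop(sprintf(
        "malformed %s field at line %d: '%s'",
        what, line_numbers[bad[1L]], trimws(s[bad[1L]])
      ), call. = FALSE)
    }
    v
  }
  serial <- as.integer(num(f(7, 11), "serial", 7))
  name <- trimws(f(13, 16))
  res_name <- trimws(f(18, 20))
  chain <- substr(lines, 22, 22)
  res_index <- as.integer(num(f(23, 26), "residue-number", 23))
  x <- num(f(31, 38), "x-coordinate", 31)
  y <- num(f(39, 46), "y-coordinate", 39)
  z <- num(f(47, 54), "z-coordinate", 47)
  element <- trimws(f(77, 78))
  no_el <- !nzchar(element)
  element[no_el] <- substr(name[no_el], 1, 1)
  data.frame(
    serial = serial, name = name, element = element,
    res_index = res_index, res_name = res_name, chain = chain,
    x = x, y = y, z = z,
    is_protein = substr(lines, 1, 6) == "ATOM  ",
    stringsAsFactors = FALSE
  )
}

#' Read a multi-model PDB trajectory
#'
#' Each `MODEL`/`ENDMDL` block is one frame. All models must contain the same
#' number of atoms in the same order; a mismatch raises a dimension error. A
#' file without `MODEL` records is read as a single-frame trajectory.
#'
#' @param text PDB content (string or character vector of lines).
#' @param state State label, `"free"` or `"bound"`.
#' @param replicate_id Integer replicate identifier.
#' @param frame_spacing Time between frames, ns.
#' @return An object of class `hdx_trajectory`: list with `frames` (array
#'   `F x n_atoms x 3`, Angstrom), `structure` (first-model [parse_pdb()]
#'   result), `frame_spacing`, `replicate_id`, `state`, `F`.
#' @export
read_trajectory <- function(text, state = c("free", "bound"), replicate_id = 1L,
                            frame_spacing = 1) {
  state <- match.arg(state)
  lines <- .as_lines(text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec) == "MODEL")
  idx <- which(is_atom)
  if (length(idx) == 0L) {
    stop("empty trajectory: no ATOM/HETATM records found", call. = FALSE)
  }
  if (length(model_starts) == 0L) {
    frame_of <- rep.int(1L, length(idx))
    n_frames <- 1L
  } else {
    frame_of <- findInterval(idx, model_starts)
    if (any(frame_of == 0L)) {
      stop("ATOM records found before the first MODEL record", call. = FALSE)
    }
    n_frames <- length(model_starts)
  }
  counts <- tabulate(frame_of, nbins = n_frames)
  if (length(unique(counts)) != 1L) {
    stop(sprintf(
      "inconsistent atom count across models: %s",
      paste(unique(counts), collapse = " vs ")
    ), call. = FALSE)
  }
  atoms <- .parse_atom_lines(lines[idx], idx)
  n_atoms <- counts[1L]
  frames <- array(NA_real_, dim = c(n_frames, n_atoms, 3L))
  ord <- order(frame_of)          # already ordered, kept for safety
  coords <- as.matrix(atoms[ord, c("x", "y", "z")])
  for (k in seq_len(3L)) {
    frames[, , k] <- matrix(coords[, k], nrow = n_frames, ncol = n_atoms,
                            byrow = TRUE)
  }
  ref <- new_structure(atoms[seq_len(n_atoms), , drop = FALSE], n_models = n_frames)
  new_trajectory(frames, ref, state, replicate_id, frame_spacing)
}

new_trajectory <- function(frames, structure, state, replicate_id,
                           frame_spacing = 1) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[1L] >= 1L)
  structure(
    list(
      frames = frames, structure = structure, frame_spacing = frame_spacing,
      replicate_id = as.integer(replicate_id), state = state,
      F = dim(frames)[1L]
    ),
    class = "hdx_trajectory"
  )
}

#' @export
print.hdx_trajectory <- function(x, ...) {
  cat(sprintf(
    "<hdx_trajectory> state=%s replicate=%d frames=%d atoms=%d (dt=%g ns)\n",
    x$state, x$replicate_id, x$F, dim(x$frames)[2L], x$frame_spacing
  ))
  invisible(x)
}

# Eligible donor residues: protein residues that are preceded by residue
# index-1 in the same chain (so chain starts and residues after a chain break
# carry no donor) and that are not proline.
.donor_candidates <- function(atoms) {
  prot <- atoms[atoms$is_protein, , drop = FALSE]
  res <- unique(prot[, c("chain", "res_index", "res_name")])
  key <- paste(res$chain, res$res_index)
  has_prev <- paste(res$chain, res$res_index - 1L) %in% key
  res[has_prev & res$res_name != "PRO", , drop = FALSE]
}

.atom_row <- function(atoms, chain, res_index, names) {
  which(atoms$chain == chain & atoms$res_index == res_index &
          atoms$name %in% names & atoms$is_protein)
}

#' Derive the backbone amide donor/acceptor topology
#'
#' Donors are the backbone amide N-H groups of every protein residue except
#' chain-initial residues (free N-terminus), residues directly after a chain
#' break, and prolines. Acceptors are the backbone carbonyl oxygens of every
#' protein residue. Ligand (`HETATM`) atoms never contribute.
#'
#' @param s An `hdx_structure`.
#' @return Object of class `hdx_topology`: list with data frames `donors`
#'   (`res_index`, `chain`, `res_name`, `n_idx`, `h_idx`) and `acceptors`
#'   (`res_index`, `chain`, `res_name`, `o_idx`); indices are row numbers into
#'   `s$atoms`.
#' @seealso [place_amide_hydrogens()] for structures lacking amide hydrogens.
#' @export
build_topology <- function(s) {
  stopifnot(inherits(s, "hdx_structure"))
  atoms <- s$atoms
  cand <- .donor_candidates(atoms)
  if (nrow(cand) > 0L) {
    n_idx <- integer(nrow(cand))
    h_idx <- integer(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ni <- .atom_row(atoms, cand$chain[i], cand$res_index[i], "N")
      hi <- .atom_row(atoms, cand$chain[i], cand$res_index[i], .BACKBONE_H_NAMES)
      n_idx[i] <- if (length(ni) > 0L) ni[1L] else NA_integer_
      h_idx[i] <- if (length(hi) > 0L) hi[1L] else NA_integer_
    }
    missing_h <- cand$res_index[!is.na(n_idx) & is.na(h_idx)]
    if (length(missing_h) > 0L) {
      stop(sprintf(
        "missing amide hydrogen for donor residue(s): %s; run place_amide_hydrogens() first",
        paste(missing_h, collapse = ", ")
      ), call. = FALSE)
    }
    ok <- !is.na(n_idx)
    donors <- data.frame(
      res_index = cand$res_index[ok], chain = cand$chain[ok],
      res_name = cand$res_name[ok],
      n_idx = n_idx[ok], h_idx = h_idx[ok], stringsAsFactors = FALSE
    )
  } else {
    donors <- data.frame(
      res_index = integer(), chain = character(), res_name = character(),
      n_idx = integer(), h_idx = integer(), stringsAsFactors = FALSE
    )
  }
  o_rows <- which(atoms$is_protein & atoms$name == "O")
  acceptors <- data.frame(
    res_index = atoms$res_index[o_rows], chain = atoms$chain[o_rows],
    res_name = atoms$res_name[o_rows], o_idx = o_rows,
    stringsAsFactors = FALSE
  )
  donors <- donors[order(donors$chain, donors$res_index), , drop = FALSE]
  acceptors <- acceptors[order(acceptors$chain, acceptors$res_index), , drop = FALSE]
  rownames(donors) <- rownames(acceptors) <- NULL
  structure(list(donors = donors, acceptors = acceptors), class = "hdx_topology")
}

#' @export
print.hdx_topology <- function(x, ...) {
  cat(sprintf("<hdx_topology> %d amide donors, %d carbonyl acceptors\n",
              nrow(x$donors), nrow(x$acceptors)))
  invisible(x)
}

#' Place missing backbone amide hydrogens
#'
#' For each eligible donor residue (non-proline, residue i >= 2 of a chain)
#' without an amide H, an H atom is added at 1.01 Angstrom from N along the
#' direction opposite the bisector of the C(i-1)->N and CA->N unit vectors,
#' in the C(i-1)-N-CA plane. This is the standard geometric construction for
#' evaluating amide hydrogen bonds on crystal structures deposited without
#' hydrogens.
#'
#' @param s An `hdx_structure`.
#' @param nh_length N-H bond length, Angstrom.
#' @return A new `hdx_structure` with hydrogens added (atom serials
#'   renumbered); residues that already have an amide H are untouched.
#' @export
place_amide_hydrogens <- function(s, nh_length = 1.01) {
  stopifnot(inherits(s, "hdx_structure"))
  atoms <- s$atoms
  cand <- .donor_candidates(atoms)
  add <- list()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chain[i]; ri <- cand$res_index[i]
    if (length(.atom_row(atoms, ch, ri, .BACKBONE_H_NAMES)) > 0L) next
    ni <- .atom_row(atoms, ch, ri, "N")
    cai <- .atom_row(atoms, ch, ri, "CA")
    cprev <- .atom_row(atoms, ch, ri - 1L, "C")
    if (length(ni) == 0L || length(cai) == 0L || length(cprev) == 0L) {
      stop(sprintf(
        "cannot place amide hydrogen for residue %s:%d: missing N, CA or preceding C",
        ch, ri
      ), call. = FALSE)
    }
    n <- as.numeric(atoms[ni[1L], c("x", "y", "z")])
    ca <- as.numeric(atoms[cai[1L], c("x", "y", "z")])
    cp <- as.numeric(atoms[cprev[1L], c("x", "y", "z")])
    u1 <- .unit(cp - n)
    u2 <- .unit(ca - n)
    dir <- -.unit(u1 + u2)
    h <- n + nh_length * dir
    row <- atoms[ni[1L], , drop = FALSE]
    row$name <- "H"; row$element <- "H"
    row$x <- h[1L]; row$y <- h[2L]; row$z <- h[3L]
    add[[length(add) + 1L]] <- list(after = ni[1L], row = row)
  }
  if (length(add) == 0L) return(s)
  # insert each H directly after its amide N, keeping residue grouping
  pos <- vapply(add, function(a) a$after, numeric(1))
  rows <- do.call(rbind, lapply(add, function(a) a$row))
  ord <- order(c(seq_len(nrow(atoms)), pos + 0.5))
  out <- rbind(atoms, rows)[ord, , drop = FALSE]
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  new_structure(out, n_models = s$n_models)
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("zero-length vector in geometric construction", call. = FALSE)
  v / n
}

.format_atom_lines <- function(atoms, bfac = NULL) {
  if (is.null(bfac)) bfac <- rep(0, nrow(atoms))
  name4 <- ifelse(nchar(atoms$name) >= 4L, substr(atoms$name, 1, 4),
                  sprintf(" %-3s", atoms$name))
  sprintf(
    "%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$is_protein, "ATOM", "HETATM"),
    atoms$serial %% 100000L, name4, atoms$res_name, atoms$chain,
    atoms$res_index, atoms$x, atoms$y, atoms$z, 1, bfac, atoms$element
  )
}

#' Write a structure as PDB text
#'
#' @param s An `hdx_structure`.
#' @param path Optional file path; if `NULL` the PDB text is returned.
#' @return Invisibly (or visibly when `path` is `NULL`) a single PDB string.
#' @export
write_pdb <- function(s, path = NULL) {
  txt <- paste(c(.format_atom_lines(s$atoms), "END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Every atom of residue `i` receives B-factor `100 * value[i]`, clipped to
#' `[-99.99, 999.99]` and formatted to two decimals in columns 61-66; residues
#' absent from the mapping get `0.00`. Used to project per-residue occupancy
#' or deuteration differences onto a 3D structure for visualization.
#'
#' @param s An `hdx_structure`.
#' @param residue_values Named numeric vector: names are residue indices,
#'   values the per-residue quantity (e.g. delta occupancy).
#' @param path Optional output file path.
#' @return PDB text (invisibly when written to `path`).
#' @export
write_bfactor_pdb <- function(s, residue_values, path = NULL) {
  vals <- rep(0, nrow(s$atoms))
  if (length(residue_values) > 0L) {
    stopifnot(all(is.finite(residue_values)))
    m <- match(as.character(s$atoms$res_index), names(residue_values))
    vals[!is.na(m)] <- residue_values[m[!is.na(m)]]
  }
  b <- pmin(pmax(100 * vals, -99.99), 999.99)
  txt <- paste(c(.format_atom_lines(s$atoms, bfac = b), "END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Write a trajectory as multi-model PDB text
#'
#' @param traj An `hdx_trajectory`.
#' @param path Optional output path.
#' @return PDB text with one `MODEL`/`ENDMDL` block per frame.
#' @export
write_trajectory <- function(traj, path = NULL) {
  atoms <- traj$structure$atoms
  blocks <- character(traj$F)
  for (f in seq_len(traj$F)) {
    a <- atoms
    a$x <- traj$frames[f, , 1L]
    a$y <- traj$frames[f, , 2L]
    a$z <- traj$frames[f, , 3L]
    blocks[f] <- paste(
      c(sprintf("MODEL     %4d", f), .format_atom_lines(a), "ENDMDL"),
      collapse = "\n"
    )
  }
  txt <- paste(c(blocks, "END"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
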