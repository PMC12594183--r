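#' @title Atomic structures and multi-frame coordinate sets
#'
#' @description
#' `anchordock` stores an atomic model as a `struct` object: an atom table
#' (one row per atom, in file order) plus an `xyz` coordinate matrix with one
#' row per frame and three columns (x, y, z) per atom, so a multi-model PDB
#' becomes a trajectory sharing a single topology. Residue identity is the
#' triple (chain, resseq, icode); numbering is taken verbatim from the file
#' (an integer offset can be applied downstream when a different isoform
#' numbering is wanted).
#'
#' @param atoms data.frame with columns `record`, `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resseq`, `icode`, `occupancy`, `element`.
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms`, column order
#'   (x1, y1, z1, x2, ...).
#' @return A `struct` object.
#' @examples
#' s <- new_struct(
#'   data.frame(record = "ATOM", serial = 1L, name = "CA", altloc = "",
#'              resname = "GLY", chain = "A", resseq = 1L, icode = "",
#'              occupancy = 1, element = "C"),
#'   matrix(c(1, 2, 3), nrow = 1))
#' natoms(s)
#' @export
new_struct <- function(atoms, xyz) {
  xyz <- matrix(as.numeric(xyz), nrow = if (is.matrix(xyz)) nrow(xyz) else 1L)
  stopifnot(is.data.frame(atoms), ncol(xyz) == 3L * nrow(atoms))
  if (nrow(atoms) > 0 && any(!is.finite(xyz)))
    stop("non-finite coordinates in structure")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz), class = "struct")
}

#' @rdname new_struct
#' @param x a `struct`.
#' @export
natoms <- function(x) nrow(x$atoms)

#' @rdname new_struct
#' @export
nframes <- function(x) nrow(x$xyz)

#' Coordinates of one frame as an n x 3 matrix
#'
#' @param x a `struct`.
#' @param frame frame index (1-based).
#' @return numeric matrix with one row per atom.
#' @export
coords <- function(x, frame = 1L) {
  stopifnot(frame >= 1L, frame <= nframes(x))
  matrix(x$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

#' Replace the coordinates of one frame
#'
#' @inheritParams coords
#' @param value n x 3 coordinate matrix.
#' @return the modified `struct`.
#' @export
set_coords <- function(x, value, frame = 1L) {
  stopifnot(nrow(value) == natoms(x), ncol(value) == 3L)
  x$xyz[frame, ] <- as.numeric(t(value))
  x
}

#' @export
print.struct <- function(x, ...) {
  cat(sprintf("<struct> %d atoms, %d frame(s), chains: %s\n", natoms(x),
              nframes(x), paste(unique(x$atoms$chain), collapse = " ")))
  invisible(x)
}

# --- PDB parsing -----------------------------------------------------------

.parse_atom_line <- function(line, lineno) {
  f <- function(a, b) trimws(substr(line, a, b))
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (any(is.na(xyz)))
    stop(sprintf("malformed coordinate field at line %d", lineno))
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  serial <- suppressWarnings(as.integer(f(7, 11)))
  resseq <- suppressWarnings(as.integer(f(23, 26)))
  if (is.na(resseq))
    stop(sprintf("malformed residue number at line %d", lineno))
  elem <- f(77, 78)
  name <- f(13, 16)
  if (!nzchar(elem)) {
    # fall back to first alphabetic character of the atom name
    elem <- sub("^[0-9']*", "", name)
    elem <- toupper(substr(elem, 1, 1))
  }
  list(record = f(1, 6), serial = serial, name = name, altloc = f(17, 17),
       resname = f(18, 20), chain = f(22, 22), resseq = resseq,
       icode = f(27, 27), x = xyz[1], y = xyz[2], z = xyz[3],
       occupancy = if (is.na(occ)) 1 else occ, element = toupper(elem))
}

# Altloc policy: keep the highest-occupancy alternate per
# (chain, resseq, icode, atom name); ties broken by altloc label order.
.filter_altloc <- function(df) {
  key <- paste(df$chain, df$resseq, df$icode, df$name, sep = "\r")
  ord <- order(key, -df$occupancy, df$altloc)
  keep <- ord[!duplicated(key[ord])]
  df[sort(keep), , drop = FALSE]
}

#' Read a (possibly multi-model) PDB file
#'
#' Fixed-column ATOM/HETATM records are parsed; MODEL/ENDMDL blocks become
#' coordinate frames sharing one topology. Hydrogens and HETATM records are
#' retained (distance-based analyses exclude them by default). When an atom
#' has alternate locations, the highest-occupancy altloc is kept, ties broken
#' by label order, so the topology is a single conformer.
#'
#' @param path path to a PDB file.
#' @return a [new_struct()] `struct`; `nframes()` gives the model count.
#' @seealso [write_pdb()], [select_atoms()]
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(rec, 1, 4) == "ATOM" |
    rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model)
  if (all(model_id[is_atom] == 0)) model_id[is_atom] <- 1L
  model_id[is_atom & model_id == 0] <- 1L

  idx <- which(is_atom)
  parsed <- lapply(idx, function(i) .parse_atom_line(lines[i], i))
  df <- do.call(rbind, lapply(parsed, function(p) as.data.frame(p)))
  df$model <- model_id[idx]

  models <- split(df, df$model)
  models <- lapply(models, .filter_altloc)
  n0 <- nrow(models[[1]])
  counts <- vapply(models, nrow, 0L)
  if (any(counts != n0))
    stop(sprintf("topology error: atom counts differ across models (%s)",
                 paste(counts, collapse = ", ")))
  sig <- function(m) paste(m$chain, m$resseq, m$icode, m$name, collapse = "|")
  if (length(models) > 1 &&
      any(vapply(models[-1], sig, "") != sig(models[[1]])))
    stop("topology error: atom identities differ across models")

  atoms <- models[[1]][c("record", "serial", "name", "altloc", "resname",
                         "chain", "resseq", "icode", "occupancy", "element")]
  xyz <- t(vapply(models, function(m) as.numeric(t(cbind(m$x, m$y, m$z))),
                  numeric(3L * n0)))
  new_struct(atoms, xyz)
}

#' Write a structure to PDB format
#'
#' Multi-frame structures are written as MODEL/ENDMDL blocks. Coordinates are
#' serialised in the fixed 8.3 columns, so a read-back preserves them to three
#' decimals.
#'
#' @param x a `struct`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  stopifnot(inherits(x, "struct"), natoms(x) > 0)
  a <- x$atoms
  name4 <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  name4 <- formatC(name4, width = -4)
  multi <- nframes(x) > 1
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (fr in seq_len(nframes(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", fr), con)
    xyzm <- coords(x, fr)
    writeLines(sprintf(
      "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial %% 100000L, name4, a$altloc, a$resname, a$chain,
      a$resseq %% 10000L, a$icode, xyzm[, 1], xyzm[, 2], xyzm[, 3],
      a$occupancy, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- Selections ------------------------------------------------------------

#' Atom selections
#'
#' A `selection` is a predicate over (chain, residue range, atom-name set,
#' record type, element); [select_atoms()] applies it, preserving atom order.
#' An empty match is legal and yields a zero-atom structure.
#'
#' @param chain chain identifier(s), or NULL for any.
#' @param resseq residue numbers (any integer vector, e.g. `266:270`), or NULL.
#' @param atoms atom-name set (e.g. `c("N","CA","C","O")`), or NULL.
#' @param het `NA` keeps both ATOM and HETATM; `TRUE`/`FALSE` restricts.
#' @param hydrogens keep hydrogen atoms (element H)? Default TRUE.
#' @return an object of class `selection`.
#' @examples
#' sel_backbone("A")
#' @export
selection <- function(chain = NULL, resseq = NULL, atoms = NULL, het = NA,
                      hydrogens = TRUE) {
  structure(list(chain = chain, resseq = resseq, atoms = atoms, het = het,
                 hydrogens = hydrogens), class = "selection")
}

#' @rdname selection
#' @export
sel_backbone <- function(chain = NULL, resseq = NULL)
  selection(chain = chain, resseq = resseq, atoms = c("N", "CA", "C", "O"),
            het = FALSE)

#' @rdname selection
#' @export
sel_calpha <- function(chain = NULL, resseq = NULL)
  selection(chain = chain, resseq = resseq, atoms = "CA", het = FALSE)

#' @rdname selection
#' @param x a `struct`.
#' @param sel a `selection`.
#' @return `select_idx`: integer atom indices; `select_atoms`: sub-`struct`.
#' @export
select_idx <- function(x, sel) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$resseq)) keep <- keep & a$resseq %in% sel$resseq
  if (!is.null(sel$atoms)) keep <- keep & a$name %in% sel$atoms
  if (!is.na(sel$het)) keep <- keep & ((a$record == "HETATM") == sel$het)
  if (!sel$hydrogens) keep <- keep & a$element != "H"
  which(keep)
}

#' @rdname selection
#' @export
select_atoms <- function(x, sel) {
  i <- select_idx(x, sel)
  cols <- as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))
  new_struct(x$atoms[i, , drop = FALSE],
             x$xyz[, cols, drop = FALSE])
}

# Heavy (non-hydrogen) protein-atom indices, the default set for
# distance-based analyses.
heavy_idx <- function(x, het = FALSE) {
  keep <- x$atoms$element != "H"
  if (!is.na(het)) keep <- keep & ((x$atoms$record == "HETATM") == het)
  which(keep)
}

# Stack single-frame structs sharing a topology into one multi-frame struct.
bind_frames <- function(structs) {
  stopifnot(length(structs) >= 1)
  xyz <- do.call(rbind, lapply(structs, function(s) s$xyz))
  new_struct(structs[[1]]$atoms, xyz)
}

# Concatenate the atoms of several single-frame structs (distinct chains).
cat_structs <- function(structs) {
  atoms <- do.call(rbind, lapply(structs, function(s) s$atoms))
  xyz <- matrix(unlist(lapply(structs, function(s) s$xyz[1, ])), nrow = 1)
  new_struct(atoms, xyz)
}
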