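# PDBQT reading and writing (AutoDock dialect).
#
# A receptor is a rigid, ordered set of typed, partially charged atoms; a
# ligand adds a torsion tree (rigid ROOT plus nested BRANCH records, one
# rotatable bond each). Only the first MODEL of a multi-model file is read.

parse_pdbqt_atoms <- function(lines, linenos, strict = FALSE) {
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(serial = integer(0), name = character(0),
                      type = character(0), charge = numeric(0)))
  }
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) {
      stop("cannot parse ", what, " on line ", ln[which(is.na(v))[1]])
    }
    v
  }
  x <- num(substr(lines, 31, 38), "x coordinate", linenos)
  y <- num(substr(lines, 39, 46), "y coordinate", linenos)
  z <- num(substr(lines, 47, 54), "z coordinate", linenos)
  serial <- suppressWarnings(as.integer(substr(lines, 7, 11)))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  name <- trimws(substr(lines, 13, 16))
  if (strict) {
    charge <- num(substr(lines, 71, 76), "charge", linenos)
    type <- trimws(substr(lines, 78, 79))
  } else {
    # tolerant mode: last two whitespace-delimited fields are charge and type
    toks <- strsplit(trimws(lines), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 2L)) stop("garbled record on line ", linenos[which(nt < 2L)[1]])
    type <- mapply(function(t, k) t[k], toks, nt)
    charge <- num(mapply(function(t, k) t[k - 1L], toks, nt), "charge", linenos)
  }
  if (any(!nzchar(type))) {
    stop("missing atom type on line ", linenos[which(!nzchar(type))[1]])
  }
  atoms <- data.frame(serial = serial, name = name, type = type,
                      charge = charge, stringsAsFactors = FALSE)
  attr(atoms, "coords") <- matrix(c(x, y, z), ncol = 3)
  atoms
}

check_atom_types <- function(types, forcefield) {
  if (is.null(forcefield)) return(invisible())
  bad <- setdiff(unique(types), forcefield$types$type)
  if (length(bad)) {
    stop("unknown atom type(s): ", paste(bad, collapse = ", "),
         "; known types: ", paste(forcefield$types$type, collapse = ", "))
  }
  invisible()
}

first_model_lines <- function(lines) {
  endm <- grep("^ENDMDL", lines)
  if (length(endm)) lines <- lines[seq_len(endm[1] - 1L)]
  lines
}

#' Read a rigid receptor from a PDBQT file
#'
#' Accepts both `ATOM` and `HETATM` records; `REMARK`/`MODEL` wrappers are
#' ignored and only the first model of a multi-model file is used.
#' Coordinates are read from the fixed PDB columns; by default the partial
#' charge and AutoDock atom type are taken from the last two
#' whitespace-delimited fields of each record (set `strict = TRUE` to require
#' the exact PDBQT columns 71-76 and 78-79).
#'
#' @param path File path.
#' @param forcefield A [load_forcefield()] table used to validate atom types,
#'   or `NULL` to skip validation.
#' @param strict Require fixed-column charge/type fields.
#' @return An object of class `receptor`: atom table plus an N x 3 coordinate
#'   matrix (Angstrom).
#' @export
read_pdbqt_receptor <- function(path, forcefield = load_forcefield(),
                                strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- first_model_lines(readLines(path, warn = FALSE))
  sel <- grep("^(ATOM|HETATM)", lines)
  if (length(sel) == 0L) stop("empty receptor: no ATOM/HETATM records in ", path)
  atoms <- parse_pdbqt_atoms(lines[sel], sel, strict)
  check_atom_types(atoms$type, forcefield)
  structure(list(atoms = atoms, coords = attr(atoms, "coords")),
            class = "receptor")
}

#' @export
print.receptor <- function(x, ...) {
  cat("<receptor>", nrow(x$atoms), "atoms, types:",
      paste(sort(unique(x$atoms$type)), collapse = " "), "\n")
  invisible(x)
}

#' Read a flexible ligand from a PDBQT file
#'
#' Parses the atoms together with the torsion tree: the rigid `ROOT` block and
#' nested `BRANCH serial_a serial_b` / `ENDBRANCH` records, each branch being
#' one rotatable bond whose rotation moves every atom in its subtree. The
#' number of torsional degrees of freedom `T` equals the number of `BRANCH`
#' records; a `TORSDOF` record is stored when present.
#'
#' @inheritParams read_pdbqt_receptor
#' @return An object of class `ligand` with the atom table, the reference
#'   (input-file) coordinates, the torsion tree and `n_torsions`.
#' @export
read_pdbqt_ligand <- function(path, forcefield = load_forcefield(),
                              strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- first_model_lines(readLines(path, warn = FALSE))

  atom_lines <- character(0)
  atom_linenos <- integer(0)
  # group: 0 = root, j > 0 = branch j (innermost)
  atom_group <- integer(0)
  branches <- list()       # list(axis_from_serial, axis_to_serial, parent)
  stack <- integer(0)      # branch indices, innermost last
  in_root <- FALSE
  seen_root <- FALSE

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^ROOT", line)) {
      if (seen_root) stop("second ROOT record on line ", ln)
      in_root <- TRUE
      seen_root <- TRUE
    } else if (grepl("^ENDROOT", line)) {
      if (!in_root) stop("ENDROOT without ROOT on line ", ln)
      in_root <- FALSE
    } else if (grepl("^BRANCH", line)) {
      f <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(f) < 3L) stop("BRANCH record missing serials on line ", ln)
      branches[[length(branches) + 1L]] <-
        list(axis_from_serial = as.integer(f[2]),
             axis_to_serial = as.integer(f[3]),
             parent = if (length(stack)) stack[length(stack)] else 0L)
      stack <- c(stack, length(branches))
    } else if (grepl("^ENDBRANCH", line)) {
      if (length(stack) == 0L) stop("unmatched ENDBRANCH on line ", ln)
      stack <- stack[-length(stack)]
    } else if (grepl("^(ATOM|HETATM)", line)) {
      atom_lines <- c(atom_lines, line)
      atom_linenos <- c(atom_linenos, ln)
      atom_group <- c(atom_group,
                      if (length(stack)) stack[length(stack)] else 0L)
    }
  }
  if (length(stack)) stop("unmatched BRANCH: ", length(stack), " unclosed")
  if (length(atom_lines) == 0L) stop("empty ligand: no ATOM/HETATM records in ",
                                     path)
  atoms <- parse_pdbqt_atoms(atom_lines, atom_linenos, strict)
  check_atom_types(atoms$type, forcefield)
  coords <- attr(atoms, "coords")

  torsdof <- NA_integer_
  td <- grep("^TORSDOF", lines, value = TRUE)
  if (length(td)) torsdof <- as.integer(strsplit(trimws(td[1]), "\\s+")[[1]][2])

  # resolve branch axis serials to atom indices and collect moved subtrees
  for (j in seq_along(branches)) {
    b <- branches[[j]]
    a <- match(b$axis_from_serial, atoms$serial)
    bb <- match(b$axis_to_serial, atoms$serial)
    if (is.na(a) || is.na(bb)) {
      stop("branch axis references missing atom serial ",
           if (is.na(a)) b$axis_from_serial else b$axis_to_serial)
    }
    branches[[j]]$axis_from <- a
    branches[[j]]$axis_to <- bb
    branches[[j]]$atoms <- which(atom_group == j)
  }
  # subtree of branch j = its own rigid group plus all descendants' groups
  desc <- function(j) {
    kids <- which(vapply(branches, function(b) b$parent, 0L) == j)
    sort(c(which(atom_group == j), unlist(lapply(kids, desc), use.names = FALSE)))
  }
  for (j in seq_along(branches)) branches[[j]]$subtree <- desc(j)

  structure(list(atoms = atoms, coords = coords,
                 root = which(atom_group == 0L),
                 groups = atom_group,
                 branches = branches,
                 n_torsions = length(branches),
                 torsdof = torsdof),
            class = "ligand")
}

#' @export
print.ligand <- function(x, ...) {
  cat("<ligand>", nrow(x$atoms), "atoms,", x$n_torsions,
      "rotatable bonds (root:", length(x$root), "atoms)\n")
  invisible(x)
}

format_pdbqt_atom <- function(serial, name, res, x, y, z, charge, type) {
  sprintf("%-6s%5d %-4s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          "ATOM", serial, name, res, "A", 1L, x, y, z, 1.00, 0.00, charge, type)
}

#' Write a receptor or ligand to a PDBQT file
#'
#' Ligands are written with their full `ROOT`/`BRANCH` torsion-tree structure
#' (parent atoms before child branches) and a `TORSDOF` record; coordinates
#' default to the stored reference coordinates but any pose matrix with the
#' same atom order may be substituted, e.g. a docked pose from [dock()].
#'
#' @param x A `receptor` or `ligand`.
#' @param path Output file path.
#' @param coords Optional N x 3 replacement coordinates.
#' @return `path`, invisibly.
#' @export
write_pdbqt <- function(x, path, coords = NULL) UseMethod("write_pdbqt")

#' @export
write_pdbqt.receptor <- function(x, path, coords = NULL) {
  xyz <- coords %||% x$coords
  stopifnot(nrow(xyz) == nrow(x$atoms))
  out <- format_pdbqt_atom(x$atoms$serial, x$atoms$name, "REC",
                           xyz[, 1], xyz[, 2], xyz[, 3],
                           x$atoms$charge, x$atoms$type)
  writeLines(out, path)
  invisible(path)
}

#' @export
write_pdbqt.ligand <- function(x, path, coords = NULL) {
  xyz <- coords %||% x$coords
  stopifnot(nrow(xyz) == nrow(x$atoms))
  fmt <- function(i) format_pdbqt_atom(x$atoms$serial[i], x$atoms$name[i],
                                       "LIG", xyz[i, 1], xyz[i, 2], xyz[i, 3],
                                       x$atoms$charge[i], x$atoms$type[i])
  out <- c("ROOT", vapply(x$root, fmt, ""), "ENDROOT")
  emit_branch <- function(j) {
    b <- x$branches[[j]]
    head <- sprintf("BRANCH %d %d", x$atoms$serial[b$axis_from],
                    x$atoms$serial[b$axis_to])
    kids <- which(vapply(x$branches, function(z) z$parent, 0L) == j)
    body <- c(vapply(b$atoms, fmt, ""),
              unlist(lapply(kids, emit_branch), use.names = FALSE))
    c(head, body, sprintf("ENDBRANCH %d %d", x$atoms$serial[b$axis_from],
                          x$atoms$serial[b$axis_to]))
  }
  top <- which(vapply(x$branches, function(z) z$parent, 0L) == 0L)
  out <- c(out, unlist(lapply(top, emit_branch), use.names = FALSE))
  td <- if (is.na(x$torsdof)) x$n_torsions else x$torsdof
  out <- c(out, sprintf("TORSDOF %d", td))
  writeLines(out, path)
  invisible(path)
}
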