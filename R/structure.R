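## Structures: ordered heavy-atom lists with chain/residue/atom identity.
##
## A "memstruct" is a list with elements
##   atoms : data.frame(serial, name, element, resname, resno, chain, insert,
##                      x, y, z, record, is_bead)
##   label : character scalar
## Atom order is stable under read -> write -> read. PDB parsing and writing
## are delegated to bio3d; bead flagging, altloc resolution and element
## inference are handled here.

#' Default membrane-bead identifiers
#'
#' Residue names and atom names accepted as lipid phosphate beads. MARTINI
#' dialects label the phosphate head-group bead \code{PO4} (older forks use
#' \code{P} or \code{BJ}); the artificial bead residue is \code{MMB}.
#' @export
default_bead_names <- function() {
  list(residues = c("MMB"), atoms = c("PO4", "P", "BJ"))
}

new_structure <- function(atoms, label = "") {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, label = label), class = "memstruct")
}

#' Number of atoms in a structure
#' @param s a \code{memstruct}.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinates of a structure
#' @param s a \code{memstruct} (or a bead data.frame).
#' @return numeric matrix with one row per atom, columns x, y, z.
#' @export
coords <- function(s) {
  a <- if (inherits(s, "memstruct")) s$atoms else s
  as.matrix(a[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s a \code{memstruct}.
#' @param xyz numeric matrix, \code{n_atoms(s)} rows and 3 columns.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == n_atoms(s), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Geometric centre of a structure
#' @param s a \code{memstruct}.
#' @export
centroid <- function(s) colMeans(coords(s))

#' @export
print.memstruct <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("memswarm structure '%s': %d atoms, %d residues, chains: %s\n",
              x$label, nrow(a),
              length(unique(paste(a$chain, a$resno, a$insert))),
              paste(unique(a$chain), collapse = " ")))
  if (any(a$is_bead)) cat(sprintf("  membrane beads: %d\n", sum(a$is_bead)))
  invisible(x)
}

# Element from the PDB atom-name columns when the element field is blank.
# Two-letter elements relevant here (FE, ZN, MG, ...) are rare in this
# package's inputs; the rule: strip digits/primes, if the first character is
# H/D (or a digit-prefixed H as in 1HB2) the element is H, else the first
# alphabetic character.
infer_element <- function(name) {
  nm <- toupper(gsub("[0-9'\\*]", "", trimws(name)))
  el <- substr(nm, 1, 1)
  el[nchar(nm) == 0] <- ""
  el[substr(nm, 1, 1) %in% c("H", "D")] <- "H"
  el
}

is_bead_record <- function(record, resname, name, bead_names) {
  record == "HETATM" &
    (trimws(resname) %in% bead_names$residues |
       trimws(name) %in% bead_names$atoms)
}

#' Read a PDB structure
#'
#' Parses ATOM and HETATM records (other records are ignored). The first
#' altloc of each atom is kept; insertion codes are preserved verbatim.
#' HETATM records whose residue or atom name matches the configured bead set
#' are flagged as membrane beads.
#'
#' @param source path to a PDB file, or a character scalar/vector of PDB text.
#' @param label label stored on the structure (defaults to the file name).
#' @param bead_names list with elements \code{residues} and \code{atoms}
#'   naming the membrane-bead records; see \code{\link{default_bead_names}}.
#' @return a \code{memstruct}.
#' @export
read_pdb <- function(source, label = NULL, bead_names = default_bead_names()) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- basename(source)
  } else {
    lines <- unlist(strsplit(paste(source, collapse = "\n"), "\n", fixed = TRUE))
    if (is.null(label)) label <- "structure"
  }
  rec <- substr(lines, 1, 6)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (length(sel) == 0) stop("no ATOM/HETATM records found in input")
  # validate coordinate fields before handing off to the parser
  for (i in sel) {
    for (f in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(lines[i], f[1], f[2])))
      if (is.na(v))
        stop(sprintf("malformed coordinate field on line %d: '%s'",
                     i, lines[i]))
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE, multi = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  # keep the first altloc per (chain, resno, insert, atom name)
  key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
               a$elety, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep, , drop = FALSE]
  el <- ifelse(is.na(a$elesy) | trimws(a$elesy) == "",
               infer_element(a$elety), toupper(trimws(a$elesy)))
  atoms <- data.frame(
    serial = a$eleno,
    name = trimws(a$elety),
    element = el,
    resname = trimws(a$resid),
    resno = a$resno,
    chain = ifelse(is.na(a$chain), " ", a$chain),
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    record = a$type,
    stringsAsFactors = FALSE)
  atoms$is_bead <- is_bead_record(atoms$record, atoms$resname, atoms$name,
                                  bead_names)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in input")
  new_structure(atoms, label)
}

#' Write a structure to PDB
#'
#' Emits fixed-column ATOM/HETATM records (3-decimal coordinates) preserving
#' chain, residue and atom identity.
#'
#' @param s a \code{memstruct}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_pdb <- function(s, file) {
  a <- s$atoms
  xyz <- as.vector(t(coords(s)))
  bio3d::write.pdb(file = file, xyz = xyz, type = a$record,
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elesy = a$element)
  invisible(file)
}

#' Remove hydrogen (and deuterium) atoms
#'
#' The statistical potential used for docking does not support hydrogens, so
#' structures are reduced to heavy atoms before any scoring.
#'
#' @param s a \code{memstruct}.
#' @return heavy-atom \code{memstruct} with original atom order preserved.
#' @export
strip_hydrogens <- function(s) {
  keep <- s$atoms$element != "H"
  new_structure(s$atoms[keep, , drop = FALSE], s$label)
}

#' Rigid-body transform
#'
#' @param rotation unit quaternion, scalar first.
#' @param translation numeric length-3 vector (Angstrom).
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0),
                            translation = c(0, 0, 0)) {
  if (!quat_is_unit(rotation, 1e-6))
    stop("rotation quaternion is not unit-norm")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Compose two rigid transforms
#'
#' \code{compose_transforms(t2, t1)} applies \code{t1} first, then \code{t2}.
#' @param t2,t1 \code{rigid_transform} objects.
#' @export
compose_transforms <- function(t2, t1) {
  R2 <- quat_to_matrix(t2$rotation)
  rigid_transform(quat_multiply(t2$rotation, t1$rotation),
                  as.vector(R2 %*% t1$translation) + t2$translation)
}

#' Apply a rigid transform to a structure
#'
#' Coordinates are mapped by rotation-then-translation; intramolecular
#' distances are preserved to numerical precision.
#'
#' @param s a \code{memstruct}.
#' @param t a \code{rigid_transform}.
#' @return transformed \code{memstruct}.
#' @export
apply_transform <- function(s, t) {
  if (!quat_is_unit(t$rotation, 1e-6))
    stop("rotation quaternion is not unit-norm")
  R <- quat_to_matrix(t$rotation)
  xyz <- coords(s) %*% t(R)
  xyz <- sweep(xyz, 2, t$translation, "+")
  set_coords(s, xyz)
}

#' Flip a system for lower-leaflet targeting
#'
#' Rotates the whole structure 180 degrees about the x-axis, so that the lower
#' membrane leaflet becomes the upper one. Use when the binding-competent side
#' of the receptor faces the lower leaflet.
#'
#' @param s a \code{memstruct}.
#' @return flipped \code{memstruct}.
#' @export
flip_about_x <- function(s) {
  apply_transform(s, rigid_transform(quat_from_axis_angle(c(1, 0, 0), pi)))
}

# All pairwise distances between two coordinate matrices (rows = points).
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
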