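## Pose scoring: a distance-binned pairwise statistical potential over heavy
## atoms, with a reserved MEMBRANE_BEAD type whose entries carry a very
## unfavourable fixed value so that poses penetrating the membrane are driven
## away during the optimization. Higher score = better pose (the more
## negative, the worse).

#' Construct a potential table
#'
#' @param atom_types character vector of type labels; the reserved label
#'   \code{MEMBRANE_BEAD} is appended if absent.
#' @param bins increasing numeric vector of distance-bin edges (Angstrom);
#'   bin i covers [bins[i], bins[i+1]). The last edge is the interaction
#'   cutoff.
#' @param values numeric array \code{(ntypes, ntypes, nbins)} of scores,
#'   symmetric in the first two dimensions. Membrane-bead entries are
#'   overwritten with \code{membrane_penalty}.
#' @param membrane_penalty score for any pair involving a membrane bead
#'   (default -999.0).
#' @return object of class \code{potential_table}.
#' @export
potential_table <- function(atom_types, bins, values,
                            membrane_penalty = -999.0) {
  if (!"MEMBRANE_BEAD" %in% atom_types) {
    atom_types <- c(atom_types, "MEMBRANE_BEAD")
    v <- array(0, dim = c(length(atom_types), length(atom_types),
                          length(bins) - 1))
    v[seq_len(dim(values)[1]), seq_len(dim(values)[2]), ] <- values
    values <- v
  }
  nb <- length(bins) - 1
  stopifnot(nb >= 1, all(diff(bins) > 0),
            all(dim(values) == c(length(atom_types), length(atom_types), nb)))
  mb <- which(atom_types == "MEMBRANE_BEAD")
  values[mb, , ] <- membrane_penalty
  values[, mb, ] <- membrane_penalty
  if (any(!is.finite(values))) stop("potential values must be finite")
  # enforce symmetry
  for (k in seq_len(nb)) {
    values[, , k] <- (values[, , k] + t(values[, , k])) / 2
  }
  structure(list(atom_types = atom_types, bins = bins, values = values,
                 interaction_cutoff = bins[length(bins)],
                 membrane_penalty = membrane_penalty),
            class = "potential_table")
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf(
    "potential table: %d atom types, %d distance bins, cutoff %.1f A, bead penalty %.1f\n",
    length(x$atom_types), length(x$bins) - 1, x$interaction_cutoff,
    x$membrane_penalty))
  invisible(x)
}

#' Read a potential table from its plain-text format
#'
#' Format: comment lines start with \code{#}; then
#' \preformatted{
#' types <label> <label> ...
#' bins <edge> <edge> ...
#' membrane_penalty <value>
#' pair <type_i> <type_j> <v_bin1> <v_bin2> ...
#' }
#' Pairs not listed default to 0; membrane-bead rows are filled with the
#' penalty automatically.
#'
#' @param path file path.
#' @return a \code{potential_table}.
#' @export
read_potential_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  tok <- strsplit(lines, "[[:space:]]+")
  key <- vapply(tok, `[`, "", 1)
  types <- tok[[which(key == "types")]][-1]
  bins <- as.numeric(tok[[which(key == "bins")]][-1])
  penalty <- -999.0
  if (any(key == "membrane_penalty"))
    penalty <- as.numeric(tok[[which(key == "membrane_penalty")]][2])
  nb <- length(bins) - 1
  if (!"MEMBRANE_BEAD" %in% types) types <- c(types, "MEMBRANE_BEAD")
  vals <- array(0, dim = c(length(types), length(types), nb))
  for (t in tok[key == "pair"]) {
    i <- match(t[2], types); j <- match(t[3], types)
    if (is.na(i) || is.na(j))
      stop(sprintf("pair row references unknown type: %s %s", t[2], t[3]))
    v <- as.numeric(t[-(1:3)])
    if (length(v) != nb) stop("pair row has wrong number of bin values")
    vals[i, j, ] <- v
    vals[j, i, ] <- v
  }
  potential_table(types, bins, vals, penalty)
}

#' The shipped reduced contact potential
#'
#' A small residue-level contact potential over poly-alanine heavy-atom types
#' (N, CA, C, O, CB): clashing pairs are strongly unfavourable, contacts in
#' the 3.5-5 Angstrom shell most favourable, with mild bonuses for
#' hydrophobic (CB-CB) packing and backbone N-O hydrogen-bond geometry. It
#' exercises the full scoring contract without the published statistical
#' potential table, which can be supplied through
#' \code{\link{read_potential_table}}.
#'
#' @return a \code{potential_table}.
#' @export
default_potential_table <- function() {
  path <- system.file("extdata", "contact_potential.txt",
                      package = "memswarm", mustWork = TRUE)
  read_potential_table(path)
}

# Map atom records to table type labels; beads -> MEMBRANE_BEAD.
atom_types_for <- function(atoms, table) {
  ty <- ifelse(atoms$is_bead, "MEMBRANE_BEAD", atoms$name)
  idx <- match(ty, table$atom_types)
  if (anyNA(idx)) {
    bad <- atoms[is.na(idx), , drop = FALSE][1, ]
    stop(sprintf(
      "atom type '%s' (chain %s, residue %s %d) not in potential table",
      bad$name, bad$chain, bad$resname, bad$resno))
  }
  idx
}

#' Score a ligand pose
#'
#' Sums the potential-table value over all intermolecular receptor-ligand
#' heavy-atom pairs within the interaction cutoff. When
#' \code{penalty_enabled}, every ligand-atom/membrane-bead pair within
#' \code{penalty_cutoff} additionally contributes the membrane penalty, so
#' poses overlapping the bead bilayer score very poorly.
#'
#' @param receptor,ligand heavy-atom \code{memstruct}s (ligand in its
#'   reference frame).
#' @param pose a \code{rigid_transform} applied to the ligand, or \code{NULL}
#'   to score the ligand where it stands.
#' @param table a \code{potential_table}.
#' @param membrane optional \code{membrane_model} providing bead coordinates.
#' @param penalty_enabled logical; the bead penalty is active only in
#'   membrane mode (off in blind and filtered modes).
#' @param penalty_cutoff distance cutoff for bead contacts (default: the
#'   table's interaction cutoff).
#' @return numeric score; higher is better.
#' @export
score_pose <- function(receptor, ligand, pose = NULL, table,
                       membrane = NULL, penalty_enabled = FALSE,
                       penalty_cutoff = table$interaction_cutoff) {
  lig <- if (is.null(pose)) ligand else apply_transform(ligand, pose)
  ti <- atom_types_for(receptor$atoms, table)
  tj <- atom_types_for(lig$atoms, table)
  d <- cross_dist(coords(receptor), coords(lig))
  sel <- which(d < table$interaction_cutoff, arr.ind = TRUE)
  s <- 0
  if (nrow(sel) > 0) {
    bin <- findInterval(d[sel], table$bins)
    ok <- bin >= 1 & bin <= length(table$bins) - 1
    idx <- cbind(ti[sel[ok, 1]], tj[sel[ok, 2]], bin[ok])
    s <- sum(table$values[idx])
  }
  if (penalty_enabled && !is.null(membrane) && nrow(membrane$beads) > 0) {
    db <- cross_dist(coords(lig), coords(membrane$beads))
    s <- s + sum(db < penalty_cutoff) * table$membrane_penalty
  }
  s
}

#' Locally optimize a ligand pose against the potential
#'
#' Derivative-free (Nelder-Mead) maximization of \code{\link{score_pose}}
#' over the six rigid-body degrees of freedom, starting from \code{pose}.
#' Used to tighten cluster representatives before final ranking and to place
#' fixture native poses at a genuine optimum of the score landscape.
#' Deterministic.
#'
#' @inheritParams score_pose
#' @param pose starting \code{rigid_transform}.
#' @param maxit optimizer iteration budget; default 200.
#' @return list with \code{pose} (optimized \code{rigid_transform}) and
#'   \code{score}.
#' @export
optimize_pose <- function(receptor, ligand, pose, table,
                          membrane = NULL, penalty_enabled = FALSE,
                          penalty_cutoff = table$interaction_cutoff,
                          maxit = 200) {
  lig0 <- apply_transform(ligand, pose)
  c_l <- centroid(lig0)
  pose_of <- function(v) {
    ang <- sqrt(sum(v[4:6]^2))
    q <- quat_from_axis_angle(v[4:6] + 1e-12, ang)
    # perturb about the current ligand centroid
    compose_transforms(
      rigid_transform(q, c_l - as.vector(quat_to_matrix(q) %*% c_l) + v[1:3]),
      pose)
  }
  obj <- function(v) {
    -score_pose(receptor, ligand, pose_of(v), table, membrane,
                penalty_enabled, penalty_cutoff)
  }
  fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  list(pose = pose_of(fit$par), score = -fit$value)
}
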