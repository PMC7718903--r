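## Refinement-stage energetics: 12-6 Lennard-Jones + Coulomb (constant
## dielectric) over intermolecular heavy-atom pairs, plus an empirical
## per-atom desolvation term based on buried accessible surface. Combined by
## the standard weighted score
##   score = 1.0*E_vdw + 0.2*E_elec + 0.1*E_AIR + 1.0*E_desolv
## with the restraint term E_AIR identically zero in this protocol (no
## interface restraints are used). Lower score = better model.

# Reduced nonbonded parameter set for poly-alanine heavy atoms.
# sigma (A), epsilon (kcal/mol), partial charge (e), per-atom solvation
# parameter (kcal/mol/A^2; negative = burial favourable).
.energy_params <- data.frame(
  name = c("N", "CA", "C", "O", "CB", "SG"),
  sigma = c(3.25, 3.50, 3.75, 2.96, 3.91, 3.55),
  eps = c(0.170, 0.066, 0.105, 0.210, 0.160, 0.250),
  charge = c(-0.50, 0.25, 0.45, -0.45, 0.25, -0.10),
  solv = c(0.0089, -0.0118, -0.0118, 0.0089, -0.0118, -0.0118),
  stringsAsFactors = FALSE)

energy_params_for <- function(atoms) {
  idx <- match(atoms$name, .energy_params$name)
  if (anyNA(idx)) {
    bad <- atoms$name[is.na(idx)][1]
    stop(sprintf("no nonbonded parameters for atom '%s'", bad))
  }
  .energy_params[idx, , drop = FALSE]
}

# Shrake-Rupley accessible surface area, heavy atoms, golden-spiral points.
# Returns per-atom ASA in A^2.
atom_sasa <- function(xyz, elements, probe = 1.4, n_points = 92) {
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  r <- vdw[elements]
  r[is.na(r)] <- 1.70
  r <- unname(r) + probe
  n <- nrow(xyz)
  # golden-spiral unit sphere
  k <- seq_len(n_points)
  phi <- acos(1 - 2 * (k - 0.5) / n_points)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  sp <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  d <- cross_dist(xyz, xyz)
  asa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + max(r) & seq_len(n) != i)
    nb <- nb[d[i, nb] < r[i] + r[nb]]
    pts <- sweep(sp * r[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      dd <- cross_dist(pts, xyz[nb, , drop = FALSE])
      exposed <- rowSums(dd < matrix(r[nb], nrow(pts), length(nb),
                                     byrow = TRUE)) == 0
    } else exposed <- rep(TRUE, n_points)
    asa[i] <- 4 * pi * r[i]^2 * mean(exposed)
  }
  asa
}

#' Intermolecular energy components of a complex
#'
#' Computes the van der Waals (12-6 Lennard-Jones, geometric-mean combining),
#' electrostatic (Coulomb with constant 332.0636 kcal A/(mol e^2) and a
#' constant dielectric), and empirical desolvation (per-atom solvation
#' parameter times buried accessible surface on binding) terms over
#' intermolecular heavy-atom pairs. The restraint term is zero by
#' construction.
#'
#' @param receptor,ligand heavy-atom \code{memstruct}s in their complex
#'   positions.
#' @param cutoff nonbonded pair cutoff in Angstrom (default 8.5).
#' @param dielectric constant relative dielectric (default 10, the constant-
#'   dielectric setting used for coarse-grained refinement).
#' @param coulomb_k electrostatic constant in kcal A/(mol e^2).
#' @return list of class \code{score_components} with elements
#'   \code{E_vdw}, \code{E_elec}, \code{E_AIR} (always 0), \code{E_desolv}.
#' @export
compute_energy_components <- function(receptor, ligand, cutoff = 8.5,
                                      dielectric = 10,
                                      coulomb_k = 332.0636) {
  pr <- energy_params_for(receptor$atoms)
  pl <- energy_params_for(ligand$atoms)
  d <- cross_dist(coords(receptor), coords(ligand))
  sel <- which(d < cutoff & d > 0, arr.ind = TRUE)
  E_vdw <- 0; E_elec <- 0
  if (nrow(sel) > 0) {
    r <- d[sel]
    sig <- sqrt(pr$sigma[sel[, 1]] * pl$sigma[sel[, 2]])
    eps <- sqrt(pr$eps[sel[, 1]] * pl$eps[sel[, 2]])
    sr6 <- (sig / r)^6
    E_vdw <- sum(4 * eps * (sr6^2 - sr6))
    E_elec <- sum(coulomb_k * pr$charge[sel[, 1]] * pl$charge[sel[, 2]] /
                    (dielectric * r))
  }
  # desolvation: buried surface = free ASA - ASA in the complex
  xyz_r <- coords(receptor); xyz_l <- coords(ligand)
  el_r <- receptor$atoms$element; el_l <- ligand$atoms$element
  if (min(d) >= 2 * (1.8 + 1.4)) {
    # partners further apart than any possible surface overlap: nothing buried
    E_desolv <- 0
  } else {
    asa_free <- c(atom_sasa(xyz_r, el_r), atom_sasa(xyz_l, el_l))
    asa_cplx <- atom_sasa(rbind(xyz_r, xyz_l), c(el_r, el_l))
    buried <- pmax(0, asa_free - asa_cplx)
    E_desolv <- sum(c(pr$solv, pl$solv) * buried)
  }
  structure(list(E_vdw = E_vdw, E_elec = E_elec, E_AIR = 0,
                 E_desolv = E_desolv), class = "score_components")
}

#' @export
print.score_components <- function(x, ...) {
  cat(sprintf("E_vdw = %.3f  E_elec = %.3f  E_AIR = %.3f  E_desolv = %.3f\n",
              x$E_vdw, x$E_elec, x$E_AIR, x$E_desolv))
  cat(sprintf("weighted score = %.3f (lower = better)\n", haddock_score(x)))
  invisible(x)
}

#' Weighted refinement score
#'
#' \code{1.0*E_vdw + 0.2*E_elec + 0.1*E_AIR + 1.0*E_desolv}. Lower values
#' indicate better models; ranking uses this convention.
#'
#' @param c a \code{score_components} (or a list with the four fields).
#' @return numeric score.
#' @export
haddock_score <- function(c) {
  1.0 * c$E_vdw + 0.2 * c$E_elec + 0.1 * c$E_AIR + 1.0 * c$E_desolv
}
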