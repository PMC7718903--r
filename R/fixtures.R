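## Synthetic fixtures: idealized poly-alanine toy complexes (a transmembrane
## helical bundle receptor plus a small soluble helical-hairpin ligand bound
## on the extracellular face), planar two-leaflet bead membranes, pseudo
## coarse-grained snapshots, and graded decoy sets. Everything is
## deterministic under a seed and valid input for every other module.

# Ideal-ish alpha-helix heavy-atom backbone in cylindrical coordinates:
# 100 degrees and 1.5 Angstrom rise per residue; per-atom radius/phase/z
# offsets approximate standard helical geometry. Residues are alanines
# (N, CA, C, O, CB).
helix_atoms <- function(n_res, chain, start_resno = 1, jitter = 0,
                        start_serial = 1) {
  per_res <- data.frame(
    name = c("N", "CA", "C", "O", "CB"),
    r = c(1.56, 2.28, 1.68, 1.95, 3.40),
    dphi = c(-27, 0, 25, 22, -8) * pi / 180,
    dz = c(-0.85, 0, 1.05, 2.20, -0.45),
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n_res)) {
    phi0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    for (k in seq_len(nrow(per_res))) {
      p <- per_res[k, ]
      rows[[length(rows) + 1]] <- data.frame(
        name = p$name, resno = start_resno + i - 1,
        x = p$r * cos(phi0 + p$dphi), y = p$r * sin(phi0 + p$dphi),
        z = z0 + p$dz, stringsAsFactors = FALSE)
    }
  }
  a <- do.call(rbind, rows)
  if (jitter > 0) {
    a$x <- a$x + stats::rnorm(nrow(a), 0, jitter)
    a$y <- a$y + stats::rnorm(nrow(a), 0, jitter)
    a$z <- a$z + stats::rnorm(nrow(a), 0, jitter)
  }
  data.frame(serial = start_serial + seq_len(nrow(a)) - 1,
             name = a$name, element = substr(a$name, 1, 1),
             resname = "ALA", resno = a$resno, chain = chain, insert = "",
             x = a$x, y = a$y, z = a$z, record = "ATOM", is_bead = FALSE,
             stringsAsFactors = FALSE)
}

# Deep local convergence of a ligand placement: restarted Nelder-Mead
# rounds until the score stops improving. Deterministic.
converge_ligand <- function(receptor, ligand, tab, maxit = 400,
                            max_rounds = 12) {
  sc <- score_pose(receptor, ligand, NULL, tab)
  for (round in seq_len(max_rounds)) {
    opt <- optimize_pose(receptor, ligand, rigid_transform(), tab,
                         maxit = maxit)
    if (opt$score - sc < 1e-6) break
    sc <- opt$score
    ligand <- apply_transform(ligand, opt$pose)
  }
  list(ligand = ligand, score = sc)
}

# The fixture native is the strongest attractor of the contact potential
# reachable by docking from the extracellular side: the hairpin is dropped
# onto the crown at 4 azimuths and each placement deep-converged; the best
# converged pose wins (the hot-spot triad makes the matched azimuth win by a
# wide margin). A final +z back-off guarantees a clash-free native.
polish_native_pose <- function(receptor, ligand_start, drop_fn) {
  tab <- default_potential_table()
  best <- NULL
  for (rot in seq(0, 3) * pi / 2) {
    lig <- ligand_start
    if (rot > 0) {
      ctr <- centroid(lig)
      q <- quat_from_axis_angle(c(0, 0, 1), rot)
      lig <- apply_transform(lig, rigid_transform(
        q, ctr - as.vector(quat_to_matrix(q) %*% ctr)))
    }
    cand <- converge_ligand(receptor, drop_fn(lig), tab)
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  out <- best$ligand
  for (k in 1:40) {
    if (count_clashes(dock_complex(receptor, out)) == 0) break
    out <- set_coords(out, sweep(coords(out), 2, c(0, 0, 0.1), "+"))
  }
  out
}

# Attach thiol-like SG atoms at given lateral (x, y) sites: each SG anchors
# to the nearest atom on the relevant face (top of the crown or belly of the
# ligand) and sticks out 1.6 A along +z (top) or -z (belly). The anchor's
# residue is renamed CYS.
add_sg_sites <- function(a, sites, top = TRUE) {
  for (i in seq_len(nrow(sites))) {
    lat <- sqrt((a$x - sites[i, 1])^2 + (a$y - sites[i, 2])^2)
    face <- if (top) a$z > max(a$z) - 6 else a$z < min(a$z) + 6
    cand <- which(lat < 3 & face)
    if (length(cand) == 0) cand <- which(lat < 4.5 & face)
    anchor <- cand[order(if (top) -a$z[cand] else a$z[cand])][1]
    res_sel <- a$chain == a$chain[anchor] & a$resno == a$resno[anchor]
    a$resname[res_sel] <- "CYS"
    sg <- a[anchor, , drop = FALSE]
    sg$name <- "SG"; sg$element <- "S"
    sg$x <- sites[i, 1]; sg$y <- sites[i, 2]
    sg$z <- a$z[anchor] + if (top) 1.6 else -1.6
    a <- rbind(a, sg)
  }
  a$serial <- seq_len(nrow(a))
  a
}

rotate_atoms <- function(a, q, t = c(0, 0, 0)) {
  R <- quat_to_matrix(q)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  a
}

#' Build a toy membrane-associated complex
#'
#' The receptor is a parallel four-helix poly-alanine bundle whose long axis
#' is the z-axis, spanning a membrane slab; the ligand is a compact
#' two-helix hairpin docked onto the extracellular (top) face by lowering it
#' until the closest intermolecular heavy-atom distance is 3.0 Angstrom. The
#' stored ligand sits in a displaced "unbound" position; \code{native_pose}
#' maps it into the native complex. Small seeded coordinate jitter makes
#' each seed a distinct case.
#'
#' @param n_res_receptor receptor residues, split over 4 helices (default
#'   120).
#' @param n_res_ligand ligand residues, split over 2 helices (default 20).
#' @param seed integer seed.
#' @return list of class \code{toy_complex}: \code{receptor}, \code{ligand}
#'   (unbound position), \code{native_pose} (\code{rigid_transform}),
#'   \code{native} (a \code{dock_complex}), \code{membrane_z} (upper, lower
#'   leaflet planes).
#' @export
make_toy_complex <- function(n_res_receptor = 120, n_res_ligand = 20,
                             seed = 1) {
  if (n_res_receptor < 8 || n_res_ligand < 8)
    stop("receptor and ligand need at least 8 residues each")
  set.seed(seed)
  per_helix <- n_res_receptor %/% 4
  # compact parallel bundle; the membrane leaflet sits just below the
  # extracellular crown so only the top face is docking-accessible
  bundle_r <- 5.5
  rec <- list()
  serial <- 1
  for (h in 1:4) {
    ang <- (h - 1) * pi / 2 + stats::runif(1, -0.05, 0.05)
    a <- helix_atoms(per_helix, chain = LETTERS[h],
                     start_resno = 1, jitter = 0.12, start_serial = serial)
    a$x <- a$x + bundle_r * cos(ang)
    a$y <- a$y + bundle_r * sin(ang)
    serial <- serial + nrow(a)
    rec[[h]] <- a
  }
  rec <- do.call(rbind, rec)
  # centre the membrane-spanning span on z = 0
  span <- (per_helix - 1) * 1.5
  rec$z <- rec$z - span * 0.45          # top ~55% of the span above z = 0
  crown_z <- max(rec$z)

  # hot-spot sites: an asymmetric, non-centrosymmetric triad of thiol-like
  # SG pseudo-cysteines on the crown; the matching triad on the ligand belly
  # makes the native registration the unique optimum of the potential
  # (no rotation about z maps the triad onto itself)
  sg_sites <- rbind(c(2.5, 5.5), c(-4.0, 5.5), c(2.5, -5.5))
  rec <- add_sg_sites(rec, sg_sites, top = TRUE)
  receptor <- new_structure(rec, "toy receptor")

  # ligand hairpin: two antiparallel helices side by side along x, with the
  # complementary SG triad on its underside
  per_lig <- n_res_ligand %/% 2
  l1 <- helix_atoms(per_lig, chain = "L", start_resno = 1, jitter = 0.12)
  l2 <- helix_atoms(per_lig, chain = "L", start_resno = per_lig + 1,
                    jitter = 0.12)
  qx <- quat_from_axis_angle(c(0, 1, 0), pi / 2)     # z-axis -> x-axis
  l1 <- rotate_atoms(l1, qx, c(-per_lig * 0.75, -5.5, 0))
  l2 <- rotate_atoms(l2, quat_multiply(quat_from_axis_angle(c(0, 0, 1), pi),
                                       qx),
                     c(per_lig * 0.75, 5.5, 0))
  lig <- rbind(l1, l2)
  lig$serial <- seq_len(nrow(lig))
  lig$x <- lig$x - mean(lig$x)
  lig$y <- lig$y - mean(lig$y)
  lig <- add_sg_sites(lig, sg_sites, top = FALSE)
  lig$z <- lig$z - min(lig$z) + crown_z + 6
  ligand_start <- new_structure(lig, "toy ligand")
  # lower a (possibly re-oriented) hairpin until closest approach is 3.0 A
  drop_fn <- function(l) {
    gap_at <- function(dz) {
      xyz <- coords(l); xyz[, 3] <- xyz[, 3] - dz
      min(cross_dist(coords(receptor), xyz))
    }
    lo <- 0; hi <- 12
    while (gap_at(hi) > 3.0) hi <- hi + 2
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (gap_at(mid) > 3.0) lo <- mid else hi <- mid
    }
    set_coords(l, sweep(coords(l), 2, c(0, 0, lo), "-"))
  }
  # the native pose is the strongest score attractor reachable from above
  ligand_native <- polish_native_pose(receptor, ligand_start, drop_fn)
  lig <- ligand_native$atoms

  # leaflet planes: upper leaflet 7 A below the crown of the shortest helix
  # (the flanks are membrane-buried), 28 A bilayer
  membrane_z <- c(upper = crown_z - 7, lower = crown_z - 7 - 28)

  # unbound storage position: translated away and reoriented
  q_unb <- quat_from_axis_angle(c(0, 1, 0), pi / 6)
  t_unb <- c(40, 25, 10)
  ligand_unbound <- apply_transform(ligand_native,
                                    rigid_transform(q_unb, t_unb))
  ligand_unbound$label <- "toy ligand (unbound position)"
  # native pose maps the stored (unbound) ligand back onto the native one
  R_inv <- quat_conjugate(q_unb)
  t_inv <- -as.vector(quat_to_matrix(R_inv) %*% t_unb)
  native_pose <- rigid_transform(R_inv, t_inv)
  structure(list(receptor = receptor, ligand = ligand_unbound,
                 native_pose = native_pose,
                 native = dock_complex(receptor, ligand_native),
                 membrane_z = membrane_z),
            class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf(paste0(
    "toy membrane complex: receptor %d atoms, ligand %d atoms\n",
    "  leaflet planes z = %.1f / %.1f A; native clashes: %d\n"),
    n_atoms(x$receptor), n_atoms(x$ligand),
    x$membrane_z[1], x$membrane_z[2], count_clashes(x$native)))
  invisible(x)
}

#' Planar two-leaflet bead membrane for a toy complex
#'
#' Square bead grids at the two leaflet planes with Gaussian z-jitter
#' (residue \code{MMB}, atom \code{PO4}, HETATM records). The default jitter
#' of 1 Angstrom emulates the z roughness of an equilibrated phosphate
#' layer.
#'
#' @param toy a \code{toy_complex} (leaflet planes and patch centring).
#' @param spacing bead grid spacing in Angstrom; default 8.
#' @param jitter Gaussian z standard deviation; default 1.
#' @param seed integer seed.
#' @param width patch width in Angstrom; default 80.
#' @return a \code{membrane_model} (leaflets detected from the generated
#'   beads; plane mode unset).
#' @export
make_planar_membrane <- function(toy, spacing = 8, jitter = 1, seed = 1,
                                 width = 80) {
  stopifnot(spacing > 0)
  set.seed(seed)
  g <- seq(-width / 2 + spacing / 2, width / 2 - spacing / 2, by = spacing)
  grid <- expand.grid(x = g, y = g)
  mk_leaflet <- function(zplane, chain, start_serial) {
    n <- nrow(grid)
    data.frame(serial = start_serial + seq_len(n) - 1,
               name = "PO4", element = "P", resname = "MMB",
               resno = seq_len(n), chain = chain, insert = "",
               x = grid$x, y = grid$y,
               z = zplane + stats::rnorm(n, 0, jitter),
               record = "HETATM", is_bead = TRUE, stringsAsFactors = FALSE)
  }
  upper <- mk_leaflet(toy$membrane_z[1], "U", 1)
  lower <- mk_leaflet(toy$membrane_z[2], "V", nrow(grid) + 1)
  detect_layers(new_structure(rbind(upper, lower), "planar bead membrane"))
}

#' Pseudo coarse-grained membrane snapshot
#'
#' Emulates a coarse-grained simulation frame: one lipid per grid point with
#' a phosphate head bead (\code{PO4}) plus choline, glycerol and tail beads,
#' on both leaflets (tails pointing into the bilayer core), and the receptor
#' replaced by backbone bead placeholders at its CA positions. Feeds the
#' phosphate-extraction / leaflet-detection / pruning chain end to end.
#'
#' @param toy a \code{toy_complex}.
#' @param seed integer seed.
#' @param spacing lipid grid spacing; default 8.
#' @param width patch width; default 80.
#' @param jitter z jitter of the phosphate layer; default 1.
#' @return a \code{memstruct}.
#' @export
make_cg_snapshot <- function(toy, seed = 1, spacing = 8, width = 80,
                             jitter = 1) {
  set.seed(seed)
  g <- seq(-width / 2 + spacing / 2, width / 2 - spacing / 2, by = spacing)
  grid <- expand.grid(x = g, y = g)
  rows <- list()
  resno <- 0
  for (leaf in c(1, -1)) {
    zp <- if (leaf == 1) toy$membrane_z[1] else toy$membrane_z[2]
    for (i in seq_len(nrow(grid))) {
      resno <- resno + 1
      zph <- zp + stats::rnorm(1, 0, jitter)
      beads <- data.frame(
        name = c("NC3", "PO4", "GL1", "C1A", "C2A"),
        x = grid$x[i] + stats::rnorm(5, 0, 0.3),
        y = grid$y[i] + stats::rnorm(5, 0, 0.3),
        z = zph + leaf * c(2.8, 0, -2.8, -6.0, -9.2),
        stringsAsFactors = FALSE)
      beads$resname <- "POP"
      beads$resno <- resno
      rows[[length(rows) + 1]] <- beads
    }
  }
  lip <- do.call(rbind, rows)
  lip <- data.frame(serial = seq_len(nrow(lip)), name = lip$name,
                    element = "C", resname = lip$resname, resno = lip$resno,
                    chain = "M", insert = "", x = lip$x, y = lip$y,
                    z = lip$z, record = "HETATM",
                    is_bead = lip$name == "PO4", stringsAsFactors = FALSE)
  # receptor placeholder backbone beads at CA positions
  ca <- toy$receptor$atoms[toy$receptor$atoms$name == "CA", , drop = FALSE]
  bb <- data.frame(serial = nrow(lip) + seq_len(nrow(ca)), name = "BB",
                   element = "C", resname = "CGP", resno = ca$resno,
                   chain = ca$chain, insert = "", x = ca$x, y = ca$y,
                   z = ca$z, record = "HETATM", is_bead = FALSE,
                   stringsAsFactors = FALSE)
  new_structure(rbind(lip, bb), "pseudo coarse-grained snapshot")
}

#' Graded decoy poses for a toy complex
#'
#' Rigid perturbations of the native pose with interface RMSD calibrated
#' into a requested band, plus an optional clash construction that pushes
#' the ligand toward the receptor core until a minimum number of
#' intermolecular clashes exists.
#'
#' @param toy a \code{toy_complex}.
#' @param n number of decoys.
#' @param displacement_range numeric (lo, hi): target i-RMSD band in
#'   Angstrom. \code{c(0, 0)} returns native poses.
#' @param seed integer seed.
#' @param clashed if \code{TRUE}, each decoy is additionally pushed toward
#'   the receptor until it has at least \code{min_clashes} clashes.
#' @param min_clashes clash target for the clashed variant; default 20.
#' @return list of \code{rigid_transform} poses (apply to \code{toy$ligand}).
#' @export
make_decoys <- function(toy, n, displacement_range = c(0, 4), seed = 1,
                        clashed = FALSE, min_clashes = 20) {
  lo <- displacement_range[1]; hi <- displacement_range[2]
  stopifnot(lo >= 0, hi >= lo)
  set.seed(seed)
  ref <- toy$native
  lig0 <- ref$ligand                       # ligand in native position
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    target <- stats::runif(1, lo, hi)
    if (target < 1e-9) {
      pert <- rigid_transform()
    } else {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      u[3] <- abs(u[3]) * 0.5 + u[3] * 0.5   # bias away from the receptor core
      u <- u / sqrt(sum(u^2))
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, 0, 0.04 * target)
      c_l <- centroid(lig0)
      pert_for <- function(s) {
        q <- quat_from_axis_angle(axis, ang)
        R <- quat_to_matrix(q)
        # rotate about the ligand centroid, then translate along u by s
        rigid_transform(q, c_l - as.vector(R %*% c_l) + s * u)
      }
      s <- target
      for (it in 1:3) {
        m <- apply_transform(lig0, pert_for(s))
        ir <- compute_irmsd(dock_complex(ref$receptor, m), ref)
        if (abs(ir - target) < 0.1) break
        s <- s * target / max(ir, 1e-6)
      }
      pert <- pert_for(s)
    }
    if (clashed) {
      # push toward the top of the receptor core in small steps
      dir <- c(colMeans(coords(ref$receptor)[
        coords(ref$receptor)[, 3] > max(coords(ref$receptor)[, 3]) - 10,
        , drop = FALSE])) - centroid(apply_transform(lig0, pert))
      dir <- dir / sqrt(sum(dir^2))
      push <- 0
      repeat {
        push <- push + 0.05
        cand <- rigid_transform(pert$rotation, pert$translation + push * dir)
        m <- apply_transform(lig0, cand)
        if (count_clashes(dock_complex(ref$receptor, m)) >= min_clashes ||
            push > 6) {
          pert <- cand
          break
        }
      }
    }
    # compose with the unbound->native map so poses apply to toy$ligand
    poses[[i]] <- compose_transforms(pert, toy$native_pose)
  }
  poses
}
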