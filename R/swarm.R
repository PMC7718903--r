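## Swarm-based rigid-body docking: swarm centres over the solvent-exposed
## receptor surface, membrane filtering, glowworm initialization, and the
## pose-space GSO loop. A pose is encoded as a 7-vector
## (tx, ty, tz, qw, qx, qy, qz): rotate the ligand about the origin of its
## reference frame by q, then translate by t.

#' Docking run configuration
#'
#' Defaults follow the published protocol: 400 initial swarms, 200 glowworms
#' per swarm, 100 optimization steps.
#'
#' @param n_swarms number of initial swarm centres (before membrane
#'   filtering); default 400.
#' @param n_glowworms glowworms (ligand poses) per swarm; default 200.
#' @param steps GSO iterations; default 100.
#' @param swarm_distance distance (Angstrom) of swarm centres from the
#'   receptor surface; default 10.
#' @param swarm_radius radius (Angstrom) of the ball around the swarm centre
#'   in which ligand centroids are initialized; default 5.
#' @param gso_rho,gso_gamma,gso_beta,gso_max_neighbors GSO update parameters
#'   (see \code{\link{gso_params}}).
#' @param gso_step move step size in pose space (Angstrom-equivalent);
#'   default 0.5.
#' @param initial_luciferin,initial_vision,max_vision luciferin and vision
#'   defaults in pose-space units.
#' @param rotation_scale Angstrom-per-radian weight converting the relative
#'   rotation angle into the pose-space metric; default 5.
#' @param gso_rot_step fixed spherical-interpolation fraction for the
#'   rotational part of a move; default 0.5.
#' @param mode \code{"blind"} (no membrane), \code{"filtered"} (membrane
#'   filters swarms only), or \code{"membrane"} (filtering plus the bead
#'   scoring penalty).
#' @param penalty_cutoff ligand-atom/bead distance (Angstrom) counted as
#'   overlapping the membrane in membrane mode; default 5, about one
#'   coarse-grained bead diameter.
#' @param cluster_cutoff BSAS ligand-RMSD cutoff in Angstrom; default 4.
#' @param polish_top number of pooled cluster representatives refined by a
#'   final local pose optimization before ranking (0 disables); default 20.
#' @param top_n number of ranked poses returned; default 100.
#' @param seed integer seed controlling all stochastic stages.
#' @return list of class \code{swarm_config}.
#' @export
swarm_config <- function(n_swarms = 400, n_glowworms = 200, steps = 100,
                         swarm_distance = 10, swarm_radius = 5,
                         gso_rho = 0.4, gso_gamma = 0.6, gso_beta = 0.08,
                         gso_max_neighbors = 5, gso_step = 0.5,
                         initial_luciferin = 5, initial_vision = 10,
                         max_vision = 20, rotation_scale = 5,
                         gso_rot_step = 0.5,
                         mode = c("membrane", "filtered", "blind"),
                         penalty_cutoff = 5,
                         cluster_cutoff = 4, polish_top = 20,
                         top_n = 100, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_swarms > 0, n_glowworms > 0, steps >= 0,
            gso_rho > 0, gso_rho < 1, gso_gamma > 0)
  structure(list(
    n_swarms = n_swarms, n_glowworms = n_glowworms, steps = steps,
    swarm_distance = swarm_distance, swarm_radius = swarm_radius,
    gso_rho = gso_rho, gso_gamma = gso_gamma, gso_beta = gso_beta,
    gso_max_neighbors = gso_max_neighbors, gso_step = gso_step,
    initial_luciferin = initial_luciferin, initial_vision = initial_vision,
    max_vision = max_vision, rotation_scale = rotation_scale,
    gso_rot_step = gso_rot_step,
    mode = mode, penalty_cutoff = penalty_cutoff,
    cluster_cutoff = cluster_cutoff, polish_top = polish_top, top_n = top_n,
    seed = seed), class = "swarm_config")
}

# Deterministic, nearly uniform directions on the unit sphere.
fibonacci_sphere <- function(n) {
  k <- seq_len(n)
  phi <- acos(1 - 2 * (k - 0.5) / n)
  theta <- pi * (1 + sqrt(5)) * (k - 0.5)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Generate swarm centres over the receptor surface
#'
#' Candidate points are placed on an inflated support surface of the
#' receptor: along each of a dense set of sphere directions \code{u}, a
#' centre sits at the maximal atom projection plus \code{distance}, which
#' guarantees every centre is at least \code{distance} from every receptor
#' atom. Candidates are reduced to \code{n} by farthest-point selection.
#' Fully deterministic for a given receptor.
#'
#' @param receptor heavy-atom \code{memstruct}.
#' @param n requested number of centres.
#' @param distance offset from the receptor surface (Angstrom).
#' @param n_candidates size of the candidate direction set; default
#'   \code{max(4 * n, 256)}.
#' @return numeric matrix of centres (n rows, xyz columns).
#' @export
generate_swarm_centers <- function(receptor, n, distance = 10,
                                   n_candidates = max(4 * n, 256)) {
  if (n_atoms(receptor) < 4) stop("receptor has fewer than 4 atoms")
  stopifnot(n > 0)
  xyz <- coords(receptor)
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  dirs <- fibonacci_sphere(n_candidates)
  proj <- rel %*% t(dirs)                    # atoms x directions
  h <- apply(proj, 2, max)                   # support function per direction
  cand <- sweep(dirs * (h + distance), 2, ctr, "+")
  if (n >= nrow(cand)) return(cand)
  # farthest-point downselection, seeded at the first candidate
  chosen <- integer(n)
  chosen[1] <- 1L
  d2min <- rowSums(sweep(cand, 2, cand[1, ])^2)
  if (n > 1) {
    for (k in 2:n) {
      chosen[k] <- which.max(d2min)
      d2 <- rowSums(sweep(cand, 2, cand[chosen[k], ])^2)
      d2min <- pmin(d2min, d2)
    }
  }
  cand[sort(chosen), , drop = FALSE]
}

#' Filter swarm centres by the membrane plane
#'
#' In \code{"filtered"} and \code{"membrane"} modes, centres below the
#' membrane's filtering plane are discarded (no swarms are generated below
#' the membrane); \code{"blind"} mode returns the input unchanged. Order is
#' preserved.
#'
#' @param centers numeric matrix of swarm centres.
#' @param membrane a \code{membrane_model} with a populated plane (ignored
#'   in blind mode).
#' @param mode run mode, see \code{\link{swarm_config}}.
#' @return filtered centre matrix.
#' @export
filter_swarms_by_membrane <- function(centers, membrane,
                                      mode = c("membrane", "filtered",
                                               "blind")) {
  mode <- match.arg(mode)
  if (mode == "blind") return(centers)
  if (is.null(membrane) || is.na(membrane$plane_z))
    stop("membrane filtering plane is not set")
  centers[centers[, 3] >= membrane$plane_z, , drop = FALSE]
}

pose_vector <- function(t) c(t$translation, t$rotation)

# Fast pose scorer over 7-vector poses. Exact: receptor atoms (and beads)
# farther than ligand-radius + cutoff from the posed ligand centroid cannot
# lie within the cutoff of any ligand atom, so they are culled before the
# pair sweep. Matches score_pose() to numerical precision.
make_fast_scorer <- function(receptor, ligand, table, membrane = NULL,
                             penalty_enabled = FALSE,
                             penalty_cutoff = table$interaction_cutoff) {
  rec_xyz <- coords(receptor)
  lig_xyz <- coords(ligand)
  ti <- atom_types_for(receptor$atoms, table)
  tj <- atom_types_for(ligand$atoms, table)
  c_lig <- colMeans(lig_xyz)
  lig_rad <- max(sqrt(rowSums(sweep(lig_xyz, 2, c_lig)^2)))
  cut <- table$interaction_cutoff
  nb <- length(table$bins) - 1
  bead_xyz <- if (!is.null(membrane)) coords(membrane$beads) else NULL
  function(p) {
    q <- p[4:7]; q <- q / sqrt(sum(q^2))
    R <- quat_to_matrix(q)
    lxyz <- sweep(lig_xyz %*% t(R), 2, p[1:3], "+")
    tc <- as.vector(R %*% c_lig) + p[1:3]
    dr <- sqrt(rowSums(sweep(rec_xyz, 2, tc)^2))
    sel_r <- which(dr < lig_rad + cut)
    s <- 0
    if (length(sel_r) > 0) {
      d <- cross_dist(rec_xyz[sel_r, , drop = FALSE], lxyz)
      hit <- which(d < cut, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        bin <- findInterval(d[hit], table$bins)
        ok <- bin >= 1 & bin <= nb
        idx <- cbind(ti[sel_r[hit[ok, 1]]], tj[hit[ok, 2]], bin[ok])
        s <- sum(table$values[idx])
      }
    }
    if (penalty_enabled && !is.null(bead_xyz) && nrow(bead_xyz) > 0) {
      db <- sqrt(rowSums(sweep(bead_xyz, 2, tc)^2))
      sel_b <- which(db < lig_rad + penalty_cutoff)
      if (length(sel_b) > 0) {
        dbl <- cross_dist(lxyz, bead_xyz[sel_b, , drop = FALSE])
        s <- s + sum(dbl < penalty_cutoff) * table$membrane_penalty
      }
    }
    s
  }
}

pose_transform <- function(p) {
  q <- p[4:7]
  rigid_transform(q / sqrt(sum(q^2)), p[1:3])
}

# Pose-space distance matrix: sqrt(|dt|^2 + (scale * angle)^2).
pose_dist_fn <- function(rotation_scale) {
  function(pos) {
    t_part <- pos[, 1:3, drop = FALSE]
    q_part <- pos[, 4:7, drop = FALSE]
    Dt2 <- cross_dist(t_part, t_part)^2
    A <- abs(tcrossprod(q_part))
    ang <- 2 * acos(pmin(1, A))
    sqrt(Dt2 + (rotation_scale * ang)^2)
  }
}

# Pose move: translation linearly by the distance-capped fraction f,
# rotation by spherical interpolation with a fixed fraction (the documented
# mechanics of the reference swarm-docking implementation; a fixed fraction
# mixes orientations far faster than distance-scaled slerp).
pose_move_fn <- function(rotation_fraction = 0.5) {
  function(xi, xj, f) {
    t_new <- xi[1:3] + f * (xj[1:3] - xi[1:3])
    q_new <- quat_slerp(xi[4:7], xj[4:7], rotation_fraction)
    c(t_new, q_new)
  }
}

#' Initialize the glowworms of a swarm
#'
#' Each glowworm receives a uniformly random orientation and a translation
#' placing the ligand centroid uniformly within \code{swarm_radius} of the
#' swarm centre. When restraint residues are given, each orientation is
#' post-rotated so that the centroid of the restrained ligand residues points
#' from the ligand centroid toward the receptor (pre-orienting the poses at
#' the likely interface).
#'
#' @param center numeric length-3 swarm centre.
#' @param ligand heavy-atom \code{memstruct} in its reference frame.
#' @param n number of glowworms.
#' @param receptor_center receptor centroid (needed for restraint
#'   pre-orientation; defaults to the origin direction from the centre).
#' @param restraint_residues optional integer vector of ligand residue
#'   numbers to orient toward the receptor.
#' @param config a \code{swarm_config} (radius, luciferin, vision defaults).
#' @param seed optional seed; when given the RNG is seeded here.
#' @return a \code{swarm}: list with \code{center}, pose matrix
#'   \code{positions} (n x 7), \code{luciferin}, \code{vision}.
#' @export
init_glowworms <- function(center, ligand, n, receptor_center = c(0, 0, 0),
                           restraint_residues = NULL,
                           config = swarm_config(), seed = NULL) {
  stopifnot(n > 0)
  if (!is.null(seed)) set.seed(seed)
  c_lig <- centroid(ligand)
  if (!is.null(restraint_residues)) {
    missing <- setdiff(restraint_residues, unique(ligand$atoms$resno))
    if (length(missing) > 0)
      stop(sprintf("restraint residues not in ligand: %s",
                   paste(missing, collapse = ", ")))
    sel <- ligand$atoms$resno %in% restraint_residues
    c_restr <- colMeans(coords(ligand)[sel, , drop = FALSE])
    v_restr <- c_restr - c_lig
  }
  dir_receptor <- receptor_center - center
  nd <- sqrt(sum(dir_receptor^2))
  dir_receptor <- if (nd > 1e-9) dir_receptor / nd else c(0, 0, -1)
  positions <- matrix(0, n, 7)
  for (i in seq_len(n)) {
    q <- quat_random()
    if (!is.null(restraint_residues)) {
      R <- quat_to_matrix(q)
      v <- as.vector(R %*% v_restr)
      q <- quat_multiply(quat_align(v, dir_receptor), q)
      q <- q / sqrt(sum(q^2))
    }
    # uniform point in the swarm ball
    repeat {
      u <- stats::runif(3, -1, 1)
      if (sum(u^2) <= 1) break
    }
    target <- center + config$swarm_radius * u
    R <- quat_to_matrix(q)
    t <- target - as.vector(R %*% c_lig)
    positions[i, ] <- c(t, q)
  }
  structure(list(center = center, positions = positions,
                 luciferin = rep(config$initial_luciferin, n),
                 vision = rep(config$initial_vision, n)),
            class = "swarm")
}

#' @export
print.swarm <- function(x, ...) {
  cat(sprintf("swarm at (%.1f, %.1f, %.1f): %d glowworms\n",
              x$center[1], x$center[2], x$center[3], nrow(x$positions)))
  invisible(x)
}

#' One GSO step on a swarm of ligand poses
#'
#' Applies the luciferin update, probabilistic movement toward brighter
#' neighbours (translation linearly, rotation by spherical interpolation) and
#' the vision-range adaptation to the swarm's glowworms.
#'
#' @param swarm a \code{swarm} (optionally carrying engine state fields
#'   \code{scores}, \code{best_positions}, \code{best_scores}).
#' @param scorer function(pose matrix) -> numeric scores, higher = better.
#' @param config a \code{swarm_config}.
#' @return the updated \code{swarm}.
#' @export
gso_step <- function(swarm, scorer, config = swarm_config()) {
  params <- gso_params(
    rho = config$gso_rho, gamma = config$gso_gamma, beta = config$gso_beta,
    max_neighbors = config$gso_max_neighbors, step_size = config$gso_step,
    initial_luciferin = config$initial_luciferin,
    initial_vision = config$initial_vision, max_vision = config$max_vision,
    dist_fn = pose_dist_fn(config$rotation_scale),
    move_fn = pose_move_fn(config$gso_rot_step))
  if (is.null(swarm$scores)) {
    st <- gso_init_state(swarm$positions, scorer, params)
    st$luciferin <- swarm$luciferin
    st$vision <- swarm$vision
  } else {
    st <- list(positions = swarm$positions, luciferin = swarm$luciferin,
               vision = swarm$vision, scores = swarm$scores,
               best_positions = swarm$best_positions,
               best_scores = swarm$best_scores)
  }
  st <- gso_iterate(st, scorer, params)
  swarm$positions <- st$positions
  swarm$luciferin <- st$luciferin
  swarm$vision <- st$vision
  swarm$scores <- st$scores
  swarm$best_positions <- st$best_positions
  swarm$best_scores <- st$best_scores
  swarm
}

#' Sequential (BSAS) clustering of scored poses
#'
#' Poses must be sorted best-first. Each pose joins the first existing
#' cluster whose representative (its best-scored member, i.e. its founder) is
#' within \code{rmsd_cutoff} ligand-coordinate RMSD, otherwise it founds a
#' new cluster.
#'
#' @param poses numeric matrix of pose 7-vectors, sorted by score descending.
#' @param ligand heavy-atom \code{memstruct} (reference frame) used to
#'   compute ligand-coordinate RMSD between poses.
#' @param rmsd_cutoff cluster radius in Angstrom; default 4.
#' @return list with \code{clusters} (list of integer index vectors) and
#'   \code{representatives} (integer vector, one best-scored member per
#'   cluster).
#' @export
cluster_poses_bsas <- function(poses, ligand, rmsd_cutoff = 4) {
  n <- nrow(poses)
  if (n == 0) return(list(clusters = list(), representatives = integer(0)))
  lig_xyz <- coords(ligand)
  posed <- function(p) {
    R <- quat_to_matrix(p[4:7] / sqrt(sum(p[4:7]^2)))
    sweep(lig_xyz %*% t(R), 2, p[1:3], "+")
  }
  rep_coords <- list(posed(poses[1, ]))
  clusters <- list(1L)
  for (i in seq_len(n)[-1]) {
    xi <- posed(poses[i, ])
    assigned <- FALSE
    for (k in seq_along(clusters)) {
      rmsd <- sqrt(mean(rowSums((xi - rep_coords[[k]])^2)))
      if (rmsd < rmsd_cutoff) {
        clusters[[k]] <- c(clusters[[k]], i)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      clusters[[length(clusters) + 1]] <- i
      rep_coords[[length(clusters)]] <- xi
    }
  }
  list(clusters = clusters,
       representatives = vapply(clusters, `[`, integer(1), 1))
}

#' Run the full membrane-driven docking protocol
#'
#' Setup (swarm centres, membrane filtering, glowworm initialization)
#' followed by \code{steps} GSO iterations per swarm. The best-ever pose per
#' glowworm is retained, clustered per swarm by sequential (BSAS) assignment,
#' and the cluster representatives pooled across swarms are ranked by score;
#' the top \code{config$top_n} poses are returned with provenance.
#'
#' @param receptor,ligand heavy-atom \code{memstruct}s; the ligand in any
#'   reference position (initial poses are randomized).
#' @param membrane a \code{membrane_model} (may be \code{NULL} in blind
#'   mode).
#' @param config a \code{swarm_config}.
#' @param restraint_residues optional ligand residue numbers for
#'   pre-orientation.
#' @return object of class \code{dock_run}: list with \code{poses} (a
#'   data.frame: rank, swarm, glowworm, score, and the pose 7-vector
#'   columns), swarm-centre bookkeeping, and the resolved config.
#' @export
run_docking <- function(receptor, ligand, membrane = NULL,
                        config = swarm_config(),
                        restraint_residues = NULL) {
  table <- default_potential_table()
  centers_all <- generate_swarm_centers(receptor, config$n_swarms,
                                        config$swarm_distance)
  centers <- filter_swarms_by_membrane(centers_all, membrane, config$mode)
  if (nrow(centers) == 0)
    stop("membrane excludes entire surface: no swarms remain after filtering")
  penalty_on <- config$mode == "membrane"
  rec_center <- centroid(receptor)
  fast <- make_fast_scorer(receptor, ligand, table, membrane,
                           penalty_enabled = penalty_on,
                           penalty_cutoff = config$penalty_cutoff)
  scorer <- function(pos) {
    vapply(seq_len(nrow(pos)), function(i) fast(pos[i, ]), numeric(1))
  }
  all_poses <- list()
  for (s in seq_len(nrow(centers))) {
    set.seed(config$seed * 1000L + s)
    sw <- init_glowworms(centers[s, ], ligand, config$n_glowworms,
                         receptor_center = rec_center,
                         restraint_residues = restraint_residues,
                         config = config)
    for (it in seq_len(config$steps)) sw <- gso_step(sw, scorer, config)
    if (is.null(sw$scores)) {           # steps = 0: score initial poses
      sc <- scorer(sw$positions)
      sw$best_positions <- sw$positions
      sw$best_scores <- sc
    }
    ord <- order(sw$best_scores, decreasing = TRUE)
    poses <- sw$best_positions[ord, , drop = FALSE]
    cl <- cluster_poses_bsas(poses, ligand, config$cluster_cutoff)
    rep_idx <- cl$representatives
    all_poses[[s]] <- data.frame(
      swarm = s, glowworm = ord[rep_idx],
      score = sw$best_scores[ord][rep_idx],
      poses[rep_idx, , drop = FALSE])
  }
  pooled <- do.call(rbind, all_poses)
  names(pooled)[4:10] <- c("tx", "ty", "tz", "qw", "qx", "qy", "qz")
  pooled <- pooled[order(pooled$score, decreasing = TRUE), , drop = FALSE]
  # final local optimization of the leading cluster representatives: the
  # swarm search localizes basins; this tightens the poses within them
  n_pol <- min(config$polish_top, nrow(pooled))
  if (n_pol > 0) {
    pose_cols <- c("tx", "ty", "tz", "qw", "qx", "qy", "qz")
    c_lig <- centroid(ligand)
    delta_pose <- function(p, v) {
      posed_c <- as.vector(quat_to_matrix(p$rotation) %*% c_lig) +
        p$translation
      dq <- quat_from_axis_angle(v[4:6] + 1e-12, sqrt(sum(v[4:6]^2)))
      compose_transforms(rigid_transform(
        dq, posed_c - as.vector(quat_to_matrix(dq) %*% posed_c) + v[1:3]),
        p)
    }
    # restarted Nelder-Mead rounds until the local optimum stops improving
    converge <- function(p, sc, rounds = 6) {
      for (round in seq_len(rounds)) {
        obj <- function(v) -fast(pose_vector(delta_pose(p, v)))
        fit <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                            control = list(maxit = 300))
        if (-fit$value - sc < 1e-6) break
        sc <- -fit$value
        p <- delta_pose(p, fit$par)
      }
      list(pose = p, score = sc)
    }
    # fixed basin-hopping kicks let a pose escape an adjacent sub-optimal
    # contact shell: lateral translations and azimuthal rotations, each
    # followed by re-convergence; kept only on improvement
    kicks <- list(c(4, 0, 0, 0, 0, 0), c(-4, 0, 0, 0, 0, 0),
                  c(0, 4, 0, 0, 0, 0), c(0, -4, 0, 0, 0, 0),
                  c(0, 0, 0, 0, 0, 0.7), c(0, 0, 0, 0, 0, -0.7),
                  c(0, 0, 0, 0.45, 0, 0))
    for (i in seq_len(n_pol)) {
      cur <- converge(pose_transform(as.numeric(pooled[i, pose_cols])),
                      pooled$score[i])
      if (i <= ceiling(n_pol / 2)) {
        for (k in kicks) {
          kicked <- delta_pose(cur$pose, k)
          cand <- converge(kicked, fast(pose_vector(kicked)), rounds = 3)
          if (cand$score > cur$score + 1e-6) cur <- cand
        }
      }
      if (cur$score > pooled$score[i]) {
        pooled[i, pose_cols] <- pose_vector(cur$pose)
        pooled$score[i] <- cur$score
      }
    }
    pooled <- pooled[order(pooled$score, decreasing = TRUE), , drop = FALSE]
  }
  pooled <- utils::head(pooled, config$top_n)
  pooled <- cbind(rank = seq_len(nrow(pooled)), pooled)
  rownames(pooled) <- NULL
  structure(list(poses = pooled,
                 n_swarms_initial = nrow(centers_all),
                 n_swarms = nrow(centers),
                 centers = centers,
                 mode = config$mode,
                 receptor_label = receptor$label,
                 ligand_label = ligand$label,
                 config = config),
            class = "dock_run")
}

#' Extract the i-th ranked pose of a docking run as a transform
#' @param run a \code{dock_run}.
#' @param rank rank (1 = best).
#' @export
dock_pose <- function(run, rank = 1) {
  p <- run$poses[run$poses$rank == rank, , drop = FALSE]
  if (nrow(p) == 0) stop("no pose at that rank")
  pose_transform(as.numeric(p[1, c("tx", "ty", "tz", "qw", "qx", "qy", "qz")]))
}

#' @export
print.dock_run <- function(x, ...) {
  cat(sprintf(paste0(
    "membrane-driven docking run (%s mode)\n",
    "  swarms: %d initial, %d after membrane filtering\n",
    "  glowworms per swarm: %d, GSO steps: %d\n",
    "  ranked poses: %d (best score %.2f)\n"),
    x$mode, x$n_swarms_initial, x$n_swarms,
    x$config$n_glowworms, x$config$steps,
    nrow(x$poses), x$poses$score[1]))
  invisible(x)
}

#' @export
summary.dock_run <- function(object, n = 10, ...) {
  cat(sprintf("Top %d poses of %d (score: higher = better)\n",
              min(n, nrow(object$poses)), nrow(object$poses)))
  print(utils::head(object$poses[, c("rank", "swarm", "glowworm", "score")],
                    n), row.names = FALSE)
  invisible(object$poses)
}

#' @export
plot.dock_run <- function(x, ...) {
  graphics::plot(x$poses$rank, x$poses$score, type = "h",
                 xlab = "rank", ylab = "pose score",
                 main = sprintf("ranked docking poses (%s mode)", x$mode), ...)
  invisible(NULL)
}
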