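sphere_receptor <- function(n = 200, R = 10) {
  dirs <- memswarm:::fibonacci_sphere(n)
  memswarm:::new_structure(data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resno = seq_len(n), chain = "A", insert = "",
    x = R * dirs[, 1], y = R * dirs[, 2], z = R * dirs[, 3],
    record = "ATOM", is_bead = FALSE, stringsAsFactors = FALSE))
}

test_that("swarm centres sit one offset above a spherical receptor", {
  rec <- sphere_receptor(R = 10)
  centers <- generate_swarm_centers(rec, 50, distance = 8)
  r <- sqrt(rowSums(sweep(centers, 2, centroid(rec))^2))
  expect_true(all(abs(r - 18) < 1))
  expect_equal(nrow(generate_swarm_centers(rec, 1, 8)), 1)
})

test_that("every centre keeps the requested distance from all atoms", {
  toy <- test_toy(1)
  centers <- generate_swarm_centers(toy$receptor, 60, distance = 10)
  expect_lte(nrow(centers), 60)
  dmin <- apply(memswarm:::cross_dist(centers, coords(toy$receptor)), 1, min)
  expect_true(all(dmin >= 10))
  tiny <- memswarm:::new_structure(sphere_receptor(200)$atoms[1:3, ])
  expect_error(generate_swarm_centers(tiny, 5, 10), "fewer than 4")
})

test_that("membrane filtering drops centres below the plane, blind keeps all", {
  centers <- rbind(c(0, 0, 25), c(0, 0, 10))
  m <- detect_layers(memswarm:::new_structure(data.frame(
    serial = 1:2, name = "PO4", element = "P", resname = "MMB", resno = 1:2,
    chain = "U", insert = "", x = c(0, 5), y = 0, z = c(20, 20),
    record = "HETATM", is_bead = TRUE)))
  m <- build_plane_variant(m, "average")
  out <- filter_swarms_by_membrane(centers, m, "membrane")
  expect_equal(nrow(out), 1)
  expect_equal(out[1, 3], 25)
  expect_identical(filter_swarms_by_membrane(centers, m, "blind"), centers)
})

test_that("surviving swarm counts are ordered beads_max <= average <= minimum <= blind", {
  toy <- test_toy(1)
  mem <- make_planar_membrane(toy, seed = 4, jitter = 1.5)
  mem <- prune_clashing_beads(mem, toy$receptor)
  centers <- generate_swarm_centers(toy$receptor, 60, 10)
  counts <- vapply(c("beads_max", "average", "minimum"), function(md) {
    nrow(filter_swarms_by_membrane(centers, build_plane_variant(mem, md),
                                   "membrane"))
  }, numeric(1))
  expect_true(counts["beads_max"] <= counts["average"])
  expect_true(counts["average"] <= counts["minimum"])
  expect_true(counts["minimum"] <= nrow(centers))
})

test_that("glowworm initialization is seeded, local and restraint-oriented", {
  toy <- test_toy(1)
  cfg <- swarm_config(seed = 5)
  ctr <- c(0, 0, 45)
  a <- init_glowworms(ctr, toy$ligand, 50, config = cfg, seed = 5)
  b <- init_glowworms(ctr, toy$ligand, 50, config = cfg, seed = 5)
  expect_identical(a$positions, b$positions)
  expect_equal(a$luciferin, rep(cfg$initial_luciferin, 50))
  # ligand centroids stay within the swarm ball
  c_lig <- centroid(toy$ligand)
  for (i in 1:50) {
    p <- a$positions[i, ]
    R <- quat_to_matrix(p[4:7])
    cc <- as.vector(R %*% c_lig) + p[1:3]
    expect_lte(sqrt(sum((cc - ctr)^2)), cfg$swarm_radius + 1e-9)
  }
  # restraint pre-orientation points the restrained patch at the receptor
  resnos <- unique(toy$ligand$atoms$resno)[1:3]
  rc <- centroid(toy$receptor)
  g <- init_glowworms(ctr, toy$ligand, 25, receptor_center = rc,
                      restraint_residues = resnos, config = cfg, seed = 6)
  sel <- toy$ligand$atoms$resno %in% resnos
  v_restr <- colMeans(coords(toy$ligand)[sel, ]) - c_lig
  dir_rec <- (rc - ctr) / sqrt(sum((rc - ctr)^2))
  for (i in 1:25) {
    R <- quat_to_matrix(g$positions[i, 4:7])
    expect_gt(sum((R %*% v_restr) * dir_rec), 0)
  }
  expect_error(init_glowworms(ctr, toy$ligand, 5,
                              restraint_residues = c(999), config = cfg),
               "999")
})

test_that("a lone swarm pose is unchanged by a GSO step", {
  toy <- test_toy(1)
  cfg <- swarm_config(seed = 2)
  sw <- init_glowworms(c(0, 0, 45), toy$ligand, 1, config = cfg, seed = 2)
  tab <- default_potential_table()
  scorer <- function(pos) {
    vapply(seq_len(nrow(pos)), function(i) {
      score_pose(toy$receptor, toy$ligand,
                 memswarm:::pose_transform(pos[i, ]), tab)
    }, numeric(1))
  }
  out <- gso_step(sw, scorer, cfg)
  expect_equal(out$positions, sw$positions)
})

test_that("BSAS clustering groups identical poses and separates distant ones", {
  toy <- test_toy(1)
  id <- memswarm:::pose_vector(rigid_transform())
  five <- matrix(rep(id, 5), nrow = 5, byrow = TRUE)
  cl <- cluster_poses_bsas(five, toy$ligand, 4)
  expect_equal(length(cl$clusters), 1)
  expect_equal(sort(cl$clusters[[1]]), 1:5)

  far <- rbind(id, memswarm:::pose_vector(rigid_transform(
    translation = c(50, 0, 0))))
  cl2 <- cluster_poses_bsas(far, toy$ligand, 4)
  expect_equal(length(cl2$clusters), 2)
  expect_equal(cl2$representatives, c(1, 2))
})

test_that("BSAS matches an independent sequential-assignment oracle", {
  toy <- test_toy(1)
  set.seed(81)
  n <- 20
  poses <- t(vapply(seq_len(n), function(i) {
    memswarm:::pose_vector(rigid_transform(
      memswarm:::quat_random(), c(rnorm(1, 0, 6), rnorm(1, 0, 6), 40)))
  }, numeric(7)))
  cl <- cluster_poses_bsas(poses, toy$ligand, 6)
  # oracle: plain re-implementation of first-fit assignment
  lig_xyz <- coords(toy$ligand)
  posed <- lapply(seq_len(n), function(i) {
    p <- poses[i, ]
    sweep(lig_xyz %*% t(quat_to_matrix(p[4:7] / sqrt(sum(p[4:7]^2)))), 2,
          p[1:3], "+")
  })
  reps <- 1L
  assign <- rep(NA_integer_, n); assign[1] <- 1L
  for (i in 2:n) {
    done <- FALSE
    for (k in seq_along(reps)) {
      if (sqrt(mean(rowSums((posed[[i]] - posed[[reps[k]]])^2))) < 6) {
        assign[i] <- k; done <- TRUE; break
      }
    }
    if (!done) { reps <- c(reps, i); assign[i] <- length(reps) }
  }
  member <- lapply(seq_along(reps), function(k) which(assign == k))
  expect_equal(cl$clusters, member)
})

test_that("docking runs are deterministic and honour steps = 0", {
  toy <- test_toy(1)
  mem <- build_plane_variant(
    prune_clashing_beads(make_planar_membrane(toy, seed = 1), toy$receptor),
    "beads_max")
  cfg <- swarm_config(n_swarms = 6, n_glowworms = 10, steps = 0,
                      polish_top = 0, seed = 3, mode = "membrane",
                      swarm_distance = 6, swarm_radius = 8)
  a <- run_docking(toy$receptor, toy$ligand, mem, cfg)
  b <- run_docking(toy$receptor, toy$ligand, mem, cfg)
  expect_identical(a$poses, b$poses)
  expect_true(all(diff(a$poses$score) <= 0))   # ranked best-first
  expect_true(all(a$poses$rank == seq_len(nrow(a$poses))))
})

test_that("blind mode uses at least as many swarms as membrane mode", {
  toy <- test_toy(1)
  mem <- build_plane_variant(
    prune_clashing_beads(make_planar_membrane(toy, seed = 1), toy$receptor),
    "beads_max")
  cfg_m <- swarm_config(n_swarms = 10, n_glowworms = 5, steps = 1,
                        polish_top = 0, seed = 4, mode = "membrane",
                        swarm_distance = 6)
  cfg_b <- cfg_m; cfg_b$mode <- "blind"
  rm_ <- run_docking(toy$receptor, toy$ligand, mem, cfg_m)
  rb <- run_docking(toy$receptor, toy$ligand, NULL, cfg_b)
  expect_gte(rb$n_swarms, rm_$n_swarms)
  expect_equal(rb$n_swarms, rb$n_swarms_initial)
})
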