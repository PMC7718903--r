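tab <- default_potential_table()

test_that("the shipped table is symmetric with a fixed bead penalty", {
  expect_true("MEMBRANE_BEAD" %in% tab$atom_types)
  expect_equal(tab$membrane_penalty, -999.0)
  mb <- match("MEMBRANE_BEAD", tab$atom_types)
  expect_true(all(tab$values[mb, , ] == -999.0))
  for (k in seq_len(dim(tab$values)[3]))
    expect_equal(tab$values[, , k], t(tab$values[, , k]))
})

test_that("separated partners score zero", {
  r <- rand_structure(20, seed = 1)
  l <- rand_structure(15, seed = 2)
  l$atoms$x <- l$atoms$x + 500
  expect_identical(score_pose(r, l, NULL, tab), 0)
})

test_that("one bead contact changes the score by exactly the penalty", {
  toy <- test_toy(1)
  lig <- toy$native$ligand
  # a single bead placed near exactly one ligand atom, far from the rest
  a1 <- lig$atoms[which.max(lig$atoms$z), , drop = FALSE]
  bead <- a1
  bead$name <- "PO4"; bead$resname <- "MMB"; bead$record <- "HETATM"
  bead$is_bead <- TRUE
  bead$z <- bead$z + 25    # above the complex
  lig2 <- lig
  lig2$atoms$z[which.max(lig$atoms$z)] <- bead$z - 2  # within penalty cutoff
  mem <- detect_layers(memswarm:::new_structure(bead))
  d <- memswarm:::cross_dist(coords(lig2), coords(mem$beads))
  expect_equal(sum(d < 5), 1)
  s_off <- score_pose(toy$receptor, lig2, NULL, tab, mem,
                      penalty_enabled = FALSE, penalty_cutoff = 5)
  s_on <- score_pose(toy$receptor, lig2, NULL, tab, mem,
                     penalty_enabled = TRUE, penalty_cutoff = 5)
  expect_equal(s_on - s_off, -999.0)
})

test_that("scores match the double-loop oracle on random complexes", {
  for (sd in 1:3) {
    r <- rand_structure(30, seed = sd, box = 8)
    l <- rand_structure(25, seed = sd + 100, box = 8)
    expect_equal(score_pose(r, l, NULL, tab), oracle_score(r, l, tab),
                 tolerance = 1e-6)
  }
})

test_that("scoring respects the applied pose and partner symmetry", {
  r <- rand_structure(25, seed = 7, box = 8)
  l <- rand_structure(20, seed = 8, box = 8)
  set.seed(51)
  pose <- rigid_transform(memswarm:::quat_random(), rnorm(3, 0, 4))
  posed <- apply_transform(l, pose)
  expect_equal(score_pose(r, l, pose, tab), score_pose(r, posed, NULL, tab),
               tolerance = 1e-9)
  # swapping which partner is "moved" leaves the score unchanged
  expect_equal(score_pose(r, posed, NULL, tab),
               score_pose(posed, r, NULL, tab), tolerance = 1e-9)
})

test_that("unknown atom types are reported by name", {
  r <- rand_structure(5, seed = 9)
  l <- rand_structure(5, seed = 10)
  l$atoms$name[2] <- "FE"
  l$atoms$x <- r$atoms$x   # force proximity
  l$atoms$y <- r$atoms$y; l$atoms$z <- r$atoms$z
  expect_error(score_pose(r, l, NULL, tab), "FE")
})

test_that("enabling the membrane penalty never raises a score", {
  toy <- test_toy(1)
  mem <- make_planar_membrane(toy, seed = 3)
  set.seed(52)
  for (k in 1:5) {
    pose <- rigid_transform(memswarm:::quat_random(),
                            centroid(toy$receptor) + c(0, 0, 25) + rnorm(3, 0, 12) -
                              centroid(toy$ligand))
    s_off <- score_pose(toy$receptor, toy$ligand, pose, tab, mem, FALSE, 5)
    s_on <- score_pose(toy$receptor, toy$ligand, pose, tab, mem, TRUE, 5)
    expect_lte(s_on, s_off)
    lg <- apply_transform(toy$ligand, pose)
    n_contact <- sum(memswarm:::cross_dist(coords(lg), coords(mem$beads)) < 5)
    if (n_contact > 0) expect_lt(s_on, s_off) else expect_equal(s_on, s_off)
  }
})

test_that("the table text round-trips through its reader", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("types A B", "bins 0 3 6", "membrane_penalty -50",
               "pair A A 1 2", "pair A B -1 0.5", "pair B B 4 4"), tf)
  t2 <- read_potential_table(tf)
  expect_equal(t2$atom_types, c("A", "B", "MEMBRANE_BEAD"))
  expect_equal(t2$membrane_penalty, -50)
  expect_equal(t2$values[1, 2, ], c(-1, 0.5))
  expect_equal(t2$values[2, 1, ], c(-1, 0.5))
  expect_equal(t2$interaction_cutoff, 6)
})

test_that("local pose optimization never worsens the score", {
  toy <- test_toy(1)
  set.seed(53)
  pose <- compose_transforms(
    rigid_transform(quat_from_axis_angle(c(0, 0, 1), 0.2), c(1, -1, 2)),
    toy$native_pose)
  s0 <- score_pose(toy$receptor, toy$ligand, pose, tab)
  opt <- optimize_pose(toy$receptor, toy$ligand, pose, tab, maxit = 100)
  expect_gte(opt$score, s0)
  expect_equal(opt$score,
               score_pose(toy$receptor, toy$ligand, opt$pose, tab),
               tolerance = 1e-9)
})
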