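make_beads <- function(z, chain = "U") {
  n <- length(z)
  memswarm:::new_structure(data.frame(
    serial = seq_len(n), name = "PO4", element = "P", resname = "MMB",
    resno = seq_len(n), chain = chain, insert = "",
    x = seq_len(n) * 2, y = 0, z = z,
    record = "HETATM", is_bead = TRUE, stringsAsFactors = FALSE))
}

test_that("phosphate extraction keeps only head-group beads", {
  toy <- test_toy(1)
  cg <- make_cg_snapshot(toy, seed = 2)
  ph <- extract_phosphate_beads(cg)
  n_lipids <- length(unique(cg$atoms$resno[cg$atoms$resname == "POP"]))
  expect_equal(n_atoms(ph), n_lipids)   # one phosphate per lipid
  expect_true(all(ph$atoms$name == "PO4"))
  # coordinates untouched
  orig <- cg$atoms[cg$atoms$name == "PO4", c("x", "y", "z")]
  expect_equal(coords(ph), as.matrix(orig), ignore_attr = TRUE)
  # tally oracle on a random subset mix
  expect_equal(n_atoms(ph), sum(cg$atoms$name == "PO4"))
})

test_that("extraction with no matching beads errors", {
  s <- rand_structure(20, seed = 5)
  expect_error(extract_phosphate_beads(s), "no phosphate beads")
  expect_error(extract_phosphate_beads(s, list(residues = character(0),
                                               atoms = character(0))),
               "empty")
})

test_that("leaflet detection splits bimodal z and orders leaflets", {
  m <- detect_layers(make_beads(c(18, 20, 22, -18, -20, -22)))
  expect_equal(length(m$upper), 3)
  expect_equal(length(m$lower), 3)
  expect_equal(m$z_avg_upper, 20)
  expect_equal(m$z_min_upper, 18)
  expect_equal(m$z_max_upper, 22)
  expect_true(min(m$beads$z[m$upper]) > max(m$beads$z[m$lower]))

  one <- detect_layers(make_beads(rep(15, 7)))
  expect_equal(length(one$upper), 7)
  expect_equal(length(one$lower), 0)
})

test_that("leaflet split matches the exhaustive two-cluster oracle and is order invariant", {
  set.seed(31)
  for (k in 1:4) {
    z <- c(rnorm(30, 17, 1.2), rnorm(25, -17, 1.2))
    z <- sample(z)
    m <- detect_layers(make_beads(z))
    # exhaustive 1-D split: threshold minimizing within-cluster sum of squares
    zs <- sort(z)
    best <- which.min(vapply(seq_len(length(zs) - 1), function(i) {
      a <- zs[1:i]; b <- zs[(i + 1):length(zs)]
      sum((a - mean(a))^2) + sum((b - mean(b))^2)
    }, numeric(1)))
    thr <- (zs[best] + zs[best + 1]) / 2
    expect_setequal(m$upper, which(z > thr))
    # permutation invariance of membership (as a set of z values)
    m2 <- detect_layers(make_beads(rev(z)))
    expect_setequal(m2$beads$z[m2$upper], m$beads$z[m$upper])
  }
})

test_that("bead pruning enforces the strict 2.5 A rule", {
  rec <- memswarm:::new_structure(data.frame(
    serial = 1, name = "CA", element = "C", resname = "ALA", resno = 1,
    chain = "A", insert = "", x = 0, y = 0, z = 0, record = "ATOM",
    is_bead = FALSE))
  beads <- make_beads(rep(0, 3))
  beads$atoms$x <- c(2.4, 2.6, 10)
  beads$atoms$y <- 0
  m <- detect_layers(beads)
  pruned <- prune_clashing_beads(m, rec)
  expect_equal(sort(pruned$beads$x), c(2.6, 10))
  # idempotent; cutoff 0 removes nothing
  expect_equal(nrow(prune_clashing_beads(pruned, rec)$beads), 2)
  expect_equal(nrow(prune_clashing_beads(m, rec, cutoff = 0)$beads), 3)
})

test_that("pruning matches the double-loop distance oracle", {
  rec <- rand_structure(40, seed = 41, box = 12)
  set.seed(42)
  z <- runif(60, -15, 15)
  beads <- make_beads(z)
  beads$atoms$x <- runif(60, -15, 15)
  beads$atoms$y <- runif(60, -15, 15)
  m <- detect_layers(beads)
  pruned <- prune_clashing_beads(m, rec, cutoff = 4)
  keep <- vapply(seq_len(60), function(i) {
    all(sqrt(colSums((t(coords(rec)) -
                        unlist(beads$atoms[i, c("x", "y", "z")]))^2)) >= 4)
  }, logical(1))
  expect_setequal(paste(pruned$beads$x, pruned$beads$z),
                  paste(beads$atoms$x[keep], beads$atoms$z[keep]))
})

test_that("plane variants select max, average and minimum z and stay ordered", {
  m <- detect_layers(make_beads(c(18, 20, 22)))
  expect_equal(build_plane_variant(m, "average")$plane_z, 20)
  expect_equal(build_plane_variant(m, "minimum")$plane_z, 18)
  expect_equal(build_plane_variant(m, "beads_max")$plane_z, 22)
  expect_error(build_plane_variant(m, "nonsense"))
  set.seed(43)
  z <- rnorm(40, 16, 2)
  mm <- detect_layers(make_beads(z))
  expect_true(build_plane_variant(mm, "minimum")$plane_z <=
                build_plane_variant(mm, "average")$plane_z)
  expect_true(build_plane_variant(mm, "average")$plane_z <=
                build_plane_variant(mm, "beads_max")$plane_z)
})
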