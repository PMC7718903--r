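test_that("clash counting uses a strict 2.5 A inequality", {
  mk <- function(x, chain) memswarm:::new_structure(data.frame(
    serial = 1, name = "CA", element = "C", resname = "ALA", resno = 1,
    chain = chain, insert = "", x = x, y = 0, z = 0, record = "ATOM",
    is_bead = FALSE))
  expect_equal(count_clashes(dock_complex(mk(0, "A"), mk(2.49, "B"))), 1)
  expect_equal(count_clashes(dock_complex(mk(0, "A"), mk(2.50, "B"))), 0)
  expect_error(count_clashes(complex_to_structure(
    dock_complex(mk(0, "A"), mk(5, "B"))), "A", "Z"), "empty partner")
})

test_that("clash counts match the double-loop oracle", {
  for (sd in 1:3) {
    r <- rand_structure(30, seed = sd, box = 6)
    l <- rand_structure(25, seed = sd + 50, box = 6, chain = "B")
    expect_equal(count_clashes(dock_complex(r, l)), oracle_clashes(r, l))
  }
})

test_that("Fnat is 1 for the reference, 0 for a far decoy, and matches the oracle", {
  toy <- test_toy(1)
  expect_equal(compute_fnat(toy$native, toy$native), 1.0)
  far <- dock_complex(toy$receptor, apply_transform(
    toy$native$ligand, rigid_transform(translation = c(100, 0, 0))))
  expect_equal(compute_fnat(far, toy$native), 0.0)
  for (sd in 1:2) {
    pose <- make_decoys(toy, 1, c(1, 3), seed = sd + 30)[[1]]
    m <- dock_complex(toy$receptor, apply_transform(toy$ligand, pose))
    expect_equal(compute_fnat(m, toy$native),
                 oracle_fnat(m, toy$native), tolerance = 1e-12)
  }
  empty_ref <- dock_complex(toy$receptor, apply_transform(
    toy$native$ligand, rigid_transform(translation = c(200, 0, 0))))
  expect_error(compute_fnat(toy$native, empty_ref), "no contacts")
})

test_that("Fnat decays monotonically along a fixed withdrawal direction", {
  toy <- test_toy(1)
  prev <- 1
  for (d in c(0, 1, 2.5, 4, 6, 10)) {
    m <- dock_complex(toy$receptor, apply_transform(
      toy$native$ligand, rigid_transform(translation = c(0, 0, d))))
    f <- compute_fnat(m, toy$native)
    expect_lte(f, prev + 1e-12)
    prev <- f
  }
})

test_that("i-RMSD is zero for the reference and invariant to rigid motion", {
  toy <- test_toy(1)
  expect_lt(compute_irmsd(toy$native, toy$native), 1e-9)
  set.seed(91)
  tr <- rigid_transform(memswarm:::quat_random(), rnorm(3, 0, 20))
  moved <- dock_complex(apply_transform(toy$native$receptor, tr),
                        apply_transform(toy$native$ligand, tr))
  expect_lt(compute_irmsd(moved, toy$native), 1e-6)
  expect_lt(compute_lrmsd(moved, toy$native), 1e-6)
})

test_that("i-RMSD matches an independent superposition oracle", {
  toy <- test_toy(1)
  pose <- make_decoys(toy, 1, c(2, 4), seed = 33)[[1]]
  model <- dock_complex(toy$receptor, apply_transform(toy$ligand, pose))
  got <- compute_irmsd(model, toy$native)
  # oracle: interface backbone via bio3d fit.xyz (independent Kabsch)
  ref <- toy$native
  ir <- memswarm:::interface_residues(ref, 10)
  mr <- memswarm:::matched_backbone(model, ref, "receptor", ir$receptor)
  ml <- memswarm:::matched_backbone(model, ref, "ligand", ir$ligand)
  P <- rbind(mr$model, ml$model); Q <- rbind(mr$ref, ml$ref)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(Q)),
                                            mobile = as.vector(t(P))))
  oracle <- sqrt(mean((fitted - as.vector(t(Q)))^2) * 3)
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("l-RMSD equals the imposed displacement for a pure ligand shift", {
  toy <- test_toy(1)
  m <- dock_complex(toy$receptor, apply_transform(
    toy$native$ligand, rigid_transform(translation = c(0, 0, 3))))
  expect_equal(compute_lrmsd(m, toy$native), 3.0, tolerance = 1e-9)
  expect_lt(compute_lrmsd(toy$native, toy$native), 1e-9)
  noligand <- dock_complex(toy$receptor,
                           memswarm:::new_structure(
                             toy$ligand$atoms[0, , drop = FALSE]))
  expect_error(compute_lrmsd(noligand, toy$native), "ligand")
})

test_that("CAPRI classes follow the printed thresholds in precedence order", {
  cls <- function(f, i, l) classify_quality(list(fnat = f, irmsd = i,
                                                 lrmsd = l))
  expect_equal(cls(0.70, 1.0, 2.0), "High")       # the worked example
  expect_equal(cls(0.35, 1.5, 4.0), "Medium")
  expect_equal(cls(0.05, 8.0, 20.0), "Incorrect")
  expect_equal(cls(0.5, 1.0, 6.0), "High")        # inclusive boundaries
  expect_equal(cls(0.3, 2.0, 6.0), "Medium")
  expect_equal(cls(0.1, 4.0, 12.0), "Acceptable")
  expect_equal(cls(0.15, 3.0, 8.0), "Acceptable")
  # the literal interval gap falls through to Incorrect (documented choice)
  expect_equal(cls(0.2, 0.5, 0.9), "Incorrect")
})

test_that("success rates aggregate cases as printed percentages", {
  mk_case <- function(q, id) data.frame(case_id = id, rank = 1:5,
                                        quality = q,
                                        stringsAsFactors = FALSE)
  good <- mk_case(c("Incorrect", "Acceptable", rep("Incorrect", 3)), "g")
  bad <- mk_case(rep("Incorrect", 5), "b")
  cases <- c(replicate(11, good, simplify = FALSE),
             replicate(7, bad, simplify = FALSE))
  expect_equal(round(success_rate(cases, 5), 1), 61.1)   # 11 of 18
  expect_equal(success_rate(replicate(4, bad, simplify = FALSE), 5), 0)
  expect_equal(success_rate(replicate(4, good, simplify = FALSE), 5), 100)
  expect_error(success_rate(list(), 5), "no cases")
  # monotone non-decreasing in top_n
  deep <- mk_case(c(rep("Incorrect", 4), "Acceptable"), "d")
  cases2 <- list(deep, bad)
  expect_lte(success_rate(cases2, 1), success_rate(cases2, 5))
})

test_that("evaluate_case produces contiguous ranks and per-model classes", {
  toy <- test_toy(1)
  poses <- make_decoys(toy, 3, c(0, 3), seed = 35)
  models <- lapply(poses, function(p) {
    dock_complex(toy$receptor, apply_transform(toy$ligand, p))
  })
  res <- evaluate_case(models, toy$native, "toy1")
  expect_equal(res$rank, 1:3)
  expect_true(all(res$quality %in% c("High", "Medium", "Acceptable",
                                     "Incorrect")))
  expect_true(all(res$fnat >= 0 & res$fnat <= 1))
  expect_true(all(res$irmsd >= 0))
})
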