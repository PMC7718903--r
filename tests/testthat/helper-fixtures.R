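# Shared fixtures and independent brute-force oracles.
# Toy complexes are expensive to build (their native pose is optimized to
# convergence), so they are memoized per test session.

.toy_cache <- new.env(parent = emptyenv())

test_toy <- function(seed = 1) {
  key <- paste0("toy_", seed)
  if (is.null(.toy_cache[[key]]))
    .toy_cache[[key]] <- make_toy_complex(seed = seed)
  .toy_cache[[key]]
}

# quick synthetic structure: n atoms with random coords in a box,
# names drawn from the shipped potential's protein types
rand_structure <- function(n, seed, chain = "A", box = 20,
                           names = c("N", "CA", "C", "O", "CB")) {
  set.seed(seed)
  df <- data.frame(
    serial = seq_len(n),
    name = rep(names, length.out = n),
    element = "C", resname = "ALA",
    resno = rep(seq_len(ceiling(n / length(names))), each = length(names))[seq_len(n)],
    chain = chain, insert = "",
    x = runif(n, -box, box), y = runif(n, -box, box),
    z = runif(n, -box, box),
    record = "ATOM", is_bead = FALSE, stringsAsFactors = FALSE)
  df$element <- substr(df$name, 1, 1)
  memswarm:::new_structure(df, paste0("rand", seed))
}

# O(n*m) double-loop pair-potential oracle for score_pose (no penalty)
oracle_score <- function(receptor, ligand, table) {
  ra <- receptor$atoms; la <- ligand$atoms
  total <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d >= table$interaction_cutoff) next
      bin <- NA
      for (b in seq_len(length(table$bins) - 1)) {
        if (d >= table$bins[b] && d < table$bins[b + 1]) { bin <- b; break }
      }
      if (is.na(bin)) next
      ti <- match(ra$name[i], table$atom_types)
      tj <- match(la$name[j], table$atom_types)
      total <- total + table$values[ti, tj, bin]
    }
  }
  total
}

# O(n*m) clash-count oracle
oracle_clashes <- function(receptor, ligand, cutoff = 2.5) {
  ra <- coords(receptor); la <- coords(ligand)
  cnt <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      if (sqrt(sum((ra[i, ] - la[j, ])^2)) < cutoff) cnt <- cnt + 1
    }
  }
  cnt
}

# exhaustive residue-contact oracle for Fnat
oracle_fnat <- function(model, reference, cutoff = 5) {
  pairs_of <- function(cplx) {
    ra <- cplx$receptor$atoms; la <- cplx$ligand$atoms
    out <- character(0)
    for (i in seq_len(nrow(ra))) {
      for (j in seq_len(nrow(la))) {
        d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                    (ra$z[i] - la$z[j])^2)
        if (d < cutoff)
          out <- c(out, paste(ra$chain[i], ra$resno[i], "-",
                              la$chain[j], la$resno[j]))
      }
    }
    unique(out)
  }
  native <- pairs_of(reference)
  length(intersect(pairs_of(model), native)) / length(native)
}

# independent least-squares superposition via Horn's quaternion method
# (eigen-decomposition of the 4x4 profile matrix; no SVD) -- used as the
# oracle for RMSD computations
horn_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_matrix(q / sqrt(sum(q^2)))
  function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, "+")
}

# tiny PDB text for parser tests
PDB_ONE_ATOM <- paste0(
  "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00",
  "           C")
PDB_BEAD <- paste0(
  "HETATM    1  PO4 MMB U   1       5.000   6.000   7.000  1.00  0.00",
  "           P")
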