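## CAPRI-style evaluation: fraction of native contacts, interface and ligand
## backbone RMSDs, quality classes, clash counts and benchmark success rates.
##
## Model and reference complexes are represented as two-component lists
## (receptor, ligand memstructs) built with dock_complex(); residues are
## matched across model and reference by (chain, residue number, insertion
## code), so the two must share numbering.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Pair a receptor and a ligand into a complex
#' @param receptor,ligand heavy-atom \code{memstruct}s in complex positions.
#' @return list of class \code{dock_complex}.
#' @export
dock_complex <- function(receptor, ligand) {
  structure(list(receptor = receptor, ligand = ligand),
            class = "dock_complex")
}

#' Merge a complex into a single structure
#' @param cplx a \code{dock_complex}.
#' @param label structure label.
#' @return a \code{memstruct} holding both partners.
#' @export
complex_to_structure <- function(cplx, label = "complex") {
  a <- rbind(cplx$receptor$atoms, cplx$ligand$atoms)
  a$serial <- seq_len(nrow(a))
  new_structure(a, label)
}

#' Split a single-structure complex by chains
#' @param s a \code{memstruct}.
#' @param receptor_chains,ligand_chains character vectors of chain ids.
#' @return a \code{dock_complex}.
#' @export
split_complex <- function(s, receptor_chains, ligand_chains) {
  ra <- s$atoms[s$atoms$chain %in% receptor_chains, , drop = FALSE]
  la <- s$atoms[s$atoms$chain %in% ligand_chains, , drop = FALSE]
  if (nrow(ra) == 0 || nrow(la) == 0)
    stop("empty partner selection: check receptor/ligand chain ids")
  dock_complex(new_structure(ra, "receptor"), new_structure(la, "ligand"))
}

as_complex <- function(x, receptor_chains = NULL, ligand_chains = NULL) {
  if (inherits(x, "dock_complex")) return(x)
  if (inherits(x, "memstruct")) {
    if (is.null(receptor_chains) || is.null(ligand_chains))
      stop("chain ids required to split a single-structure complex")
    return(split_complex(x, receptor_chains, ligand_chains))
  }
  if (is.list(x) && !is.null(x$receptor) && !is.null(x$ligand))
    return(dock_complex(x$receptor, x$ligand))
  stop("cannot interpret input as a complex")
}

#' Count intermolecular steric clashes
#'
#' A clash is any heavy-atom/heavy-atom intermolecular contact strictly
#' shorter than \code{cutoff} (2.5 Angstrom by default, hydrogens excluded by
#' the heavy-atom precondition).
#'
#' @param complex a \code{dock_complex}, or a single \code{memstruct} with
#'   \code{receptor_chains}/\code{ligand_chains} given.
#' @param receptor_chains,ligand_chains chain ids when \code{complex} is a
#'   single structure.
#' @param cutoff clash distance in Angstrom.
#' @return integer clash count.
#' @export
count_clashes <- function(complex, receptor_chains = NULL,
                          ligand_chains = NULL, cutoff = 2.5) {
  cplx <- as_complex(complex, receptor_chains, ligand_chains)
  d <- cross_dist(coords(cplx$receptor), coords(cplx$ligand))
  sum(d < cutoff)
}

# residue-level contact pairs (character keys) between partners
residue_contacts <- function(cplx, cutoff) {
  ra <- cplx$receptor$atoms; la <- cplx$ligand$atoms
  d <- cross_dist(coords(cplx$receptor), coords(cplx$ligand))
  sel <- which(d < cutoff, arr.ind = TRUE)
  if (nrow(sel) == 0) return(character(0))
  rk <- paste(ra$chain, ra$resno, ra$insert, sep = "|")
  lk <- paste(la$chain, la$resno, la$insert, sep = "|")
  unique(paste(rk[sel[, 1]], lk[sel[, 2]], sep = "::"))
}

#' Fraction of native contacts
#'
#' Native contacts are reference residue pairs (one residue per partner) with
#' any heavy-atom pair closer than \code{contact_cutoff}; Fnat is the
#' fraction of them reproduced in the model.
#'
#' @param model,reference complexes (see \code{\link{dock_complex}}) sharing
#'   residue numbering.
#' @param contact_cutoff contact distance in Angstrom; default 5.
#' @return Fnat in [0, 1].
#' @export
compute_fnat <- function(model, reference, contact_cutoff = 5.0) {
  model <- as_complex(model); reference <- as_complex(reference)
  native <- residue_contacts(reference, contact_cutoff)
  if (length(native) == 0) stop("reference complex has no contacts")
  modeled <- residue_contacts(model, contact_cutoff)
  length(intersect(native, modeled)) / length(native)
}

# Kabsch: rotation/translation superposing P onto Q (n x 3 each);
# returns the transform applied to arbitrary coordinates.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, "+")
}

rmsd_xyz <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# matched backbone coordinate sets between model and reference for a
# selection of residue keys; partner = "receptor"/"ligand"
matched_backbone <- function(model, reference, partner, res_keys = NULL) {
  am <- model[[partner]]$atoms; ar <- reference[[partner]]$atoms
  keym <- paste(am$chain, am$resno, am$insert, sep = "|")
  keyr <- paste(ar$chain, ar$resno, ar$insert, sep = "|")
  bm <- am$name %in% BACKBONE_ATOMS
  br <- ar$name %in% BACKBONE_ATOMS
  if (!is.null(res_keys)) {
    bm <- bm & keym %in% res_keys
    br <- br & keyr %in% res_keys
  }
  idm <- paste(keym, am$name, sep = "@")[bm]
  idr <- paste(keyr, ar$name, sep = "@")[br]
  common <- intersect(idr, idm)
  if (length(common) == 0)
    stop("no matching backbone atoms between model and reference")
  Mi <- which(bm)[match(common, idm)]
  Ri <- which(br)[match(common, idr)]
  list(model = coords(am[Mi, , drop = FALSE]),
       ref = coords(ar[Ri, , drop = FALSE]))
}

# reference interface residue keys per partner
interface_residues <- function(reference, interface_cutoff) {
  ra <- reference$receptor$atoms; la <- reference$ligand$atoms
  d <- cross_dist(coords(reference$receptor), coords(reference$ligand))
  rk <- paste(ra$chain, ra$resno, ra$insert, sep = "|")
  lk <- paste(la$chain, la$resno, la$insert, sep = "|")
  near <- d < interface_cutoff
  list(receptor = unique(rk[rowSums(near) > 0]),
       ligand = unique(lk[colSums(near) > 0]))
}

#' Interface backbone RMSD
#'
#' Interface residues are those of the reference with any heavy atom within
#' \code{interface_cutoff} of the partner. The model's interface backbone
#' (N, CA, C, O) is least-squares superposed onto the reference interface
#' backbone and the RMSD reported.
#'
#' @param model,reference complexes sharing residue numbering.
#' @param interface_cutoff interface definition distance; default 10.
#' @return i-RMSD in Angstrom.
#' @export
compute_irmsd <- function(model, reference, interface_cutoff = 10.0) {
  model <- as_complex(model); reference <- as_complex(reference)
  ir <- interface_residues(reference, interface_cutoff)
  if (length(ir$receptor) + length(ir$ligand) == 0)
    stop("empty interface in reference")
  mr <- matched_backbone(model, reference, "receptor", ir$receptor)
  ml <- matched_backbone(model, reference, "ligand", ir$ligand)
  P <- rbind(mr$model, ml$model)
  Q <- rbind(mr$ref, ml$ref)
  fit <- kabsch_fit(P, Q)
  rmsd_xyz(fit(P), Q)
}

#' Ligand backbone RMSD
#'
#' The model is superposed on the reference receptor backbone; the RMSD over
#' ligand backbone atoms is then computed without further fitting.
#'
#' @param model,reference complexes sharing residue numbering.
#' @return l-RMSD in Angstrom.
#' @export
compute_lrmsd <- function(model, reference) {
  model <- as_complex(model); reference <- as_complex(reference)
  if (n_atoms(model$ligand) == 0 || n_atoms(reference$ligand) == 0)
    stop("missing ligand partner")
  mr <- matched_backbone(model, reference, "receptor")
  fit <- kabsch_fit(mr$model, mr$ref)
  ml <- matched_backbone(model, reference, "ligand")
  rmsd_xyz(fit(ml$model), ml$ref)
}

#' CAPRI metrics of a model against a reference
#'
#' @param model,reference complexes sharing residue numbering.
#' @param contact_cutoff Fnat contact cutoff (5 Angstrom).
#' @param interface_cutoff interface definition cutoff (10 Angstrom).
#' @return list of class \code{capri_metrics}: \code{fnat}, \code{irmsd},
#'   \code{lrmsd}.
#' @export
capri_metrics <- function(model, reference, contact_cutoff = 5.0,
                          interface_cutoff = 10.0) {
  structure(list(fnat = compute_fnat(model, reference, contact_cutoff),
                 irmsd = compute_irmsd(model, reference, interface_cutoff),
                 lrmsd = compute_lrmsd(model, reference)),
            class = "capri_metrics")
}

#' @export
print.capri_metrics <- function(x, ...) {
  cat(sprintf("Fnat %.3f  i-RMSD %.3f A  l-RMSD %.3f A  -> %s\n",
              x$fnat, x$irmsd, x$lrmsd, classify_quality(x)))
  invisible(x)
}

#' CAPRI quality class of a model
#'
#' Classes are evaluated in precedence order using the published interval
#' criteria: High (Fnat >= 0.5 and i-RMSD <= 1 or l-RMSD <= 1), Medium
#' (Fnat >= 0.3 and 1 < i-RMSD <= 2 or 1 < l-RMSD <= 5), Acceptable
#' (Fnat >= 0.1 and 2 < i-RMSD <= 4 or 5 < l-RMSD <= 10); anything else is
#' Incorrect. The literal intervals leave gaps (e.g. Fnat 0.2 with both
#' RMSDs tiny matches no positive class); such models fall through to
#' Incorrect here -- a documented reading, not the only possible one.
#'
#' @param m a \code{capri_metrics} (or list with fnat/irmsd/lrmsd).
#' @return one of \code{"High"}, \code{"Medium"}, \code{"Acceptable"},
#'   \code{"Incorrect"}.
#' @export
classify_quality <- function(m) {
  f <- m$fnat; i <- m$irmsd; l <- m$lrmsd
  if (f >= 0.5 && (i <= 1 || l <= 1)) return("High")
  if (f >= 0.3 && ((i > 1 && i <= 2) || (l > 1 && l <= 5))) return("Medium")
  if (f >= 0.1 && ((i > 2 && i <= 4) || (l > 5 && l <= 10)))
    return("Acceptable")
  "Incorrect"
}

quality_rank <- function(class) {
  match(class, c("High", "Medium", "Acceptable", "Incorrect"))
}

#' Evaluate a ranked set of models against a reference
#'
#' @param models list of complexes in rank order (best first).
#' @param reference the native complex.
#' @param case_id case identifier.
#' @return data.frame of class \code{case_result}: rank, fnat, irmsd, lrmsd,
#'   quality, clashes.
#' @export
evaluate_case <- function(models, reference, case_id = "case") {
  rows <- lapply(seq_along(models), function(i) {
    m <- capri_metrics(models[[i]], reference)
    data.frame(case_id = case_id, rank = i, fnat = m$fnat, irmsd = m$irmsd,
               lrmsd = m$lrmsd, quality = classify_quality(m),
               clashes = count_clashes(models[[i]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("case_result", class(out))
  out
}

#' Benchmark success rate
#'
#' The percentage of cases with at least one Acceptable-or-better model among
#' the top \code{top_n} ranks.
#'
#' @param cases list of \code{case_result} data.frames (from
#'   \code{\link{evaluate_case}}) or any data.frames with \code{rank} and
#'   \code{quality} columns.
#' @param top_n ranking depth (1, 5, 10, 20, 50, 100, ...).
#' @return success rate in percent.
#' @export
success_rate <- function(cases, top_n) {
  if (length(cases) == 0) stop("no cases supplied")
  hit <- vapply(cases, function(cs) {
    sel <- cs$rank <= top_n
    any(quality_rank(cs$quality[sel]) <= 3)
  }, logical(1))
  100 * sum(hit) / length(hit)
}
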