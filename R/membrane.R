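## Membrane bead model: phosphate-bead extraction from a coarse-grained
## snapshot, leaflet detection, receptor-clash pruning, and the z-plane
## variants used to filter swarms.
##
## A "membrane_model" is a list with
##   beads        : atom data.frame (as in memstruct$atoms, is_bead TRUE)
##   upper, lower : integer index vectors into beads (leaflet membership)
##   z_max_upper, z_avg_upper, z_min_upper : z statistics of the upper leaflet
##   plane_mode   : one of "beads_max", "average", "minimum", "none"
##   plane_z      : the active filtering-plane z (NA when plane_mode = "none")

new_membrane_model <- function(beads, upper, lower,
                               plane_mode = "none", plane_z = NA_real_) {
  zu <- beads$z[upper]
  structure(list(
    beads = beads, upper = upper, lower = lower,
    z_max_upper = max(zu), z_avg_upper = mean(zu), z_min_upper = min(zu),
    plane_mode = plane_mode, plane_z = plane_z), class = "membrane_model")
}

#' @export
print.membrane_model <- function(x, ...) {
  cat(sprintf(paste0(
    "membrane model: %d beads (%d upper / %d lower leaflet)\n",
    "  upper-leaflet z: min %.2f  avg %.2f  max %.2f A\n"),
    nrow(x$beads), length(x$upper), length(x$lower),
    x$z_min_upper, x$z_avg_upper, x$z_max_upper))
  if (x$plane_mode != "none")
    cat(sprintf("  filtering plane (%s): z = %.2f A\n", x$plane_mode, x$plane_z))
  invisible(x)
}

#' Extract phosphate beads from a coarse-grained snapshot
#'
#' All lipid beads except the phosphate head-group beads are discarded: the
#' phosphates trace the two outermost layers of the bilayer and are the only
#' membrane representation retained for docking.
#'
#' @param cg a \code{memstruct} holding the coarse-grained snapshot.
#' @param bead_names list with \code{residues} and \code{atoms} components
#'   identifying phosphate beads (default \code{\link{default_bead_names}}
#'   plus the literal atom name \code{PO4}).
#' @return a \code{memstruct} containing only the phosphate beads, coordinates
#'   untouched, \code{is_bead} set.
#' @export
extract_phosphate_beads <- function(cg, bead_names = default_bead_names()) {
  if (length(bead_names$residues) + length(bead_names$atoms) == 0)
    stop("bead_names must not be empty")
  a <- cg$atoms
  sel <- a$name %in% bead_names$atoms | a$resname %in% bead_names$residues
  if (!any(sel))
    stop("no phosphate beads found; check bead_names")
  a <- a[sel, , drop = FALSE]
  a$is_bead <- TRUE
  new_structure(a, paste0(cg$label, " [phosphate beads]"))
}

#' Detect membrane leaflets from bead z-coordinates
#'
#' The snapshot is expected with the z-axis perpendicular to the membrane
#' plane. Beads are split into one or two layers by the largest gap in their
#' sorted z values (a deterministic 1-D two-cluster split); the split is only
#' accepted when the gap is wide enough to indicate two leaflets, otherwise a
#' single layer is assumed. The layer with the greater mean z is the upper
#' leaflet.
#'
#' @param beads a \code{memstruct} of beads (or an atom data.frame).
#' @param min_gap minimal z gap (Angstrom) accepted as a leaflet separation;
#'   default 10, about half a bilayer thickness.
#' @return a \code{membrane_model} (plane mode \code{"none"}).
#' @export
detect_layers <- function(beads, min_gap = 10) {
  a <- if (inherits(beads, "memstruct")) beads$atoms else beads
  if (nrow(a) < 1) stop("no beads supplied")
  z <- a$z
  ord <- order(z)
  if (nrow(a) == 1) return(new_membrane_model(a, 1L, integer(0)))
  gaps <- diff(z[ord])
  k <- which.max(gaps)
  if (gaps[k] < min_gap) {
    # single layer
    return(new_membrane_model(a, seq_len(nrow(a)), integer(0)))
  }
  low_idx <- sort(ord[seq_len(k)])
  high_idx <- sort(ord[(k + 1):length(ord)])
  new_membrane_model(a, upper = high_idx, lower = low_idx)
}

#' Remove beads clashing with the receptor
#'
#' Beads closer than \code{cutoff} (strict \code{<}) to any receptor heavy
#' atom are removed; they would overlap with the inserted atomistic
#' transmembrane protein.
#'
#' @param membrane a \code{membrane_model}.
#' @param receptor heavy-atom \code{memstruct}.
#' @param cutoff distance cutoff in Angstrom (default 2.5).
#' @return pruned \code{membrane_model} (plane mode and statistics recomputed
#'   from the surviving beads).
#' @export
prune_clashing_beads <- function(membrane, receptor, cutoff = 2.5) {
  if (nrow(membrane$beads) == 0) return(membrane)
  d <- cross_dist(coords(membrane$beads), coords(receptor))
  keep <- apply(d, 1, min) >= cutoff
  beads <- membrane$beads[keep, , drop = FALSE]
  if (nrow(beads) == 0) stop("all beads pruned; receptor overlaps membrane")
  m <- detect_layers(beads)
  if (membrane$plane_mode != "none")
    m <- build_plane_variant(m, membrane$plane_mode)
  m
}

#' Set the membrane filtering plane
#'
#' The swarm filter uses a single z plane derived from the upper leaflet:
#' its maximum (\code{"beads_max"}), average (\code{"average"}) or minimum
#' (\code{"minimum"}) bead z-coordinate. Explicit bead coordinates are kept on
#' the model in every mode; the scoring penalty uses them only when the run
#' mode enables it.
#'
#' @param membrane a \code{membrane_model} with a populated upper leaflet.
#' @param mode one of \code{"beads_max"}, \code{"average"}, \code{"minimum"}.
#' @return the model with \code{plane_mode}/\code{plane_z} set.
#' @export
build_plane_variant <- function(membrane,
                                mode = c("beads_max", "average", "minimum")) {
  mode <- match.arg(mode)
  z <- switch(mode,
              beads_max = membrane$z_max_upper,
              average = membrane$z_avg_upper,
              minimum = membrane$z_min_upper)
  membrane$plane_mode <- mode
  membrane$plane_z <- z
  membrane
}

#' Build a membrane model from a coarse-grained snapshot
#'
#' Convenience chain: extract phosphate beads, detect leaflets, prune beads
#' clashing with the receptor, set the filtering plane.
#'
#' @param cg coarse-grained snapshot (\code{memstruct}).
#' @param receptor heavy-atom receptor (\code{memstruct}), or \code{NULL} to
#'   skip pruning.
#' @param mode plane mode passed to \code{\link{build_plane_variant}}.
#' @param bead_names see \code{\link{extract_phosphate_beads}}.
#' @param prune_cutoff see \code{\link{prune_clashing_beads}}.
#' @return a \code{membrane_model}.
#' @export
build_membrane <- function(cg, receptor = NULL, mode = "beads_max",
                           bead_names = default_bead_names(),
                           prune_cutoff = 2.5) {
  beads <- extract_phosphate_beads(cg, bead_names)
  m <- detect_layers(beads)
  if (!is.null(receptor)) m <- prune_clashing_beads(m, receptor, prune_cutoff)
  build_plane_variant(m, mode)
}
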