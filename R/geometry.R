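#' POTRA anchor residues
#'
#' The six loop C-alpha anchors that bracket the five POTRA domains of
#' E. coli BamA, in author numbering of the deposited models: F24, T93,
#' A175, Y266, N345, R421. Consecutive triplets of these points define the
#' four inter-domain angles P1-P2 through P4-P5.
#' @export
POTRA_ANCHORS <- c(24L, 93L, 175L, 266L, 345L, 421L)

#' Expected one-letter identities at the anchors, used to flag numbering
#' mismatches (precursor vs mature numbering) rather than fail silently.
#' @rdname POTRA_ANCHORS
#' @export
POTRA_ANCHOR_RESIDUES <- c("PHE", "THR", "ALA", "TYR", "ASN", "ARG")

vnorm <- function(v) sqrt(sum(v * v))

#' Angle at a vertex between two flanking points
#'
#' Returns the in-plane angle at `p2` between the rays `p2 -> p1` and
#' `p2 -> p3`, in degrees. Three points always define a plane, so this is
#' the planar inter-domain angle used for consecutive anchor triplets
#' (e.g. T93-A175-Y266 for POTRA 2-3).
#'
#' @param p1,p2,p3 Numeric length-3 coordinates (Angstrom); `p2` is the
#'   vertex.
#' @return Angle in degrees, in (0, 180].
#' @export
interdomain_angle <- function(p1, p2, p3) {
  u <- as.numeric(p1) - as.numeric(p2)
  v <- as.numeric(p3) - as.numeric(p2)
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < 0.1 || nv < 0.1) {
    stop("degenerate geometry: vertex coincides with a flanking point")
  }
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Inter-domain angle profile of the POTRA chain
#'
#' Resolves the six anchor C-alpha atoms on the BamA chain and computes the
#' four consecutive-triplet angles P1-P2, P2-P3, P3-P4, P4-P5. All six
#' anchors must be present; missing anchors are reported by number. The
#' residue identity found at each anchor is attached so that a numbering
#' mismatch with the expected anchors is visible in the printout.
#'
#' @param structure A [bam_structure()].
#' @param bama_chain Chain identifier of BamA.
#' @param anchors Integer vector of six anchor residue numbers (default
#'   [POTRA_ANCHORS]).
#' @return An object of class `angle_profile`: named numeric vector of four
#'   angles in degrees with attributes `anchors` and `anchor_resid`.
#' @export
potra_angle_profile <- function(structure, bama_chain,
                                anchors = POTRA_ANCHORS) {
  if (length(anchors) != 6) stop("exactly six anchor residues required")
  r <- resolve_required(structure, selection(bama_chain, anchors, "CA"),
                        what = "POTRA anchors")
  pts <- r$points
  angles <- vapply(1:4, function(i) {
    interdomain_angle(pts[i, ], pts[i + 1, ], pts[i + 2, ])
  }, numeric(1))
  names(angles) <- c("P1-P2", "P2-P3", "P3-P4", "P4-P5")
  structure(angles, class = "angle_profile",
            anchors = r$resno, anchor_resid = r$resid,
            structure_id = structure$id)
}

#' @export
print.angle_profile <- function(x, digits = 1, ...) {
  cat("<angle_profile> ", attr(x, "structure_id"), "\n", sep = "")
  cat("  anchors:", paste(sprintf("%s%d", attr(x, "anchor_resid"),
                                  attr(x, "anchors")), collapse = " "), "\n")
  v <- unclass(x)
  cat(paste(sprintf("  %s: %.*f deg", names(v), digits, v),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Membrane frame from the barrel principal axis
#'
#' The membrane (or detergent micelle) is modelled as a slab of half
#' thickness `slab_half_thickness` (default 20 Angstrom, i.e. a ~40
#' Angstrom micelle) centred on the beta-barrel. The slab normal is the
#' dominant principal axis of the centred barrel C-alpha cloud; its sign is
#' chosen so that a designated extracellular residue projects positive,
#' which fixes the periplasm -> extracellular orientation.
#'
#' @param structure A [bam_structure()].
#' @param barrel_selection A [selection()] covering the transmembrane
#'   barrel C-alpha atoms (at least 12 residues).
#' @param reference_extracellular_residue Author number of a residue on the
#'   extracellular side of the barrel, used only to orient the normal.
#' @param slab_half_thickness Slab half thickness in Angstrom.
#' @return An object of class `membrane_frame`: list with `origin`
#'   (barrel centroid), `normal` (unit vector), `slab_half_thickness`.
#' @export
estimate_membrane_frame <- function(structure, barrel_selection,
                                    reference_extracellular_residue,
                                    slab_half_thickness = 20) {
  stopifnot(slab_half_thickness > 0)
  r <- resolve_selection(structure, barrel_selection)
  pts <- r$points
  if (nrow(pts) < 12) stop("need at least 12 barrel C-alpha points, got ",
                           nrow(pts))
  origin <- colMeans(pts)
  centred <- sweep(pts, 2, origin)
  sv <- svd(centred)
  if (sv$d[1] < 1e-8 || sv$d[1] / max(sv$d[2], 1e-12) > 1e6) {
    stop("degenerate barrel point cloud (collinear or coincident points)")
  }
  ## guard against a planar cloud: third singular value must carry signal
  if (sv$d[3] < 1e-8) stop("degenerate barrel point cloud (planar)")
  normal <- sv$v[, 1]
  normal <- normal / vnorm(normal)
  ref <- resolve_required(
    structure,
    selection(barrel_selection$chain, reference_extracellular_residue,
              barrel_selection$atom),
    what = "extracellular reference residue")
  if (sum((ref$points[1, ] - origin) * normal) < 0) normal <- -normal
  structure(list(origin = origin, normal = normal,
                 slab_half_thickness = slab_half_thickness),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat("<membrane_frame>\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) A\n",
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  normal: (%.4f, %.4f, %.4f)  (periplasm -> extracellular)\n",
              x$normal[1], x$normal[2], x$normal[3]))
  cat(sprintf("  slab half thickness: %.1f A\n", x$slab_half_thickness))
  invisible(x)
}

#' Vertical extension below the membrane slab
#'
#' Measures how far the most distal selected C-alpha hangs below the
#' periplasmic face of the membrane slab, along the membrane normal: the
#' periplasmic face level minus the minimum projection of the selection,
#' clamped at zero when the whole selection lies inside (or above) the
#' slab. Differencing this quantity between two conformations gives the
#' vertical POTRA extension.
#'
#' @param structure A [bam_structure()].
#' @param frame A [estimate_membrane_frame()] result.
#' @param potra_selection A [selection()] of the periplasmic (POTRA)
#'   C-alpha atoms to measure.
#' @return Extension in Angstrom (>= 0).
#' @export
vertical_extension <- function(structure, frame, potra_selection) {
  stopifnot(inherits(frame, "membrane_frame"))
  r <- resolve_selection(structure, potra_selection)
  if (nrow(r$points) == 0) stop("empty POTRA selection")
  proj <- as.vector(r$points %*% frame$normal)
  face <- sum(frame$origin * frame$normal) - frame$slab_half_thickness
  max(0, face - min(proj))
}

#' Lateral-gate geometry between barrel strands 1 and 16
#'
#' Measures the distance between the gate residue pair (author numbers 430
#' and 808 in BamA, the I430C/K808C disulfide-trap positions) and
#' classifies the gate as closed when the distance is at or below the
#' threshold. Default is the C-beta distance with a 6.0 Angstrom
#' disulfide-compatibility bound; in C-alpha mode the default threshold is
#' 8.0 Angstrom. For glycine the C-beta falls back to C-alpha with a
#' warning.
#'
#' @param structure A [bam_structure()].
#' @param bama_chain Chain identifier of BamA.
#' @param atom `"CB"` (default) or `"CA"`.
#' @param threshold Distance threshold in Angstrom; defaults to 6.0 for
#'   `"CB"` and 8.0 for `"CA"`.
#' @param residue_pair Author numbers of the two gate residues.
#' @return An object of class `gate_metrics`: list with `residue_pair`,
#'   `atom`, `distance` (Angstrom), `threshold`, `state` (`"open"` or
#'   `"closed"`).
#' @export
gate_metrics <- function(structure, bama_chain, atom = c("CB", "CA"),
                         threshold = NULL, residue_pair = c(430L, 808L)) {
  atom <- match.arg(atom)
  if (is.null(threshold)) threshold <- if (atom == "CB") 6.0 else 8.0
  stopifnot(length(residue_pair) == 2)
  pts <- matrix(NA_real_, 2, 3)
  for (i in 1:2) {
    r <- resolve_selection(structure,
                           selection(bama_chain, residue_pair[i], atom))
    if (length(r$missing) > 0 && atom == "CB") {
      rca <- resolve_selection(structure,
                               selection(bama_chain, residue_pair[i], "CA"))
      if (length(rca$missing) > 0) {
        stop("gate residue ", residue_pair[i], " missing on chain ",
             bama_chain)
      }
      warning("no CB for gate residue ", residue_pair[i],
              " (glycine?); using CA")
      r <- rca
    } else if (length(r$missing) > 0) {
      stop("gate residue ", residue_pair[i], " missing on chain ", bama_chain)
    }
    pts[i, ] <- r$points[1, ]
  }
  d <- vnorm(pts[1, ] - pts[2, ])
  structure(list(residue_pair = residue_pair, atom = atom, distance = d,
                 threshold = threshold,
                 state = if (d <= threshold) "closed" else "open"),
            class = "gate_metrics")
}

#' @export
print.gate_metrics <- function(x, ...) {
  cat(sprintf("<gate_metrics> %d-%d %s-%s distance %.2f A (threshold %.1f) -> %s\n",
              x$residue_pair[1], x$residue_pair[2], x$atom, x$atom,
              x$distance, x$threshold, x$state))
  invisible(x)
}
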