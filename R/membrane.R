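## Hydropathy scales, indexed by one-letter residue code.
##
## "ww_interface": Wimley-White water -> POPC-interface transfer free
## energies, stored as favorability (-dG, kcal/mol) so larger = more
## membrane-interface-favorable; aromatics (Trp, Tyr, Phe) score high,
## which matters for Trp-rich interaction segments such as the BamA POTRA 3
## loop. Charged forms are used for D/E/K/R, neutral for His.
## "kyte_doolittle": classic hydropathy index (penalizes Trp).
HYDROPATHY_SCALES <- list(
  ww_interface = c(
    A = -0.17, R = -0.81, N = -0.42, D = -1.23, C = 0.24,
    E = -2.02, Q = -0.58, G = -0.01, H = -0.17, I = 0.31,
    L = 0.56, K = -0.99, M = 0.23, F = 1.13, P = -0.45,
    S = -0.13, T = -0.14, W = 1.85, Y = 0.94, V = -0.07),
  kyte_doolittle = c(
    A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
    E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
    L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
    S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
)

#' Sliding-window hydropathy scan
#'
#' Computes the windowed arithmetic mean of per-residue scale values and
#' merges maximal runs of window centers scoring above the cutoff into
#' candidate membrane-interaction segments. With the default interface
#' scale and cutoff 0, a segment marks centers whose local environment has
#' favorable transfer into a membrane interface; on the BamA POTRA 3 loop
#' sequence RDE-VPWWNVVG-DRK the single segment falls inside the
#' hydrophobic core and excludes the charged flanks.
#'
#' @param sequence One-letter amino-acid string (20 standard letters).
#' @param window Odd window length (default 3, suited to short loops).
#' @param scale `"ww_interface"` (default) or `"kyte_doolittle"`, or a
#'   named numeric vector over the 20 letters.
#' @param cutoff Segment cutoff in scale units (default 0).
#' @return An object of class `hydropathy_profile`: list with `positions`
#'   (window centers, 1-based), `scores`, and `segments` (data frame
#'   `start`, `end`, `mean_score`; coordinates are sequence positions of
#'   window centers).
#' @export
hydropathy_scan <- function(sequence, window = 3, scale = "ww_interface",
                            cutoff = 0) {
  if (window %% 2 != 1) stop("window must be odd")
  if (is.character(scale)) {
    if (!scale %in% names(HYDROPATHY_SCALES)) {
      stop("unknown scale '", scale, "'")
    }
    scale_name <- scale
    scale <- HYDROPATHY_SCALES[[scale]]
  } else scale_name <- "custom"
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  n <- length(letters1)
  if (window > n) stop("window (", window, ") exceeds sequence length (", n, ")")
  bad <- which(!letters1 %in% names(scale))
  if (length(bad) > 0) {
    stop("unknown residue letter '", letters1[bad[1]], "' at position ", bad[1])
  }
  vals <- unname(scale[letters1])
  half <- (window - 1) / 2
  scores <- as.numeric(stats::filter(vals, rep(1 / window, window),
                                     sides = 2))
  centers <- (half + 1):(n - half)
  scores <- scores[centers]
  above <- scores > cutoff
  segments <- runs_to_segments(centers, above, scores)
  structure(list(sequence = sequence, window = window, scale = scale_name,
                 cutoff = cutoff, positions = centers, scores = scores,
                 segments = segments),
            class = "hydropathy_profile")
}

## merge maximal TRUE-runs over consecutive positions into segments
runs_to_segments <- function(positions, flag, score) {
  if (!any(flag)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_score = numeric(0)))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(
    start = positions[starts[keep]],
    end = positions[ends[keep]],
    mean_score = vapply(keep, function(k) {
      mean(score[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %d residues, window %d, scale %s, cutoff %g\n",
              nchar(x$sequence), x$window, x$scale, x$cutoff))
  if (nrow(x$segments) == 0) {
    cat("  no segments above cutoff\n")
  } else {
    for (i in seq_len(nrow(x$segments))) {
      s <- x$segments[i, ]
      cat(sprintf("  segment %d-%d (%s), mean score %.2f\n", s$start, s$end,
                  substr(x$sequence, s$start, s$end), s$mean_score))
    }
  }
  invisible(x)
}

#' Residue segments buried in the membrane slab
#'
#' Reports, per chain, the maximal runs of consecutive modelled residues
#' whose C-alpha projection along the membrane normal lies within the slab
#' (inclusive at the boundary), together with the mean burial depth
#' (half thickness minus |offset from the slab midplane|). This is the
#' structural counterpart of the sequence scan: it finds the segments that
#' sit inside a ~40 Angstrom micelle/membrane slab, such as the BamD
#' membrane-facing helix or the POTRA 3 loop.
#'
#' @param structure A [bam_structure()].
#' @param frame A [estimate_membrane_frame()] result.
#' @param chains Chains to scan (default: all chains in the structure).
#' @return Data frame with `chain`, `start_residue`, `end_residue`,
#'   `n_residues`, `mean_depth` (Angstrom inside the slab), sorted by
#'   chain then start; segments never overlap.
#' @export
slab_burial <- function(structure, frame, chains = NULL) {
  stopifnot(inherits(frame, "membrane_frame"))
  if (is.null(chains)) chains <- structure_chains(structure)
  mid <- sum(frame$origin * frame$normal)
  h <- frame$slab_half_thickness
  out <- list()
  for (ch in chains) {
    r <- resolve_selection(structure, selection(ch, NULL, "CA"))
    if (nrow(r$points) == 0) next
    off <- as.vector(r$points %*% frame$normal) - mid
    inside <- abs(off) <= h
    if (!any(inside)) next
    ## contiguous = consecutive modelled residues in author order
    grp <- cumsum(c(TRUE, diff(r$resno) != 1))
    for (g in unique(grp)) {
      sel <- which(grp == g & inside)
      if (length(sel) == 0) next
      sub <- cumsum(c(TRUE, diff(sel) != 1))
      for (s in unique(sub)) {
        run <- sel[sub == s]
        out[[length(out) + 1]] <- data.frame(
          chain = ch,
          start_residue = r$resno[run[1]],
          end_residue = r$resno[run[length(run)]],
          n_residues = length(run),
          mean_depth = mean(h - abs(off[run]))
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(0), start_residue = integer(0),
                      end_residue = integer(0), n_residues = integer(0),
                      mean_depth = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chain, res$start_residue), , drop = FALSE]
  rownames(res) <- NULL
  res
}
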