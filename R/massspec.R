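## average-isotope residue masses (Da) for the 20 standard amino acids
## (residue = amino acid minus water); water 18.0153 Da
AVG_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MASS <- 18.0153
PROTON_MASS <- 1.00728

#' Electrospray charge-state peak series
#'
#' An ordered list of m/z peaks assumed to be consecutive charge states of
#' a single species, as seen in a native mass spectrum of an intact
#' complex.
#'
#' @param mz_values Strictly increasing m/z values (Th), all > 0.
#' @param intensities Optional peak intensities.
#' @return An object of class `peak_series`.
#' @export
peak_series <- function(mz_values, intensities = NULL) {
  mz_values <- as.numeric(mz_values)
  if (any(mz_values <= 0)) stop("m/z values must be positive")
  if (is.unsorted(mz_values, strictly = TRUE)) {
    stop("m/z values must be strictly increasing")
  }
  structure(list(mz_values = mz_values, intensities = intensities),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("<peak_series> %d peaks, m/z %.2f..%.2f Th\n",
              length(x$mz_values), min(x$mz_values), max(x$mz_values)))
  invisible(x)
}

#' Infer charges of a charge-state series
#'
#' For a protonated species M the peak at charge z sits at (M + z p)/z.
#' The charge of the highest-charge (lowest m/z) peak is found by a
#' candidate search: for each candidate z1 the implied neutral mass is
#' propagated to every other peak, the nearest integer charge assigned,
#' and the candidate minimizing the relative spread of per-peak masses
#' wins (the smallest such candidate, so a ladder is never reported at a
#' charge multiple). The series need not be strictly consecutive — a
#' missing intermediate charge state is tolerated — but the assignment
#' must reconstruct a single common mass.
#'
#' @param series A [peak_series()] with at least 2 peaks.
#' @param proton_mass Proton mass in Da (default 1.00728).
#' @param max_rel_spread Maximum allowed relative spread (sd/mean) of the
#'   per-peak neutral masses before the spacing is declared non-physical.
#' @param max_charge Upper bound of the candidate search (default 200).
#' @return Integer vector of charges, one per peak (descending as m/z
#'   ascends, all >= 1).
#' @export
infer_charges <- function(series, proton_mass = PROTON_MASS,
                          max_rel_spread = 0.01, max_charge = 200) {
  mz <- series$mz_values
  n <- length(mz)
  if (n < 2) stop("need at least 2 peaks to infer charges")
  best <- NULL; best_spread <- Inf
  for (z1 in seq_len(max_charge)) {
    m_hat <- z1 * (mz[1] - proton_mass)
    z <- round(m_hat / (mz - proton_mass))
    z[1] <- z1
    if (any(z < 1) || any(diff(z) >= 0)) next
    ## physical ladders are compact: consecutive charges up to a couple of
    ## missing states, never a widely spread assignment that only fits
    ## because integer rounding can absorb arbitrary spacing at high z
    if (z[1] - z[n] > n + 2) next
    masses <- z * (mz - proton_mass)
    spread <- stats::sd(masses) / mean(masses)
    if (spread < best_spread - 1e-12) {
      best_spread <- spread; best <- z
    }
    if (best_spread <= max_rel_spread / 10) break  # smallest good z1 wins
  }
  if (is.null(best) || best_spread > max_rel_spread) {
    stop("peak spacing inconsistent with charge states of one species; ",
         "best relative mass spread ", signif(best_spread, 3))
  }
  as.integer(best)
}

#' Neutral mass from an assigned charge-state series
#'
#' Each peak gives a neutral-mass estimate z (m/z - p); the series mass is
#' their mean and `mass_sd` their standard deviation, the same convention
#' as the "observed mass +/- sd" reported for intact complexes.
#'
#' @param series A [peak_series()].
#' @param charges Integer charges, one per peak (e.g. from
#'   [infer_charges()]).
#' @param proton_mass Proton mass in Da.
#' @return An object of class `deconvolution_result`: list with `mass`
#'   (Da), `mass_sd` (Da), `charges`, `per_peak_mass`, `residuals` (Da,
#'   per-peak mass minus mean).
#' @export
mass_from_series <- function(series, charges = NULL,
                             proton_mass = PROTON_MASS) {
  if (is.null(charges)) charges <- infer_charges(series, proton_mass)
  mz <- series$mz_values
  if (length(charges) != length(mz)) stop("one charge per peak required")
  per <- charges * (mz - proton_mass)
  m <- mean(per)
  structure(list(mass = m,
                 mass_sd = if (length(per) > 1) stats::sd(per) else 0,
                 charges = as.integer(charges),
                 per_peak_mass = per, residuals = per - m),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> mass %.0f +/- %.0f Da (charges %d..%d, %d peaks)\n",
              x$mass, x$mass_sd, max(x$charges), min(x$charges),
              length(x$charges)))
  invisible(x)
}

#' Predicted average mass of a multi-subunit complex
#'
#' Sums average-isotope sequence masses over components: each component
#' contributes count x (sum of residue masses + one water + modification
#' mass). Modification masses carry lipid anchors, bound cofactors or any
#' other non-sequence mass.
#'
#' @param components List of lists/data-frame rows with fields `sequence`
#'   (one-letter string), `count` (>= 1, default 1) and `modification_mass`
#'   (Da, default 0).
#' @return Total average mass in Da (0 for an empty component list).
#' @export
subunit_mass_sum <- function(components) {
  if (length(components) == 0) return(0)
  if (is.data.frame(components)) {
    components <- split(components, seq_len(nrow(components)))
  }
  total <- 0
  for (comp in components) {
    seq1 <- toupper(comp$sequence)
    count <- if (is.null(comp$count)) 1 else comp$count
    mod <- if (is.null(comp$modification_mass)) 0 else comp$modification_mass
    stopifnot(count >= 1)
    letters1 <- strsplit(seq1, "")[[1]]
    bad <- which(!letters1 %in% names(AVG_RESIDUE_MASS))
    if (length(bad) > 0) {
      stop("unknown residue letter '", letters1[bad[1]], "' at position ",
           bad[1])
    }
    chain_mass <- sum(AVG_RESIDUE_MASS[letters1]) + WATER_MASS
    total <- total + count * (chain_mass + mod)
  }
  total
}

#' Read a 1- or 2-column peak list
#'
#' @param path Text/CSV file with m/z in the first column and optional
#'   intensity in the second; `#` comments allowed.
#' @param sep Field separator (default: any whitespace or comma).
#' @return A [peak_series()].
#' @export
read_peaks <- function(path, sep = "") {
  d <- utils::read.table(path, header = FALSE, sep = sep,
                         comment.char = "#")
  peak_series(sort(d[[1]]),
              intensities = if (ncol(d) > 1) d[[2]][order(d[[1]])] else NULL)
}
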