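## Seeded synthetic-data generators. Every generator records its ground
## truth in the structure metadata (or attributes), so recovery tests can
## consume only the data and compare against the recorded truth.

## evaluate expr under a temporary RNG state; NULL seed = use current RNG
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- as.numeric(axis); u <- u / vnorm(u)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniform random rotation matrix
#'
#' @param seed Optional integer seed (current RNG stream when `NULL`).
#' @return 3 x 3 proper rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(
      a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
      2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
      2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2
    ), 3, 3)
  })
}

ca_table <- function(chain, resno, coords, resid = "GLY", elety = "CA") {
  coords <- matrix(coords, ncol = 3)
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = rep_len(resid, nrow(coords)),
             elety = rep_len(elety, nrow(coords)),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occ = 1, alt = "", stringsAsFactors = FALSE)
}

#' Synthetic beta-barrel point set
#'
#' A C-alpha-only chain tracing a helical path on a cylinder of known
#' radius, height and axis: a geometric stand-in for the BamA
#' transmembrane barrel. The true axis (unit vector, extracellular
#' direction = +axis) is recorded in `meta$true_axis`.
#'
#' @param n_points Number of points (>= 12; default 64).
#' @param radius Cylinder radius in Angstrom (default 12.5, the C-alpha
#'   radius of a 16-strand barrel).
#' @param height Cylinder height in Angstrom (default 40).
#' @param axis Cylinder axis (default z).
#' @param turns Integer number of helical turns (default 2).
#' @param noise_sd Isotropic Gaussian coordinate noise, Angstrom.
#' @param seed Optional seed for the noise.
#' @param chain Chain identifier (default `"A"`).
#' @param resno_start First author residue number (default 1).
#' @return A [bam_structure()] whose highest-numbered residue sits at the
#'   extracellular (+axis) rim.
#' @export
make_toy_barrel <- function(n_points = 64, radius = 12.5, height = 40,
                            axis = c(0, 0, 1), turns = 2, noise_sd = 0,
                            seed = NULL, chain = "A", resno_start = 1) {
  if (n_points < 12) stop("need at least 12 points")
  if (n_points %% 2 != 0) stop("n_points must be even (two antipodal strands)")
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  i <- seq_len(n_points) - 1
  ## two antipodal helical strands sharing height levels: pairing each
  ## phase with its opposite at the same height decouples the in-plane
  ## coordinates from height, so the principal axis is exactly the
  ## cylinder axis for the noise-free cloud
  half <- n_points / 2
  j <- c(0:(half - 1), 0:(half - 1))
  phi <- 2 * pi * turns * j / half + rep(c(0, pi), each = half)
  z <- -height / 2 + height * j / (half - 1)
  pts <- cbind(radius * cos(phi), radius * sin(phi), z)
  ## rotate canonical z-axis frame onto the requested axis
  u <- axis / vnorm(axis)
  if (abs(sum(u * c(0, 0, 1))) < 1 - 1e-12) {
    ang <- acos(min(1, max(-1, u[3]))) * 180 / pi
    R <- rotation_about_axis(c(-u[2], u[1], 0), ang)  # z x u
    pts <- pts %*% t(R)
  } else if (u[3] < 0) {
    pts[, 3] <- -pts[, 3]
  }
  if (noise_sd > 0) {
    pts <- pts + with_seed(seed, matrix(stats::rnorm(3 * n_points,
                                                     sd = noise_sd),
                                        ncol = 3))
  }
  bam_structure(
    id = sprintf("toy_barrel_r%g_h%g", radius, height),
    atoms = ca_table(chain, resno_start + i, pts),
    source_format = "synthetic",
    meta = list(true_axis = u, radius = radius, height = height)
  )
}

#' Synthetic multi-domain anchor chain
#'
#' Six C-alpha anchor points with prescribed consecutive-triplet angles and
#' equal arm lengths, numbered with the POTRA anchor scheme (24, 93, 175,
#' 266, 345, 421) and carrying the expected anchor residue identities, so
#' the real angle-profiling pipeline runs unchanged on synthetic input.
#' The chain is built in a plane and then (when a seed is given) placed at
#' a random rigid pose. True angles live in `meta$true_angles`.
#'
#' @param angles Four inter-domain angles in degrees, each in (0, 180].
#' @param arm_length Distance between consecutive anchors, Angstrom.
#' @param seed Optional seed for the random pose (canonical in-plane pose
#'   when `NULL`).
#' @param chain Chain identifier (default `"A"`).
#' @return A [bam_structure()] with 6 residues.
#' @export
make_domain_chain <- function(angles, arm_length = 30, seed = NULL,
                              chain = "A") {
  if (length(angles) != 4) stop("exactly four angles required")
  if (any(angles <= 0 | angles > 180)) stop("angles must be in (0, 180]")
  if (arm_length <= 0.1) stop("arm length too small")
  pts <- matrix(0, 6, 3)
  d <- c(1, 0)
  p <- c(0, 0)
  for (i in 1:5) {
    p_next <- p + arm_length * d
    pts[i + 1, 1:2] <- p_next
    if (i < 5) {
      s <- if (i %% 2 == 1) 1 else -1  # alternate turn direction
      alpha <- s * (pi - angles[i] * pi / 180)
      Rm <- matrix(c(cos(alpha), sin(alpha), -sin(alpha), cos(alpha)), 2, 2)
      d <- as.vector(Rm %*% d)
    }
    p <- p_next
  }
  if (!is.null(seed)) {
    R <- random_rotation(seed)
    shift <- with_seed(seed + 1L, stats::runif(3, -50, 50))
    pts <- sweep(pts %*% t(R), 2, shift, "+")
  }
  bam_structure(
    id = "toy_domain_chain",
    atoms = ca_table(chain, POTRA_ANCHORS, pts,
                     resid = POTRA_ANCHOR_RESIDUES),
    source_format = "synthetic",
    meta = list(true_angles = angles, arm_length = arm_length)
  )
}

#' Rotate the distal part of a chain about a hinge
#'
#' Residues with author numbers strictly after the hinge residue are
#' rotated rigidly about an axis through the hinge C-alpha; everything
#' else is untouched. This is the ground-truth generator for hinge
#' detection: a residue at distance r from the hinge axis moves by the
#' chord length 2 r sin(theta/2).
#'
#' @param structure A [bam_structure()].
#' @param chain Chain to bend.
#' @param hinge_residue Author number of the pivot residue (must exist).
#' @param axis Rotation axis direction.
#' @param angle_deg Rotation angle in degrees.
#' @return Transformed [bam_structure()] with `meta$true_hinge` recorded.
#' @export
apply_hinge <- function(structure, chain, hinge_residue, axis = c(0, 0, 1),
                        angle_deg = 10) {
  r <- resolve_selection(structure, selection(chain, hinge_residue, "CA"))
  if (length(r$missing) > 0) {
    stop("hinge residue ", hinge_residue, " not present on chain ", chain)
  }
  pivot <- r$points[1, ]
  R <- rotation_about_axis(axis, angle_deg)
  a <- structure$atoms
  move <- a$chain == chain & a$resno > hinge_residue
  if (any(move)) {
    pts <- as.matrix(a[move, c("x", "y", "z")])
    pts <- sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
    a$x[move] <- pts[, 1]; a$y[move] <- pts[, 2]; a$z[move] <- pts[, 3]
  }
  structure$atoms <- a
  structure$meta$true_hinge <- list(chain = chain, residue = hinge_residue,
                                    axis = axis / vnorm(axis),
                                    angle_deg = angle_deg)
  structure
}

#' Simulate a saturating folding-assay trace
#'
#' F(t) = plateau (1 - exp(-k t)) + drift, with linear plateau drift
#' starting where the exponential rate has decayed to 1 percent of its
#' initial value, plus Gaussian noise: an idealized fluorogenic OmpT
#' folding readout sampled every `dt` seconds. The true half-time
#' ln(2)/k is recorded in the `truth` attribute.
#'
#' @param k Folding rate constant, 1/s.
#' @param plateau Plateau amplitude, a.u.
#' @param drift_slope Linear plateau drift, a.u./s (default 0).
#' @param noise_sd Gaussian noise sd, a.u. (default 0).
#' @param dt Sampling interval, s (default 10, the plate-reader cadence).
#' @param duration Total duration, s (default 8/k, well into saturation).
#' @param seed Optional seed for the noise.
#' @param label Condition label.
#' @return A [kinetic_trace()] with attribute `truth` = list(k, half_time,
#'   plateau).
#' @export
simulate_trace <- function(k, plateau, drift_slope = 0, noise_sd = 0,
                           dt = 10, duration = 8 / k, seed = NULL,
                           label = "sim") {
  stopifnot(k > 0, plateau > 0, dt > 0)
  t <- seq(0, duration, by = dt)
  t_plateau <- log(100) / k
  y <- plateau * (1 - exp(-k * t)) + drift_slope * pmax(0, t - t_plateau)
  if (noise_sd > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(t), sd = noise_sd))
  }
  tr <- kinetic_trace(t, y, label = label)
  attr(tr, "truth") <- list(k = k, half_time = log(2) / k, plateau = plateau)
  tr
}

#' Simulate an electrospray charge-state series
#'
#' Peaks at (M + z p)/z for z in `z_min..z_max`, in ascending m/z order,
#' with optional Gaussian m/z noise. The true neutral mass is recorded in
#' the `truth` attribute.
#'
#' @param mass Neutral mass M in Da.
#' @param z_min,z_max Inclusive charge range (>= 1).
#' @param mz_noise_sd Gaussian m/z noise sd in Th (default 0).
#' @param seed Optional seed for the noise.
#' @param proton_mass Proton mass in Da.
#' @return A [peak_series()] with attribute `truth` = list(mass, charges).
#' @export
simulate_charge_series <- function(mass, z_min, z_max, mz_noise_sd = 0,
                                   seed = NULL, proton_mass = PROTON_MASS) {
  stopifnot(z_min >= 1, z_max >= z_min, mass > 0)
  z <- z_max:z_min                       # ascending m/z
  mz <- (mass + z * proton_mass) / z
  if (mz_noise_sd > 0) {
    mz <- mz + with_seed(seed, stats::rnorm(length(mz), sd = mz_noise_sd))
    mz <- sort(mz)
  }
  ps <- peak_series(mz)
  attr(ps, "truth") <- list(mass = mass, charges = z)
  ps
}
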