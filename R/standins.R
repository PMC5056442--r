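#' Synthetic stand-in BAM complex
#'
#' Builds a fully synthetic, geometry-only stand-in for the BamABCDE
#' complex in one of three conformations, emulating the relative geometry
#' reported for the deposited models (cryo-EM model, lateral-closed
#' BamB-containing crystal form, lateral-open BamB-less crystal form).
#' These are NOT the deposited coordinates: they are C-alpha point models
#' whose designed quantities (POTRA inter-domain angles, vertical POTRA
#' extension below the membrane slab, BamD hinge flex, lateral-gate
#' separation) take the published values, so the full deposited-model
#' workflow — write to PDB, reload, profile angles, estimate the membrane
#' frame, measure extension, superpose on BamE, detect the BamD hinge,
#' classify the gate — can run and be validated end to end without any
#' download.
#'
#' Designed geometry by conformation:
#' \describe{
#'   \item{`"em"`}{POTRA profile with P2-P3 = 120 deg, POTRA chain
#'     extended 20 Angstrom below the periplasmic slab face, lateral gate
#'     open, BamD N-terminal half flexed about residue 157 with 6 Angstrom
#'     mean displacement (relative to the other conformations).}
#'   \item{`"lateral_closed"`}{P2-P3 = 120 deg (BamB-present, wide),
#'     compact POTRA chain (2 Angstrom below the face), gate closed.}
#'   \item{`"lateral_open"`}{P2-P3 = 107 deg (in the 104-110 deg band),
#'     extended POTRA chain (18 Angstrom), gate open, BamD unflexed.}
#' }
#'
#' Chains: A = BamA (POTRA anchors 24/93/175/266/345/421 plus a 64-point
#' toy barrel numbered 424-808 with gate residues 430/808 carrying CB
#' atoms), D = BamD (C-alpha chain 30-240), E = BamE (C-alpha chain
#' 20-110, identical across conformations so it can anchor partial
#' superpositions). All designed values are recorded in `meta$design`.
#'
#' @param conformation `"em"`, `"lateral_closed"` or `"lateral_open"`.
#' @param seed Optional seed; when given, the whole complex is placed at a
#'   seeded random rigid pose (exercising pose-independence of every
#'   downstream measurement).
#' @return A [bam_structure()].
#' @export
synthetic_bam_complex <- function(conformation = c("em", "lateral_closed",
                                                   "lateral_open"),
                                  seed = NULL) {
  conformation <- match.arg(conformation)
  cfg <- switch(conformation,
    em = list(angles = c(102, 120, 135, 118), extension = 20,
              gate_cb = 12, bamd_flex = TRUE),
    lateral_closed = list(angles = c(95, 120, 128, 112), extension = 2,
                          gate_cb = 4.5, bamd_flex = FALSE),
    lateral_open = list(angles = c(98, 107, 130, 120), extension = 18,
                        gate_cb = 12, bamd_flex = FALSE))

  ## --- BamA barrel: cylinder r=15, h=40 about z, resno 424..808 ---
  barrel <- make_toy_barrel(n_points = 64, radius = 15, height = 40,
                            axis = c(0, 0, 1), chain = "A")
  ## renumber into the barrel range, skipping the gate numbers 430/808
  ## which get explicit atoms below; keep all 64 points so the antipodal
  ## pairing (and with it the exact principal axis) is preserved
  resno <- seq(425, 803, by = 6)
  ba <- barrel$atoms
  ba$resno <- as.integer(resno)
  extracellular_ref <- resno[which.max(ba$z)]   # at the +z rim

  ## gate residues 430 (beta-1) and 808 (beta-16) astride the seam at
  ## mid-height; CB 1.5 A radially inward of CA
  half_sep <- asin(cfg$gate_cb / (2 * 13.5))  # half seam angle
  gate <- do.call(rbind, lapply(list(c(430L, -1), c(808L, 1)), function(g) {
    phi <- g[2] * half_sep
    ca <- c(15 * cos(phi), 15 * sin(phi), 0)
    cb <- c(13.5 * cos(phi), 13.5 * sin(phi), 0)
    rbind(ca_table("A", g[1], ca, resid = "CYS"),
          ca_table("A", g[1], cb, resid = "CYS", elety = "CB"))
  }))

  ## --- POTRA anchor chain, in the x-z plane, hanging below the barrel ---
  potra <- make_domain_chain(cfg$angles, arm_length = 30, chain = "A")
  pp <- as.matrix(potra$atoms[, c("x", "y", "z")])
  pp <- pp %*% t(rotation_about_axis(c(1, 0, 0), 90))  # xy-plane -> xz-plane
  ## place so the deepest anchor sits `extension` below the slab face (z=-20)
  target_min_z <- -20 - cfg$extension
  pp[, 3] <- pp[, 3] + (target_min_z - min(pp[, 3]))
  pp[, 1] <- pp[, 1] - mean(pp[, 1]) + 25          # off to the barrel side
  pa <- potra$atoms
  pa$x <- pp[, 1]; pa$y <- pp[, 2]; pa$z <- pp[, 3]

  ## --- BamD: straight C-alpha chain 30..240 along x at z = -25 ---
  nd <- 240 - 30 + 1
  dx <- (seq_len(nd) - 1) * 3.8
  dpts <- cbind(dx - 400, rep(40, nd), rep(-25, nd))
  if (cfg$bamd_flex) {
    hinge_i <- which((30:240) == 157)
    pivot <- dpts[hinge_i, ]
    ## rotate the N-terminal half (residues < 157) about z through the
    ## hinge CA; angle chosen so the N-half mean displacement is 6 A
    m_mean <- mean(seq_len(hinge_i - 1))
    theta <- 2 * asin(6 / (2 * 3.8 * m_mean)) * 180 / pi
    R <- rotation_about_axis(c(0, 0, 1), theta)
    idx <- seq_len(hinge_i - 1)
    dpts[idx, ] <- sweep(sweep(dpts[idx, , drop = FALSE], 2, pivot) %*% t(R),
                         2, pivot, "+")
  }
  da <- ca_table("D", 30:240, dpts)

  ## --- BamE: helical C-alpha chain 20..110, identical in all forms ---
  ne <- 110 - 20 + 1
  i <- seq_len(ne) - 1
  epts <- cbind(-40 + 2.3 * cos(i * 100 * pi / 180),
                55 + 2.3 * sin(i * 100 * pi / 180),
                -28 + 0.3 * i)
  ea <- ca_table("E", 20:110, epts)

  atoms <- rbind(pa, ba, gate, da, ea)
  s <- bam_structure(
    id = paste0("synthetic_bam_", conformation),
    atoms = atoms, source_format = "synthetic",
    meta = list(design = c(cfg, list(conformation = conformation,
                                     extracellular_ref = extracellular_ref,
                                     bamd_hinge = 157L)))
  )
  if (!is.null(seed)) {
    s <- apply_transform(s, random_rotation(seed),
                         with_seed(seed + 17L, stats::runif(3, -30, 30)))
  }
  s
}
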