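test_that("vertex angle handles orthogonal, collinear and degenerate input", {
  expect_equal(interdomain_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_equal(interdomain_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 180)
  ## symmetric in the flanking points
  p <- list(c(1, 2, 3), c(0, -1, 2), c(-4, 0, 1))
  expect_equal(interdomain_angle(p[[1]], p[[2]], p[[3]]),
               interdomain_angle(p[[3]], p[[2]], p[[1]]))
  expect_error(interdomain_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
})

test_that("angle profile round-trips prescribed angles through the generator", {
  set.seed(42)
  for (i in 1:25) {
    ang <- runif(4, 20, 175)
    s <- make_domain_chain(ang, seed = i)
    prof <- potra_angle_profile(s, "A")
    expect_lt(max(abs(unclass(prof) - ang)), 1e-6)
  }
  ## collinear chain
  prof180 <- potra_angle_profile(make_domain_chain(rep(180, 4)), "A")
  expect_equal(as.numeric(prof180), rep(180, 4))
})

test_that("angle profile reports anchor identities and missing anchors", {
  s <- make_domain_chain(c(100, 110, 120, 130))
  prof <- potra_angle_profile(s, "A")
  expect_equal(attr(prof, "anchor_resid"), POTRA_ANCHOR_RESIDUES)
  s$atoms <- s$atoms[s$atoms$resno != 93L, ]
  expect_error(potra_angle_profile(s, "A"), "93")
})

test_that("membrane frame recovers the barrel axis, also after rotation", {
  b <- make_toy_barrel()
  fr <- estimate_membrane_frame(b, selection("A", NULL), 64)
  expect_lt(max(abs(fr$normal - c(0, 0, 1))), 1e-6)
  expect_equal(sqrt(sum(fr$normal^2)), 1, tolerance = 1e-9)
  ## known rotation
  R <- rotation_about_axis(c(2, -1, 4), 53)
  axis_true <- as.vector(R %*% c(0, 0, 1))
  b2 <- make_toy_barrel(axis = axis_true)
  fr2 <- estimate_membrane_frame(b2, selection("A", NULL), 64)
  expect_lt(max(abs(fr2$normal - axis_true)), 1e-6)
})

test_that("axis estimate stays within 2 degrees under 5% coordinate noise", {
  devs <- vapply(1:15, function(s) {
    b <- make_toy_barrel(noise_sd = 0.05 * 12.5, seed = s)
    fr <- estimate_membrane_frame(b, selection("A", NULL), 64)
    acos(min(1, abs(sum(fr$normal * c(0, 0, 1))))) * 180 / pi
  }, numeric(1))
  expect_lt(mean(devs), 2)
})

test_that("frame orientation follows the extracellular reference residue", {
  b <- make_toy_barrel()
  up <- estimate_membrane_frame(b, selection("A", NULL), 64)   # top rim
  down <- estimate_membrane_frame(b, selection("A", NULL), 1)  # bottom rim
  expect_equal(down$normal, -up$normal, tolerance = 1e-9)
  expect_equal(down$origin, up$origin, tolerance = 1e-9)
})

test_that("degenerate barrel clouds are rejected", {
  flat <- straight_chain(20, chain = "A")
  expect_error(estimate_membrane_frame(flat, selection("A", NULL), 1),
               "degenerate")
  expect_error(estimate_membrane_frame(straight_chain(5, chain = "A"),
                                       selection("A", NULL), 1),
               "at least 12")
})

test_that("vertical extension measures overhang below the periplasmic face", {
  b <- make_toy_barrel()                       # slab face at z = -20
  fr <- estimate_membrane_frame(b, selection("A", NULL), 64)
  ## selection entirely inside the slab
  expect_equal(vertical_extension(b, fr, selection("A", NULL)), 0)
  ## a point placed 35 A below the face
  extra <- bam_structure("probe", rbind(
    b$atoms,
    data.frame(chain = "P", resno = 1L, insert = "", resid = "GLY",
               elety = "CA", x = 0, y = 0, z = -55, occ = 1, alt = "")))
  expect_equal(vertical_extension(extra, fr, selection("P", 1)), 35,
               tolerance = 1e-6)
  expect_error(vertical_extension(b, fr, selection("A", 9999)), "empty",
               ignore.case = TRUE)
})

test_that("gate metrics classify closed/open with an inclusive threshold", {
  mk <- function(d_cb) {
    atoms <- rbind(
      data.frame(chain = "A", resno = 430L, insert = "", resid = "CYS",
                 elety = c("CA", "CB"), x = c(0, 0), y = 0, z = c(1, 0),
                 occ = 1, alt = ""),
      data.frame(chain = "A", resno = 808L, insert = "", resid = "CYS",
                 elety = c("CA", "CB"), x = c(d_cb, d_cb), y = 0,
                 z = c(1, 0), occ = 1, alt = ""))
    bam_structure("gate", atoms)
  }
  expect_equal(gate_metrics(mk(0), "A")$distance, 0)
  expect_equal(gate_metrics(mk(0), "A")$state, "closed")
  ## exactly at the threshold counts as closed
  expect_equal(gate_metrics(mk(6), "A")$state, "closed")
  expect_equal(gate_metrics(mk(6.01), "A")$state, "open")
  ## CA mode uses its own default threshold
  g <- gate_metrics(mk(7), "A", atom = "CA")
  expect_equal(g$state, "closed")
  expect_equal(g$threshold, 8)
})

test_that("gate CB falls back to CA for glycine, errors when absent", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 430L, insert = "", resid = "GLY",
               elety = "CA", x = 0, y = 0, z = 0, occ = 1, alt = ""),
    data.frame(chain = "A", resno = 808L, insert = "", resid = "CYS",
               elety = c("CA", "CB"), x = c(3, 3), y = 0, z = 0,
               occ = 1, alt = ""))
  s <- bam_structure("gly_gate", atoms)
  expect_warning(g <- gate_metrics(s, "A"), "CA")
  expect_equal(g$distance, 3)
  s2 <- s
  s2$atoms <- s2$atoms[s2$atoms$resno != 808L, ]
  expect_error(suppressWarnings(gate_metrics(s2, "A")), "808")
})

test_that("angles and gate distances are rigid-motion invariant", {
  em <- synthetic_bam_complex("em")
  prof0 <- unclass(potra_angle_profile(em, "A"))
  gate0 <- gate_metrics(em, "A")$distance
  for (s in 1:10) {
    moved <- random_pose(em, s)
    expect_lt(max(abs(unclass(potra_angle_profile(moved, "A")) - prof0)),
              1e-6)
    expect_lt(abs(gate_metrics(moved, "A")$distance - gate0), 1e-6)
  }
})
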