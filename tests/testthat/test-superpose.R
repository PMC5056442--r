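test_that("superposing identical sets gives identity and zero rmsd", {
  set.seed(3)
  P <- matrix(rnorm(18, sd = 10), 6, 3)
  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("superposition recovers the inverse of a rigid transform", {
  set.seed(4)
  P <- matrix(rnorm(21, sd = 8), 7, 3)
  R <- random_rotation(11); tv <- c(4, -7, 2)
  Q <- sweep(P %*% t(R), 2, tv, "+")
  s <- kabsch_superpose(Q, P)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$rotation, t(R), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 point")
  expect_error(kabsch_superpose(P[1:4, ], P), "length")
})

test_that("least-squares rmsd matches the brute-force rotation oracle", {
  for (i in 1:4) {
    set.seed(100 + i)
    n <- sample(4:8, 1)
    P <- matrix(rnorm(3 * n, sd = 6), n, 3)
    Q <- sweep(P %*% t(random_rotation(200 + i)), 2, rnorm(3, sd = 5), "+") +
      matrix(rnorm(3 * n, sd = 0.4), n, 3)
    fit <- kabsch_superpose(Q, P)
    oracle <- brute_force_min_rmsd(Q, P)
    expect_lt(abs(fit$rmsd - oracle), 1e-3)
    expect_lte(fit$rmsd, oracle + 1e-9)   # never worse than any grid point
  }
})

test_that("a structure aligned against itself shows zero displacement", {
  em <- synthetic_bam_complex("em", seed = 5)
  fl <- partial_align_displacement(em, em, selection("E", NULL),
                                  selection("D", NULL))
  expect_lt(max(fl$per_residue$displacement), 1e-9)
  fl <- detect_hinge(fl)
  expect_true(is.na(fl$hinge_residue))
})

test_that("hinge rotation displaces residues by the chord length", {
  ch <- straight_chain(60, chain = "D", resno_start = 100L)
  for (theta in c(12, 35, 60)) {
    bent <- apply_hinge(ch, "D", 130L, axis = c(0, 0, 1), angle_deg = theta)
    fl <- partial_align_displacement(ch, bent, selection("D", 100:130),
                                     selection("D", NULL))
    moved <- fl$per_residue[fl$per_residue$resno > 130, ]
    r <- 3.8 * (moved$resno - 130)
    expect_lt(max(abs(moved$displacement - 2 * r * sin(theta * pi / 360))),
              1e-6)
    still <- fl$per_residue[fl$per_residue$resno <= 130, ]
    expect_lt(max(still$displacement), 1e-9)
  }
})

test_that("hinge detection finds a noise-free step exactly and obeys bounds", {
  mk_report <- function(disp, resno = seq_along(disp)) {
    structure(list(per_residue = data.frame(resno = resno,
                                            displacement = disp),
                   hinge_residue = NA_integer_,
                   mean_pre_hinge = NA_real_, mean_post_hinge = NA_real_),
              class = "flex_report")
  }
  ## all-zero -> none
  expect_true(is.na(detect_hinge(mk_report(rep(0, 30)))$hinge_residue))
  ## step 0 -> 5 at residue 18
  disp <- c(rep(0, 17), rep(5, 23))
  expect_equal(detect_hinge(mk_report(disp))$hinge_residue, 18L)
  ## anchored end may be on either side
  expect_equal(detect_hinge(mk_report(rev(disp)))$hinge_residue, 23L)
  ## window must fit
  expect_error(detect_hinge(mk_report(rep(1, 8))), "at least")
  expect_error(detect_hinge(mk_report(rep(1, 30)), smoothing_window = 4),
               "odd")
})

test_that("applied hinges are recovered exactly across angles and poses", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(115:160, 1)
    theta <- runif(1, 5, 60)
    ch <- straight_chain(120, chain = "D", resno_start = 80L)
    bent <- random_pose(apply_hinge(ch, "D", k, angle_deg = theta), i)
    fl <- partial_align_displacement(ch, bent, selection("D", 80:k),
                                     selection("D", NULL))
    fl <- detect_hinge(fl)
    expect_equal(fl$hinge_residue, k)
  }
})
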