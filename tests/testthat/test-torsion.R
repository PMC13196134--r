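# Articular patch areas, epiphysis frame construction and torsion angles.

test_that("patch area sums triangle areas and scales quadratically", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  p <- articular_patch(sq)
  expect_equal(patch_area(p), 1)
  doubled <- articular_patch(triangle_mesh(sq$vertices * 2, sq$faces))
  expect_equal(patch_area(doubled), 4)
  expect_error(articular_patch(sq, integer(0)), "empty")

  # dense spherical cap vs the closed-form cap area 2 pi r^2 (1 - cos a)
  cap <- halluxrom:::.spherical_cap_mesh(3, c(0, 0, 0), c(1, 0, 0),
                                         40 * pi / 180, nphi = 96,
                                         nrings = 48)
  expect_equal(patch_area(articular_patch(cap)),
               2 * pi * 9 * (1 - cos(40 * pi / 180)), tolerance = 0.002)
})

test_that("epiphysis frames encode the constructed twist per convention", {
  sq <- triangle_mesh(rbind(c(0, 0, 0), c(0, 1, 0), c(0, 1, 1), c(0, 0, 1)),
                      rbind(c(1, 2, 3), c(1, 3, 4)))
  prox <- articular_patch(sq)
  dist <- articular_patch(triangle_mesh(sweep(sq$vertices, 2, c(20, 0, 0),
                                              "+"), sq$faces))
  cyl_y <- cylinder(c(20, 0, 0), c(0, 1, 0), 1.5)
  cyl_z <- cylinder(c(0, 0, 0), c(0, 0, 1), 1.8)

  # primate convention, zero twist: distal y tracks the head cylinder (y),
  # proximal z tracks the proximal cylinder (z) -> identical axes
  fr <- build_epiphysis_frames(prox, dist, cyl_y, cyl_z, "primate_marsupial")
  expect_equal(fr$proximal_frame$basis, fr$distal_frame$basis,
               tolerance = 1e-9)
  expect_equal(torsion_angle(fr$proximal_frame, fr$distal_frame), 0,
               tolerance = 1e-9)

  # head cylinder twisted 40 degrees about the long axis
  tw <- 40 * pi / 180
  cyl_tw <- cylinder(c(20, 0, 0), c(0, cos(tw), sin(tw)), 1.5)
  fr2 <- build_epiphysis_frames(prox, dist, cyl_tw, cyl_z,
                                "primate_marsupial")
  expect_equal(torsion_angle(fr2$proximal_frame, fr2$distal_frame), 40,
               tolerance = 1e-6)

  # rodent convention assigns the head cylinder to distal z instead: twist
  # the zero-reference z axis by 40 degrees about the long axis
  cyl_tw_z <- cylinder(c(20, 0, 0), c(0, -sin(tw), cos(tw)), 1.5)
  fr3 <- build_epiphysis_frames(prox, dist, cyl_tw_z,
                                cylinder(c(0, 0, 0), c(0, 1, 0), 1.8),
                                "rodent_scandentian")
  expect_equal(torsion_angle(fr3$proximal_frame, fr3$distal_frame), 40,
               tolerance = 1e-6)

  # cylinder axis along the long axis is degenerate
  expect_error(build_epiphysis_frames(prox, dist,
                                      cylinder(c(20, 0, 0), c(1, 0.02, 0), 1.5),
                                      cyl_z, "primate_marsupial"),
               "5 degrees")
})

test_that("torsion angle is unsigned, symmetric and rigid-invariant", {
  f1 <- identity_frame()
  expect_equal(torsion_angle(f1, f1), 0)
  tw <- 51 * pi / 180
  f2 <- frame(c(0, 0, 0), c(1, 0, 0),
              c(0, cos(tw), sin(tw)), c(0, -sin(tw), cos(tw)))
  expect_equal(torsion_angle(f1, f2), 51, tolerance = 1e-9)
  expect_equal(torsion_angle(f2, f1), torsion_angle(f1, f2))
  set.seed(91)
  R <- random_rotation()
  g1 <- frame(c(1, 2, 3), R %*% f1$basis[, 1], R %*% f1$basis[, 2],
              R %*% f1$basis[, 3])
  g2 <- frame(c(4, 5, 6), R %*% f2$basis[, 1], R %*% f2$basis[, 2],
              R %*% f2$basis[, 3])
  expect_equal(torsion_angle(g1, g2), 51, tolerance = 1e-9)
  # frames with different x directions are rejected
  f3 <- frame(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  expect_error(torsion_angle(f1, f3), "x direction")
})

test_that("synthetic metatarsal twists are recovered within 2 degrees", {
  for (tw in c(2, 39, 86)) {
    for (seed in 1:3) {
      mt <- make_synthetic_metatarsal(tw, seed = seed)
      res <- measure_metatarsal_torsion(mt$proximal_patch, mt$distal_patch,
                                        mt$head_points, mt$proximal_points,
                                        mt$head_axis_init,
                                        mt$proximal_axis_init,
                                        mt$convention)
      expect_lt(abs(res$alpha_deg - tw), 2)
    }
  }
  # the rodent/scandentian frame assignment recovers the twist as well
  mt <- make_synthetic_metatarsal(25, seed = 4,
                                  convention = "rodent_scandentian")
  res <- measure_metatarsal_torsion(mt$proximal_patch, mt$distal_patch,
                                    mt$head_points, mt$proximal_points,
                                    mt$head_axis_init, mt$proximal_axis_init,
                                    mt$convention)
  expect_lt(abs(res$alpha_deg - 25), 2)
})
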