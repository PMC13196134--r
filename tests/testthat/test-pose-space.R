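# Cosine correction, critical alpha, alpha shapes and excursions.

test_that("cosine correction follows zcc = z cos(y) and its edge cases", {
  expect_equal(unname(unlist(cosine_correct(
    data.frame(z_deg = 0, y_deg = 0, x_deg = 0)))), c(0, 0, 0))
  cc <- cosine_correct(data.frame(z_deg = 100, y_deg = 60, x_deg = 10))
  expect_equal(c(cc$zcc, cc$ycc, cc$xcc), c(50, 60, 10), tolerance = 1e-12)
  cc90 <- cosine_correct(data.frame(z_deg = c(170, -45), y_deg = c(90, -90),
                                    x_deg = c(7, -7)))
  expect_equal(cc90$zcc, c(0, 0), tolerance = 1e-12)
  expect_error(cosine_correct(data.frame(z_deg = 0, y_deg = 95, x_deg = 0)),
               "90")
})

test_that("cosine correction preserves y and x and shrinks |z|", {
  set.seed(71)
  poses <- data.frame(z_deg = runif(200, -180, 180) - 1e-9,
                      y_deg = runif(200, -90, 90),
                      x_deg = runif(200, -180, 180) - 1e-9)
  cc <- cosine_correct(poses)
  expect_identical(cc$ycc, poses$y_deg)
  expect_identical(cc$xcc, poses$x_deg)
  expect_true(all(abs(cc$zcc) <= abs(poses$z_deg) + 1e-12))
})

test_that("critical alpha: regular tetrahedron, split clusters, dense bound", {
  a <- 10
  tet <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  expect_equal(critical_alpha(tet), a * sqrt(3 / 8), tolerance = 1e-4)

  set.seed(72)
  c1 <- matrix(runif(60), ncol = 3)
  c2 <- c1
  c2[, 1] <- c2[, 1] + 100
  expect_gte(critical_alpha(rbind(c1, c2)), 50)

  cloud <- matrix(runif(900), ncol = 3)
  d <- delaunay_tetrahedra(cloud)
  expect_lte(critical_alpha(cloud), max(d$circumradius))
  expect_error(critical_alpha(tet[1:3, ]), "4")
})

test_that("select_alpha applies the floor-or-critical rule", {
  cs <- expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10))
  sel <- select_alpha(cs)  # critical ~ 8.66 below the floor
  expect_equal(as.numeric(sel), 50)
  expect_equal(attr(sel, "critical_alpha"), sqrt(3) * 5, tolerance = 1e-4)

  set.seed(73)
  c1 <- matrix(runif(60), ncol = 3)
  c2 <- c1
  c2[, 1] <- c2[, 1] + 100
  sel2 <- select_alpha(rbind(c1, c2))  # critical exceeds the floor
  expect_equal(as.numeric(sel2), attr(sel2, "critical_alpha"))
  expect_gt(as.numeric(sel2), 50)
})

test_that("alpha shape volume: hull limit, split clusters, degenerate input", {
  cs <- expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10))
  expect_equal(alpha_shape(cs, 1e6)$volume, 1000, tolerance = 1e-2)
  expect_error(alpha_shape(cs[1:3, ], 10), "4")

  # two cubes 100 apart: alpha above the cube circumradius (8.66) but far
  # below the bridging radius keeps exactly the two hulls
  c2 <- cs
  c2$x <- c2$x + 100
  split <- alpha_shape(rbind(cs, c2), 20)
  expect_equal(split$volume, 2000, tolerance = 0.05 * 2000)

  flat <- expand.grid(x = 0:3, y = 0:3)
  flat$z <- 0
  expect_warning(res <- alpha_shape(flat, 10), "coplanar")
  expect_equal(res$volume, 0)
})

test_that("alpha shape volume is monotone in alpha and reaches the hull", {
  P <- quasirandom_cloud(500)
  vols <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.6), function(a) {
    alpha_shape(P, a)$volume
  }, numeric(1))
  expect_true(all(diff(vols) >= -1e-12))
  # alpha -> infinity limit equals the independently computed hull volume
  expect_equal(alpha_shape(P, 1e9)$volume, HULL_VOL_QUASI_500,
               tolerance = 1e-5)
})

test_that("uniformly random rotations are uniform in corrected (zcc, ycc)", {
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    n <- 10000
    q <- matrix(rnorm(4 * n), ncol = 4)
    q <- q / sqrt(rowSums(q^2))
    ang <- t(apply(q, 1, function(qi) euler_zyx(quat_to_matrix(qi))))
    zcc <- ang[, 1] * cos(ang[, 2] * pi / 180)
    ycc <- ang[, 2]
    # inside |ycc| < 60, |zcc| < 90 the corrected density is exactly uniform
    sel <- abs(ycc) < 60 & abs(zcc) < 90
    counts <- table(cut(zcc[sel], seq(-90, 90, 30)),
                    cut(ycc[sel], seq(-60, 60, 30)))
    expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
  }
})

test_that("excursion summary matches a linear scan", {
  one <- excursion_summary(data.frame(zcc = 5, ycc = -10, xcc = 20))
  expect_equal(one$min, one$max)
  expect_equal(one$min, c(5, -10, 20))
  two <- excursion_summary(data.frame(zcc = c(0, 10), ycc = c(0, -20),
                                      xcc = c(0, 30)))
  expect_equal(two$min, c(0, -20, 0))
  expect_equal(two$max, c(10, 0, 30))
  set.seed(74)
  cloud <- data.frame(zcc = rnorm(100), ycc = rnorm(100), xcc = rnorm(100))
  es <- excursion_summary(cloud)
  expect_equal(es$min, unname(sapply(cloud, min)))
  expect_equal(es$max, unname(sapply(cloud, max)))
  expect_error(excursion_summary(cloud[0, ]), "empty")
})
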