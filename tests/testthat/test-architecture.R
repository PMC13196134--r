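# Storage corrections, muscle lengths, ACSA, body-mass normalization and
# the Pearson correlation gate.

test_that("storage corrections apply and compose the stated factors", {
  expect_equal(corrected_volume(1, "ethanol_long"), 2.49)
  expect_equal(corrected_volume(1, "ethanol_short"), 1.64)
  expect_equal(corrected_volume(1, "formalin_month"), 1.32)
  expect_equal(corrected_volume(10, c("ethanol_short", "formalin_month")),
               21.648)
  expect_equal(corrected_volume(5, character(0)), 5)
  # linearity and flag-order independence
  expect_equal(corrected_volume(7, c("formalin_month", "ethanol_short")),
               7 * corrected_volume(1, c("ethanol_short", "formalin_month")))
  expect_error(corrected_volume(1, c("ethanol_short", "ethanol_long")),
               "exclusive")
  expect_error(corrected_volume(1, "air_dried"), "unknown")
})

test_that("muscle length handles straight, curved and multi-belly chains", {
  expect_equal(muscle_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  expect_equal(muscle_length(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 5))), 10)
  expect_equal(muscle_length(list(rbind(c(0, 0, 0), c(8, 0, 0)),
                                  rbind(c(0, 0, 0), c(0, 12, 0)))), 10)
  expect_error(muscle_length(rbind(c(1, 1, 1), c(1, 1, 1))), "duplicate")
  # rigid invariance
  set.seed(101)
  ch <- rbind(runif(3), runif(3), runif(3))
  tf <- random_rigid()
  expect_equal(muscle_length(ch), muscle_length(transform_points(tf, ch)),
               tolerance = 1e-9)
})

test_that("ACSA is volume over length", {
  expect_equal(acsa(20, 5), 4)
  expect_equal(acsa(3.7, 1), 3.7)
  expect_error(acsa(20, 0), "positive")
  set.seed(102)
  v <- runif(20, 1, 100)
  l <- runif(20, 1, 50)
  expect_equal(acsa(v, l), v / l)
})

test_that("mass normalization reproduces the worked relative ACSA", {
  # contrahens I: ACSA 0.16 mm^2 in both specimens rounds to 0.005 at the
  # 3-decimal reporting precision for masses 196.8 g and 175.0 g
  expect_equal(round(normalize_by_mass(0.16, 196.8, 0.66), 3), 0.005)
  expect_equal(round(normalize_by_mass(0.16, 175.0, 0.66), 3), 0.005)
  expect_equal(normalize_by_mass(10, 100, 1), 0.1)
  expect_equal(normalize_by_mass(42, 1, 0.66), 42)
  expect_error(normalize_by_mass(1, 100, 0.5), "exponent")
  expect_error(normalize_by_mass(1, -1, 1), "positive")
})

test_that("the printed-identity chain rel_acsa = (vol/len)/mass^0.66 holds", {
  res <- architecture_result(raw_volume_mm3 = 12, preservation = "ethanol_long",
                             chains = rbind(c(0, 0, 0), c(0, 0, 20)),
                             body_mass_g = 150)
  expect_equal(res$acsa_mm2, res$corrected_volume_mm3 / res$length_mm)
  expect_equal(res$rel_acsa,
               (res$corrected_volume_mm3 / res$length_mm) / 150^0.66)
})

test_that("correlation gate matches the textbook formula and gates on p", {
  masses <- c(10, 20, 40, 80, 160)
  g <- correlation_gate(masses * 0.3, masses)
  expect_equal(g$r, 1, tolerance = 1e-12)
  expect_true(g$normalize)
  expect_error(correlation_gate(rep(2, 5), masses), "variance")
  expect_error(correlation_gate(1:2, 1:2), "3")

  x <- c(12.1, 15.3, 9.8, 22.4, 31.0, 27.5, 18.2, 40.9, 36.6, 25.0)
  y <- c(110, 140, 90, 210, 260, 240, 160, 390, 310, 220)
  g2 <- correlation_gate(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt(8 / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = 8)
  expect_equal(g2$r, r, tolerance = 1e-10)
  expect_equal(g2$p, p, tolerance = 1e-10)
})

test_that("architecture table gates per muscle and species count", {
  set.seed(103)
  masses <- c(10, 25, 60, 150, 300, 45)
  records <- data.frame(
    specimen = sprintf("S%d", 1:6),
    species = c("a", "b", "c", "d", "e", "f"),
    muscle = "fhb",
    raw_volume_mm3 = 0.4 * masses * exp(rnorm(6, 0, 0.05)),
    body_mass_g = masses,
    length_mm = 2 * masses^0.33,
    ethanol_short = FALSE, ethanol_long = FALSE, formalin_month = FALSE)
  rare <- data.frame(
    specimen = c("S1", "S2"), species = c("a", "a"), muscle = "contrahens1",
    raw_volume_mm3 = c(1.2, 1.5), body_mass_g = c(10, 25),
    length_mm = c(8, 9),
    ethanol_short = FALSE, ethanol_long = FALSE, formalin_month = FALSE)
  tab <- architecture_table(rbind(records, rare))
  fhb <- tab[tab$muscle == "fhb", ]
  expect_true(all(fhb$gated))
  expect_true(all(!is.na(fhb$rel_volume)))  # strongly mass-correlated
  expect_equal(fhb$rel_volume,
               round(fhb$corrected_volume_mm3 / fhb$body_mass_g, 3))
  # a muscle present in one species is never normalized
  c1 <- tab[tab$muscle == "contrahens1", ]
  expect_true(all(!c1$gated))
  expect_true(all(is.na(c1$rel_acsa)))
})
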