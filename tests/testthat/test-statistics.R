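# Histogram -> energy conversion, interpolation and term statistics.

test_that("energy_from_counts implements the inverse Boltzmann relation", {
  h <- feature_histogram(c(0.5, 0.5, 1.5, 1.5), breaks_x = c(0, 1, 2))
  tab <- energy_from_counts(h)                 # uniform background
  expect_equal(unname(tab$energy), c(0, 0))

  # p = 2 * p_bg in the first bin of three
  h3 <- feature_histogram(rep(c(0.5, 1.5, 2.5), c(4, 1, 1)), c(0, 1, 2, 3))
  tab3 <- energy_from_counts(h3, background = c(1, 1, 1) / 3)
  expect_equal(tab3$energy[1], -log(2))

  # under-populated bins become repulsive at 18 BCLEU
  h2 <- feature_histogram(rep(c(0.5, 1.5), c(10, 1)), c(0, 1, 2))
  tab2 <- energy_from_counts(h2, min_count = 2)
  expect_equal(tab2$energy[2], 18)

  expect_warning(t0 <- energy_from_counts(
    feature_histogram(numeric(0), c(0, 1, 2))), "all-zero")
  expect_equal(unname(t0$energy), c(18, 18))

  expect_error(energy_from_counts(h, background = c(1, 1)), "sum to 1")
  expect_error(energy_from_counts(h, background = c(0, 1)), "zero where")
})

test_that("scaling all counts leaves the energies unchanged", {
  set.seed(21)
  x <- runif(500, 0, 10)
  h1 <- feature_histogram(x, seq(0, 10))
  h2 <- h1; h2$counts <- h2$counts * 7
  e1 <- energy_from_counts(h1, min_count = 0)
  e2 <- energy_from_counts(h2, min_count = 0)
  expect_equal(e1$energy, e2$energy)
})

test_that("evaluate_table interpolates linearly between bin centers", {
  tab <- structure(list(energy = c(-1, 0, 2), breaks_x = c(0, 1, 2, 3),
                        breaks_y = NULL, oob_x = c("clamp", "clamp"),
                        oob_y = NULL, circular_y = FALSE, repulsive = 18),
                   class = "energy_table")
  expect_equal(evaluate_table(tab, 0.5), -1)            # exactly at a center
  expect_equal(evaluate_table(tab, 1.0), -0.5)          # midway
  expect_equal(evaluate_table(tab, c(-5, 10)), c(-1, 2))  # clamped
  expect_error(evaluate_table(tab, NaN), "NaN")
})

test_that("the zero policy ramps the energy to 0 at the support edge", {
  tab <- structure(list(energy = c(-1, -2), breaks_x = c(0, 1, 2),
                        breaks_y = NULL, oob_x = c("clamp", "zero"),
                        oob_y = NULL, circular_y = FALSE, repulsive = 18),
                   class = "energy_table")
  expect_equal(evaluate_table(tab, 1.5), -2)
  expect_equal(evaluate_table(tab, 1.75), -1)   # halfway up the ramp
  expect_equal(evaluate_table(tab, 2), 0)
  expect_equal(evaluate_table(tab, 25), 0)
})

test_that("2D evaluation matches the bilinear formula by hand", {
  e <- matrix(c(1, 2, 3, 4), 2, 2)   # centers (0.5, 1.5) x (5, 15)
  tab <- structure(list(energy = e, breaks_x = c(0, 1, 2),
                        breaks_y = c(0, 10, 20),
                        oob_x = c("clamp", "clamp"), oob_y = c("clamp", "clamp"),
                        circular_y = FALSE, repulsive = 18),
                   class = "energy_table")
  tx <- 0.3; ty <- 0.6
  hand <- (1 - tx) * (1 - ty) * e[1, 1] + (1 - tx) * ty * e[1, 2] +
    tx * (1 - ty) * e[2, 1] + tx * ty * e[2, 2]
  expect_equal(evaluate_table(tab, 0.5 + tx, 5 + 10 * ty), hand)
  expect_equal(evaluate_table(tab, 0.5, 5), e[1, 1])
})

test_that("circular angle axes interpolate across +/-180 continuously", {
  e <- matrix(seq(-2, 2, length.out = 24), 1, 24)
  tab <- structure(list(energy = e, breaks_x = c(0, 1),
                        breaks_y = seq(-180, 180, by = 15),
                        oob_x = c("clamp", "clamp"), oob_y = c("clamp", "clamp"),
                        circular_y = TRUE, repulsive = 18),
                   class = "energy_table")
  v1 <- evaluate_table(tab, 0.5, 179.999)
  v2 <- evaluate_table(tab, 0.5, -179.999)
  expect_lt(abs(v1 - v2), 1e-3)
  # wrap midpoint between last and first centers
  expect_equal(evaluate_table(tab, 0.5, 180), (e[1] + e[24]) / 2)
})

test_that("a single antiparallel sheet trains a pairing table peaked at its geometry", {
  set.seed(22)
  topo <- toy_topology("sheet3_anti")[1:2]
  m <- make_toy_protein(topo)
  tab <- build_term_statistics(list(m), "strand_pairing")
  ix <- arrayInd(which.min(tab$energy), dim(tab$energy))
  d_bin <- c(tab$breaks_x[ix[1]], tab$breaks_x[ix[1] + 1])
  t_bin <- c(tab$breaks_y[ix[2]], tab$breaks_y[ix[2] + 1])
  expect_true(d_bin[1] <= 4.75 && 4.75 < d_bin[2])
  expect_true(all(abs(t_bin) >= 150))  # antiparallel: |theta| near 165
})

test_that("a one-model database occupies a single radius-of-gyration bin", {
  set.seed(23)
  m <- make_toy_protein(toy_topology("helix_pair"))
  tab <- build_term_statistics(list(m), "radius_gyration")
  v <- radius_of_gyration_norm(m)
  occupied <- which(tab$energy < tab$repulsive)
  expect_length(occupied, 1L)
  expect_true(tab$breaks_x[occupied] <= v && v < tab$breaks_x[occupied + 1])
})

test_that("pair background for a uniform anchor gas grows like the shell area", {
  set.seed(24)
  n <- 400
  m <- point_model(matrix(runif(3 * n, 0, 30), ncol = 3),
                   aa = sample(c("ALA", "LEU"), n, replace = TRUE))
  tabs <- build_term_statistics(list(m), "aa_pair")
  # recover the background from the trained table of an abundant pair:
  # E = -ln(p / p_bg) and the observed p IS the marginal-driven background
  # family, so compare the raw pair-distance histogram with c * d^2
  f <- ssescore:::pair_features(m)
  h <- feature_histogram(f$d, seq(0, 20))
  d <- seq(0.5, 19.5)
  sel <- d > 2 & d < 12           # away from box-edge depletion
  fit <- lm(h$counts[sel] ~ 0 + I(d[sel]^2))
  rel <- (h$counts[sel] - fitted(fit)) / max(h$counts)
  expect_lt(sqrt(mean(rel^2)), 0.1)
  expect_true(all(c("ALA:ALA", "ALA:LEU", "LEU:LEU") %in% names(tabs)))
})

test_that("training is invariant under rigid transformation of the database", {
  set.seed(25)
  db <- make_fixture_database(4, seed = 5)
  R <- random_rotation(); tv <- runif(3, -30, 30)
  db2 <- lapply(db, global_transform, R = R, t = tv)
  t1 <- train_tables(db)
  t2 <- train_tables(db2)
  expect_equal(t1$strand_pairing$energy, t2$strand_pairing$energy, tolerance = 1e-6)
  expect_equal(t1$packing_hh$energy, t2$packing_hh$energy, tolerance = 1e-6)
  expect_equal(t1$loop_length$energy, t2$loop_length$energy, tolerance = 1e-6)
  expect_equal(t1$environment$LEU$energy, t2$environment$LEU$energy, tolerance = 1e-6)
  expect_equal(t1$contact_order$energy, t2$contact_order$energy, tolerance = 1e-6)
})

test_that("table sets survive a JSON round trip", {
  tabs <- fx_tables()
  f <- withr::local_tempfile(fileext = ".json")
  write_tables(tabs, f)
  tabs2 <- read_tables(f)
  set.seed(26)
  m <- make_toy_protein(toy_topology("beta_sandwich"))
  expect_equal(score_model(m, tabs2), score_model(m, tabs), tolerance = 1e-10)
  expect_error(read_tables(withr::local_tempfile(lines = "{}", fileext = ".json")),
               "not an ssescore")
})
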