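# The twelve scoring terms.

test_that("neighbor_count uses the 4.0/11.4 half-cosine transition", {
  at <- function(d) point_model(rbind(c(0, 0, 0), c(d, 0, 0)), seq_ids = c(1, 10))
  expect_equal(neighbor_count(at(4.0), rows = 1), 1)
  expect_equal(neighbor_count(at(7.7), rows = 1), 0.5)
  expect_equal(neighbor_count(at(11.4), rows = 1), 0)
  expect_equal(neighbor_count(at(3.0), rows = 1), 1)
  expect_equal(neighbor_count(at(15), rows = 1), 0)
  # minimal sequence separation of three residues
  near <- point_model(rbind(c(0, 0, 0), c(4, 0, 0)), seq_ids = c(1, 3))
  expect_equal(neighbor_count(near, rows = 1), 0)
})

test_that("environment and pair scores match exhaustive summation oracles", {
  set.seed(41)
  tabs <- fx_tables()
  coords <- matrix(runif(30, 0, 14), ncol = 3)
  aa <- sample(FIXTURE_ALPHABET, 10, replace = TRUE)
  m <- point_model(coords, seq_ids = seq(1, 28, by = 3), aa = aa)

  # environment: per-residue table lookups at the neighbour count
  env_oracle <- 0
  for (i in 1:10) {
    nc <- 0
    for (j in setdiff(1:10, i)) {
      if (abs(m$residues$seq_id[i] - m$residues$seq_id[j]) < 3) next
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      w <- if (d <= 4) 1 else if (d >= 11.4) 0 else
        (cos(pi * (d - 4) / 7.4) + 1) / 2
      nc <- nc + w
    }
    env_oracle <- env_oracle + evaluate_table(tabs$environment[[aa[i]]], nc)
  }
  expect_equal(score_environment(m, tabs), env_oracle, tolerance = 1e-9)

  # pair distances: all unordered pairs, seq sep >= 12, d < 20
  pair_oracle <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    if (abs(m$residues$seq_id[i] - m$residues$seq_id[j]) < 12) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d >= 20) next
    key <- paste(sort(c(aa[i], aa[j])), collapse = ":")
    pair_oracle <- pair_oracle + evaluate_table(tabs$aa_pair[[key]], d)
  }
  expect_equal(score_aa_pair(m, tabs), pair_oracle, tolerance = 1e-9)
})

test_that("pairs below 12 residues separation or beyond 20 A contribute 0", {
  tabs <- fx_tables()
  m1 <- point_model(rbind(c(0, 0, 0), c(5, 0, 0)), seq_ids = c(1, 12))  # sep 11
  expect_equal(score_aa_pair(m1, tabs), 0)
  m2 <- point_model(rbind(c(0, 0, 0), c(25, 0, 0)), seq_ids = c(1, 14))
  expect_equal(score_aa_pair(m2, tabs), 0)
})

test_that("loop length score evaluates the (n, d) table at the axis tips", {
  tabs <- fx_tables()
  set.seed(42)
  m1 <- make_toy_protein(list(list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0))))
  expect_equal(score_loop_length(m1, tabs), 0)   # single SSE

  m2 <- make_toy_protein(toy_topology("helix_pair"))
  lf <- ssescore:::loop_features(m2)
  expect_equal(nrow(lf), 1L)
  tip_a <- m2$sses[[1]]$frag$full_end[m2$sses[[1]]$frag$n_frag, ]
  tip_b <- m2$sses[[2]]$frag$full_start[1, ]
  expect_equal(lf$d, sqrt(sum((tip_b - tip_a)^2)), tolerance = 1e-9)
  expect_equal(score_loop_length(m2, tabs),
               evaluate_table(tabs$loop_length, lf$n, lf$d))

  # a 2-residue loop forced to bridge 30 A is strongly unfavourable
  e_far <- evaluate_table(tabs$loop_length, 2, 30)
  expect_gt(e_far, 2)
  expect_gt(e_far, evaluate_table(tabs$loop_length, lf$n, lf$d))
})

test_that("sse contact scores split strand pairs into pairing and sandwich", {
  tabs <- fx_tables()
  set.seed(43)
  m1 <- make_toy_protein(list(list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0))))
  expect_equal(unname(score_sse_contacts(m1, tabs)), c(0, 0))

  # ideal antiparallel sheet scored with tables trained on it: favourable
  sheet <- make_toy_protein(toy_topology("sheet3_anti")[1:2])
  own <- train_tables(list(sheet))
  sc <- score_sse_contacts(sheet, own)
  expect_lt(sc[["strand_pairing"]], 0)

  # helices 25 A apart: beyond the table support, zero contribution
  topo <- list(list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0)),
               list(type = "H", len = 9, R = diag(3), t = c(25, 0, 0)))
  far <- make_toy_protein(topo)
  expect_equal(unname(score_sse_contacts(far, tabs)), c(0, 0))
})

test_that("contact order and radius of gyration follow their definitions", {
  # no contacts
  m0 <- point_model(rbind(c(0, 0, 0), c(50, 0, 0)), seq_ids = c(1, 20))
  expect_equal(contact_order_norm(m0), 0)
  # one contact at separation s among n residues -> s^2 / n
  m1 <- point_model(rbind(c(0, 0, 0), c(5, 0, 0)), seq_ids = c(1, 8),
                    n_residues = 8)
  expect_equal(contact_order_norm(m1), 49 / 8)
  # brute force on a random cloud
  set.seed(44)
  n <- 12
  coords <- matrix(runif(3 * n, 0, 12), ncol = 3)
  m2 <- point_model(coords, seq_ids = 1:n)
  seps <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 8) seps <- c(seps, j - i)
  }
  expect_equal(contact_order_norm(m2), mean(seps)^2 / n)

  expect_equal(radius_of_gyration_norm(point_model(rbind(c(1, 2, 3)))), 0)
  two <- point_model(rbind(c(0, 0, 0), c(2, 0, 0)), n_residues = 2)
  expect_equal(radius_of_gyration_norm(two) * 2, 1.0)  # r^2 itself is 1
  cloud <- point_model(coords, seq_ids = 1:n, n_residues = n)
  r2 <- mean(colSums((t(coords) - colMeans(coords))^2))
  expect_equal(radius_of_gyration_norm(cloud), r2 / n)
})

test_that("ss agreement is minus the error function of the standard score", {
  set.seed(45)
  m <- make_toy_protein(list(list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0))))
  sq <- m$residues$seq_id
  mk_pred <- function(pH) data.frame(seq_id = sq, pH = pH, pE = 0.1, pC = 0.1)
  # p = mu -> erf(0) = 0 per residue (PSIPRED helix mu 0.76)
  expect_equal(score_ss_agreement(m, mk_pred(0.76), "PSIPRED"), 0)
  # p = mu + sigma -> -erf(1/sqrt(2)) each
  v <- score_ss_agreement(m, mk_pred(0.96), "PSIPRED")
  expect_equal(v / 9, -(2 * pnorm(1) - 1), tolerance = 1e-9)
  expect_equal(v / 9, -0.6827, tolerance = 1e-4)
  # disagreement is positive
  expect_gt(score_ss_agreement(m, mk_pred(0.2), "PSIPRED"), 0)
  # missing residues raise an error
  bad <- mk_pred(0.7)[-3, ]
  expect_error(score_ss_agreement(m, bad, "PSIPRED"), "missing prediction")
})

test_that("amino acid clash ramps from 0 at d_min to 1 at d_min - 1", {
  p <- default_clash_params()
  at <- function(d) point_model(rbind(c(0, 0, 0), c(d, 0, 0)), seq_ids = c(1, 5))
  dmin <- p$aa_min_distance["ALA", "ALA"]
  expect_equal(score_aa_clash(at(dmin), p), 0)
  expect_equal(score_aa_clash(at(dmin - 1), p), 1)
  expect_equal(score_aa_clash(at(dmin - 0.5), p), 0.5)
  expect_equal(score_aa_clash(at(dmin - 1.7), p), 1)   # capped
  # sequence-local pairs are exempt
  seqnear <- point_model(rbind(c(0, 0, 0), c(1, 0, 0)), seq_ids = c(1, 2))
  expect_equal(score_aa_clash(seqnear, p), 0)
})

test_that("SSE clash uses per-type minimum distances with a 1 A ramp", {
  p <- default_clash_params()
  two_strands <- function(sep) {
    set.seed(46)
    make_toy_protein(list(
      list(type = "E", len = 5, R = diag(3), t = c(0, 0, 0)),
      list(type = "E", len = 5, R = diag(3), t = c(sep, 0, 0))))
  }
  expect_equal(score_sse_clash(two_strands(3.0), p), 0)  # at the 3 A threshold
  expect_gt(score_sse_clash(two_strands(2.5), p), 0)
  full <- score_sse_clash(two_strands(2.0), p)
  half <- score_sse_clash(two_strands(2.5), p)
  expect_equal(half / full, 0.5, tolerance = 0.05)       # ramp midpoint
  two_hel <- make_toy_protein(list(
    list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0)),
    list(type = "H", len = 9, R = diag(3), t = c(5, 0, 0))))
  expect_equal(score_sse_clash(two_hel, p), 0)           # 5 A >= 4 A HH minimum
  expect_gt(score_sse_clash(make_toy_protein(list(
    list(type = "H", len = 9, R = diag(3), t = c(0, 0, 0)),
    list(type = "H", len = 9, R = diag(3), t = c(3.5, 0, 0)))), p), 0)
})

test_that("loop closure penalizes spans beyond slope * n + intercept", {
  p <- default_clash_params()
  set.seed(47)
  m <- make_toy_protein(toy_topology("helix_pair"))
  expect_equal(score_loop_closure(m, p), 0)
  # drag the second helix away until the loop cannot close
  m2 <- transform_sse(m, 2, diag(3), c(40, 0, 0))
  expect_gt(score_loop_closure(m2, p), 0)
  # refit the 5th-percentile regression from synthetic loop samples
  set.seed(48)
  n <- rep(1:15, each = 300)
  d <- runif(length(n), 0, 3.1 * n + 3.5)
  fit <- fit_loop_closure(n, d)
  expect_equal(unname(fit["slope"]), 0.95 * 3.1, tolerance = 0.05)
  expect_equal(unname(fit["intercept"]), 0.95 * 3.5, tolerance = 0.6)
})

vunit_test <- function(v) v / sqrt(sum(v^2))

test_that("derive_aa_min_distance applies the 0.05 A first-bin rule", {
  set.seed(49)
  d <- c(2.31, 2.33, 3.0, 3.4, runif(60, 3.5, 9))
  models <- lapply(d, function(r)
    point_model(rbind(c(0, 0, 0), c(r, 0, 0)), seq_ids = c(1, 9), aa = "LEU"))
  mat <- derive_aa_min_distance(models)
  # first 0.05 bin with > 1 count: [2.30, 2.35)
  expect_equal(mat["LEU", "LEU"], 2.30, tolerance = 1e-9)
  expect_equal(mat["ALA", "VAL"], 3.0)   # unobserved pair keeps the fallback
  expect_true(isSymmetric(mat))
})

test_that("all twelve terms are invariant under rigid motion", {
  set.seed(50)
  tabs <- fx_tables()
  m <- make_toy_protein(toy_topology("helix_on_sheet"))
  preds <- list(JUFO = synth_predictions(m, method = "JUFO", seed = 51),
                PSIPRED = synth_predictions(m, seed = 52))
  s0 <- score_model(m, tabs, predictions = preds)
  for (i in 1:3) {
    m2 <- global_transform(m, random_rotation(), runif(3, -25, 25))
    expect_equal(score_model(m2, tabs, predictions = preds), s0, tolerance = 1e-6)
  }
})

test_that("statistical terms respond continuously to small perturbations", {
  set.seed(53)
  tabs <- fx_tables()
  m <- make_toy_protein(toy_topology("sheet3_anti"))
  base <- score_model(m, tabs)
  stat_terms <- c("aa_distance", "aa_neighbor", "loop_length", "radius_gyration",
                  "sse_packing", "strand_pairing", "contact_order")
  for (eps in c(1e-3, 1e-4)) {
    m2 <- m
    i <- sample(nrow(m2$residues), 1)
    m2$residues$ax[i] <- m2$residues$ax[i] + eps
    delta <- abs(score_model(m2, tabs)[stat_terms] - base[stat_terms])
    expect_lt(max(delta), 200 * eps)
  }
})

test_that("penalty terms are non-negative and zero on fixture natives", {
  set.seed(54)
  for (tp in topology_names()) {
    m <- make_toy_protein(toy_topology(tp))
    expect_equal(score_aa_clash(m), 0)
    expect_equal(score_sse_clash(m), 0)
    expect_equal(score_loop_closure(m), 0)
  }
  # and >= 0 on arbitrary decoys
  m <- make_toy_protein(toy_topology("beta_sandwich"))
  for (i in 1:10) {
    d <- perturb_model(m)
    expect_gte(score_aa_clash(d), 0)
    expect_gte(score_sse_clash(d), 0)
    expect_gte(score_loop_closure(d), 0)
  }
})
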