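# Shared fixtures and independent oracles. Heavy objects are built once per
# test run and memoised here.

.fx <- new.env(parent = emptyenv())

fx_db <- function() {
  if (is.null(.fx$db)) .fx$db <- make_fixture_database(50, seed = 1)
  .fx$db
}

fx_tables <- function() {
  if (is.null(.fx$tables)) .fx$tables <- train_tables(fx_db())
  .fx$tables
}

# Minimal anchor-only model: one "strand" SSE without fragments, so the
# residue-level terms are exercised in isolation.
point_model <- function(coords, seq_ids = seq_len(nrow(coords)),
                        aa = "ALA", n_residues = NULL, sse = TRUE) {
  coords <- as.matrix(coords)
  res <- data.frame(chain = "A", seq_id = as.integer(seq_ids),
                    aa = rep(aa, length.out = nrow(coords)),
                    ax = coords[, 1], ay = coords[, 2], az = coords[, 3],
                    has_bb = FALSE,
                    nx = NA_real_, ny = NA_real_, nz = NA_real_,
                    cax = NA_real_, cay = NA_real_, caz = NA_real_,
                    cx = NA_real_, cy = NA_real_, cz = NA_real_,
                    ox = NA_real_, oy = NA_real_, oz = NA_real_)
  # one single-residue SSE per residue: every residue is an SSE residue
  # regardless of seq_id spacing
  sses <- if (sse) lapply(seq_len(nrow(res)), function(i)
    list(type = "E", rows = i)) else list()
  protein_model(res, sses, n_residues = n_residues)
}

# Hand-built fragment set for geometry unit tests: k fragments given as a
# list of (origin, axis, half length, face).
make_frag <- function(type, origin, axis, half = 4, face = NULL) {
  origin <- matrix(origin, ncol = 3, byrow = TRUE)
  axis <- matrix(axis, ncol = 3, byrow = TRUE)
  axis <- axis / sqrt(rowSums(axis^2))
  k <- nrow(origin)
  if (is.null(face) && type == "E") {
    face <- t(apply(axis, 1, function(a) {
      v <- c(-a[2], a[1], 0)
      if (sum(v^2) < 1e-8) v <- c(1, 0, 0)
      v / sqrt(sum(v^2))
    }))
  } else if (!is.null(face)) {
    face <- matrix(face, ncol = 3, byrow = TRUE)
    face <- face / sqrt(rowSums(face^2))
  }
  list(type = type, len = if (type == "H") 5L else 3L, n_frag = k,
       rise = if (type == "H") 1.5 else 3.4,
       half_full = half + 2, half_eff = half,
       origin = origin, axis = axis,
       full_start = origin - (half + 2) * axis,
       full_end = origin + (half + 2) * axis,
       eff_start = origin - half * axis,
       eff_end = origin + half * axis,
       face = face)
}

# Two-stage dense grid search oracle for the segment-segment distance.
grid_shortest <- function(a0, a1, b0, b1, n = 200) {
  best <- c(0, 0)
  span <- 1
  centre <- c(0.5, 0.5)
  for (stage in 1:3) {
    s <- pmin(1, pmax(0, seq(centre[1] - span / 2, centre[1] + span / 2,
                             length.out = n)))
    tt <- pmin(1, pmax(0, seq(centre[2] - span / 2, centre[2] + span / 2,
                              length.out = n)))
    pa <- outer(s, rep(1, n))
    d2 <- matrix(0, n, n)
    A <- lapply(1:3, function(i) a0[i] + s * (a1[i] - a0[i]))
    B <- lapply(1:3, function(i) b0[i] + tt * (b1[i] - b0[i]))
    for (i in 1:3) d2 <- d2 + outer(A[[i]], B[[i]], "-")^2
    ix <- arrayInd(which.min(d2), dim(d2))
    centre <- c(s[ix[1]], tt[ix[2]])
    best <- sqrt(min(d2))
    span <- span * 3 / n
  }
  best
}

# Rigid transform of a whole model about the origin.
global_transform <- function(model, R, t) {
  for (k in seq_along(model$sses)) {
    model <- transform_sse(model, k, R, t, about = c(0, 0, 0))
  }
  model
}

random_rotation <- function() {
  u <- rnorm(3)
  rotation_about(u / sqrt(sum(u^2)), runif(1, 0, 360))
}

expect_rigid_invariant <- function(value_fn, model, tol = 1e-6) {
  v0 <- value_fn(model)
  R <- random_rotation()
  m2 <- global_transform(model, R, runif(3, -20, 20))
  expect_equal(value_fn(m2), v0, tolerance = tol)
}
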