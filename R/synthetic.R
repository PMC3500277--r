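# Synthetic fixture generation: ideal SSE coordinates, toy topologies,
# perturbation decoys and synthetic secondary-structure prediction files.

.AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Ideal SSE coordinates in a canonical frame
#'
#' Builds an ideal alpha-helix (phi = -60, psi = -45; rise about 1.5
#' Angstrom per residue) or beta-strand (phi = -120, psi = 135; rise about
#' 3.4 Angstrom per residue) of `n` residues, oriented with its main axis
#' along +z (N- to C-terminal) and centred at the origin. Anchors are ideal
#' C-beta positions (H-alpha2 slot at 1.09 Angstrom for glycine).
#'
#' @param type "H" or "E".
#' @param n number of residues.
#' @param sequence three-letter codes (recycled); default all "ALA".
#' @return list of n x 3 matrices `N`, `CA`, `C`, `anchor`, plus `aa`.
#' @export
ideal_sse <- function(type, n, sequence = "ALA") {
  stopifnot(type %in% c("H", "E"), n >= 1)
  aa <- rep(sequence, length.out = n)
  pad <- 4L
  bb <- build_ideal_backbone(type, n + 2L * pad)
  m <- nrow(bb$CA)
  fit <- kabsch(bb$CA[1:(m - 1), , drop = FALSE], bb$CA[2:m, , drop = FALSE])
  sc <- screw_axis(fit$R, fit$t)
  keep <- seq_len(n) + pad
  canon <- function(x) {
    x <- sweep(x, 2, sc$point)
    ax <- vcross(sc$axis, c(0, 0, 1))
    R0 <- if (vnorm(ax) < 1e-9) diag(3) else
      rotation_about(ax, acos(min(1, max(-1, sc$axis[3]))) * .DEG)
    x %*% t(R0)
  }
  N <- canon(bb$N)[keep, , drop = FALSE]
  CA <- canon(bb$CA)[keep, , drop = FALSE]
  C <- canon(bb$C)[keep, , drop = FALSE]
  zc <- mean(range(CA[, 3]))
  off <- c(mean(CA[, 1]) * 0, mean(CA[, 2]) * 0, zc)  # centre along the axis
  N <- sweep(N, 2, off); CA <- sweep(CA, 2, off); C <- sweep(C, 2, off)
  anchor <- t(vapply(seq_len(n), function(i) {
    reconstruct_cbeta(N[i, ], CA[i, ], C[i, ],
                      length = if (aa[i] == "GLY") 1.09 else NULL)
  }, numeric(3)))
  list(type = type, n = n, aa = aa, N = N, CA = CA, C = C, anchor = anchor)
}

#' Assemble a toy protein from placed ideal SSEs
#'
#' Each topology entry places one ideal SSE via `x' = R x + t`. Sequence
#' numbering starts at 1; loop lengths between consecutive SSEs are taken
#' from `loops` or, by default, chosen as the smallest length whose maximal
#' bridgeable span (loop-closure slope/intercept) covers the actual C-N
#' gap, so the native satisfies all penalty terms exactly.
#'
#' @param topo list of `list(type, len, R, t)` in sequence order.
#' @param sequence three-letter codes for all SSE residues in order;
#'   `NULL` draws a natural-composition random sequence (uses the RNG).
#' @param loops integer loop lengths (length `length(topo) - 1`) or NULL.
#' @param chain chain identifier.
#' @return a [protein_model].
#' @export
make_toy_protein <- function(topo, sequence = NULL, loops = NULL, chain = "A") {
  n_tot <- sum(vapply(topo, `[[`, numeric(1), "len"))
  if (is.null(sequence)) sequence <- random_sequence(n_tot)
  stopifnot(length(sequence) == n_tot)
  parts <- list()
  at <- 0L
  for (s in topo) {
    seq_s <- sequence[(at + 1L):(at + s$len)]
    at <- at + s$len
    g <- ideal_sse(s$type, s$len, seq_s)
    tr <- function(x) sweep(x %*% t(s$R), 2, s$t, "+")
    parts[[length(parts) + 1L]] <- list(type = s$type, aa = g$aa,
                                        N = tr(g$N), CA = tr(g$CA),
                                        C = tr(g$C), anchor = tr(g$anchor))
  }
  cp <- default_clash_params()
  seq_id <- 1L
  rows <- list(); sses <- list(); row0 <- 0L
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (k > 1) {
      dcn <- vnorm(p$N[1, ] - parts[[k - 1]]$C[nrow(parts[[k - 1]]$C), ])
      n_loop <- if (!is.null(loops)) loops[k - 1] else
        max(2L, as.integer(ceiling((dcn + 4 - cp$loop_closure_intercept) /
                                     cp$loop_closure_slope)))
      seq_id <- seq_id + n_loop
    }
    idx <- seq_len(p$n <- nrow(p$CA))
    rows[[k]] <- data.frame(chain = chain, seq_id = seq_id + idx - 1L,
                            aa = p$aa, ax = p$anchor[, 1], ay = p$anchor[, 2],
                            az = p$anchor[, 3], has_bb = TRUE,
                            nx = p$N[, 1], ny = p$N[, 2], nz = p$N[, 3],
                            cax = p$CA[, 1], cay = p$CA[, 2], caz = p$CA[, 3],
                            cx = p$C[, 1], cy = p$C[, 2], cz = p$C[, 3],
                            ox = NA_real_, oy = NA_real_, oz = NA_real_)
    sses[[k]] <- list(type = p$type, rows = row0 + idx)
    row0 <- row0 + length(idx)
    seq_id <- seq_id + length(idx)
  }
  protein_model(do.call(rbind, rows), sses, n_residues = seq_id - 1L)
}

#' Built-in toy topologies
#'
#' Placement recipes emulating common folds at native-like packing
#' geometry: helix pairs/bundles at about 10.5 Angstrom axis distance with
#' moderate crossing angles, antiparallel sheets at 4.75 Angstrom strand
#' spacing with a 15-degree inter-strand twist, a helix packed on a sheet
#' face and a two-sheet sandwich.
#'
#' @param name one of `topology_names()`.
#' @param len_jitter integer; SSE lengths vary by up to this many residues
#'   (uses the RNG when > 0).
#' @return a topology list for [make_toy_protein].
#' @export
toy_topology <- function(name, len_jitter = 0L) {
  jl <- function(len) {
    if (len_jitter > 0) len + sample(-len_jitter:len_jitter, 1) else len
  }
  place <- function(type, len, R = diag(3), t = c(0, 0, 0))
    list(type = type, len = jl(len), R = R, t = t)
  rx <- function(a) rotation_about(c(1, 0, 0), a)
  ry <- function(a) rotation_about(c(0, 1, 0), a)
  # SSE lengths differ within each topology so that swapping two SSEs is
  # never a geometric no-op
  switch(name,
    helix_pair = list(
      place("H", 17),
      place("H", 14, rx(180) %*% rx(-22), c(10.5, 0, 0))
    ),
    helix_bundle3 = list(
      place("H", 16, rx(8)),
      place("H", 12, rx(180) %*% rx(-14), c(10.5, 0, 0)),
      place("H", 14, rx(10) %*% ry(12), c(5.25, 10.4, 0))
    ),
    sheet3_anti = list(
      place("E", 8),
      place("E", 7, rx(180) %*% rx(-15), c(4.75, 0, 0)),
      place("E", 6, rx(-30), c(9.5, 0, 0))
    ),
    helix_on_sheet = list(
      place("E", 7),
      place("E", 8, rx(180) %*% rx(-15), c(4.75, 0, 0)),
      place("E", 6, rx(-30), c(9.5, 0, 0)),
      place("H", 14, rx(180) %*% ry(-20) %*% rx(-15), c(4.75, 11.5, 0))
    ),
    beta_sandwich = {
      G <- ry(-30)   # second sheet: same local geometry, rotated rigidly
      list(
        place("E", 7),
        place("E", 6, rx(180) %*% rx(-15), c(4.75, 0, 0)),
        place("E", 8, G %*% rx(180) %*% rx(-15),
              as.numeric(G %*% c(4.75, 0, 0)) + c(0, 10, 0)),
        place("E", 6, G, c(0, 10, 0))
      )
    },
    stop("unknown topology: ", name)
  )
}

#' @rdname toy_topology
#' @export
topology_names <- function() {
  c("helix_pair", "helix_bundle3", "sheet3_anti", "helix_on_sheet",
    "beta_sandwich")
}

#' Rigidly transform one SSE of a model
#'
#' Applies `x' = R (x - about) + about + t` to the residues (anchors and
#' backbone) and precomputed fragment geometry of SSE `k`.
#'
#' @param model a [protein_model].
#' @param k SSE index.
#' @param R 3x3 rotation matrix.
#' @param t translation (Angstrom).
#' @param about rotation centre; default the SSE's CA centroid.
#' @return the transformed model (input untouched).
#' @export
transform_sse <- function(model, k, R = diag(3), t = c(0, 0, 0),
                          about = NULL) {
  s <- model$sses[[k]]
  res <- model$residues
  rot <- function(x) sweep(sweep(x, 2, about) %*% t(R), 2, about + t, "+")
  if (is.null(about)) {
    about <- colMeans(as.matrix(res[s$rows, c("cax", "cay", "caz")]))
  }
  for (cols in list(c("ax", "ay", "az"), c("nx", "ny", "nz"),
                    c("cax", "cay", "caz"), c("cx", "cy", "cz"),
                    c("ox", "oy", "oz"))) {
    m <- as.matrix(res[s$rows, cols])
    if (!anyNA(m)) res[s$rows, cols] <- rot(m)
  }
  model$residues <- res
  f <- s$frag
  if (!is.null(f)) {
    f$origin <- rot(f$origin)
    f$axis <- f$axis %*% t(R)
    if (!is.null(f$face)) f$face <- f$face %*% t(R)
    f$full_start <- f$origin - f$half_full * f$axis
    f$full_end <- f$origin + f$half_full * f$axis
    f$eff_start <- f$origin - max(f$half_eff, 1e-3) * f$axis
    f$eff_end <- f$origin + max(f$half_eff, 1e-3) * f$axis
    model$sses[[k]]$frag <- f
  }
  model
}

#' Apply one random perturbation move
#'
#' The four benchmark decoy moves: (1) rigid rotation and translation of
#' one SSE, (2) SSE flip (180-degree rotation about an axis perpendicular
#' to the SSE's main axis through its centre), (3) swapping the positions
#' of two SSEs, and (4) SSE removal. The input model is untouched (copy
#' semantics); randomness uses the current RNG stream.
#'
#' @param model a [protein_model].
#' @param move one of "rigid", "flip", "swap", "remove"; `NULL` picks
#'   uniformly among the applicable moves.
#' @param rot_max,trans_max magnitudes of the rigid move (degrees,
#'   Angstrom).
#' @return perturbed [protein_model].
#' @export
perturb_model <- function(model, move = NULL, rot_max = 60, trans_max = 8) {
  ns <- length(model$sses)
  stopifnot(ns >= 1)
  moves <- c("rigid", "flip", if (ns >= 2) c("swap", "remove"))
  if (is.null(move)) move <- sample(moves, 1)
  k <- sample.int(ns, 1)
  axis_of <- function(k) {
    f <- model$sses[[k]]$frag
    if (!is.null(f)) vunit(colMeans(f$axis)) else c(0, 0, 1)
  }
  if (move == "rigid") {
    u <- vunit(stats::rnorm(3))
    R <- rotation_about(u, stats::runif(1, 0, rot_max))
    t <- vunit(stats::rnorm(3)) * stats::runif(1, 0, trans_max)
    transform_sse(model, k, R, t)
  } else if (move == "flip") {
    perp <- .any_perp(axis_of(k))
    ang <- stats::runif(1, 0, 360)  # random perpendicular direction
    perp <- as.numeric(rotation_about(axis_of(k), ang) %*% perp)
    transform_sse(model, k, rotation_about(perp, 180))
  } else if (move == "swap") {
    kk <- sample(setdiff(seq_len(ns), k), 1)
    res <- model$residues
    ca <- function(k) colMeans(as.matrix(
      res[model$sses[[k]]$rows, c("cax", "cay", "caz")]))
    c1 <- ca(k); c2 <- ca(kk)
    model <- transform_sse(model, k, diag(3), c2 - c1)
    transform_sse(model, kk, diag(3), c1 - c2)
  } else if (move == "remove") {
    keep <- setdiff(seq_len(ns), k)
    drop_rows <- model$sses[[k]]$rows
    res <- model$residues[-drop_rows, , drop = FALSE]
    rownames(res) <- NULL
    shift <- function(rows) rows - vapply(rows, function(r)
      sum(drop_rows < r), numeric(1))
    sses <- lapply(model$sses[keep], function(s)
      list(type = s$type, rows = as.integer(shift(s$rows))))
    m2 <- protein_model(res, sses, n_residues = model$n_residues,
                        chains = model$chains)
    # keep the already-computed fragments (identical geometry)
    for (i in seq_along(keep)) m2$sses[[i]]$frag <- model$sses[[keep[i]]]$frag
    m2
  } else stop("unknown move: ", move)
}

#' Generate a fixture training database
#'
#' Deterministic (under seed) collection of toy proteins cycling through
#' the built-in topologies with small placement jitter (rotations up to 5
#' degrees, translations up to 0.4 Angstrom per SSE), length variation of
#' +/- 1 residue and natural-composition random sequences. All natives
#' satisfy the penalty terms exactly.
#'
#' @param n_proteins number of models.
#' @param seed RNG seed.
#' @return list of [protein_model].
#' @export
make_fixture_database <- function(n_proteins = 50, seed = 1) {
  fams <- topology_names()
  with_seed(seed, {
    lapply(seq_len(n_proteins), function(i) {
      topo <- toy_topology(fams[(i - 1) %% length(fams) + 1], len_jitter = 1L)
      topo <- lapply(topo, function(s) {
        jR <- rotation_about(vunit(stats::rnorm(3)), stats::runif(1, 0, 5))
        s$R <- jR %*% s$R
        s$t <- s$t + vunit(stats::rnorm(3)) * stats::runif(1, 0, 0.4)
        s
      })
      make_toy_protein(topo)
    })
  })
}

#' Synthetic secondary-structure prediction
#'
#' Draws per-residue 3-state probabilities such that, for a fraction
#' `accuracy` of residues, the assigned state's probability follows the
#' method's clipped normal `N(mu_ss, sigma_ss)`; for the remainder a wrong
#' state receives the high probability. The remaining probability mass is
#' split randomly over the other states.
#'
#' @param model a [protein_model].
#' @param accuracy fraction of correctly predicted residues.
#' @param method "JUFO" or "PSIPRED".
#' @param params see [default_ss_params()].
#' @param seed optional RNG seed.
#' @return data.frame `seq_id`, `aa`, `state`, `pC`, `pH`, `pE` covering
#'   the full sequence (loop residues are coil).
#' @export
synth_predictions <- function(model, accuracy = 0.8, method = "PSIPRED",
                              params = default_ss_params(), seed = NULL) {
  pm <- params[[method]]
  res <- model$residues
  n <- model$n_residues
  state <- rep("C", n)
  aa1 <- rep("X", n)
  for (s in model$sses) state[res$seq_id[s$rows]] <- s$type
  aa1[res$seq_id] <- unname(.AA_321[res$aa])
  states <- c("C", "H", "E")
  with_seed(seed, {
    p <- matrix(0, n, 3, dimnames = list(NULL, states))
    for (i in seq_len(n)) {
      truth <- state[i]
      hit <- stats::runif(1) < accuracy
      lead <- if (hit) truth else sample(setdiff(states, truth), 1)
      mu <- pm[[lead]]["mu"]; sg <- pm[[lead]]["sigma"]
      ph <- min(0.99, max(0.05, stats::rnorm(1, mu, sg)))
      rest <- stats::runif(2)
      rest <- rest / sum(rest) * (1 - ph)
      p[i, lead] <- ph
      p[i, setdiff(states, lead)] <- rest
    }
    data.frame(seq_id = seq_len(n), aa = aa1, state = state,
               pC = p[, "C"], pH = p[, "H"], pE = p[, "E"])
  })
}

#' Read / write PSIPRED-style .ss2 prediction files
#'
#' Tabular format: residue index, one-letter amino acid, predicted state
#' (C/H/E), and the coil, helix and strand probabilities.
#'
#' @param prediction data.frame as returned by [synth_predictions].
#' @param path file path.
#' @return `read_ss2` returns the prediction data.frame.
#' @export
write_ss2 <- function(prediction, path) {
  lines <- c("# PSF format secondary structure prediction", "")
  pred_state <- c("C", "H", "E")[max.col(prediction[, c("pC", "pH", "pE")])]
  lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                            prediction$seq_id, prediction$aa, pred_state,
                            prediction$pC, prediction$pH, prediction$pE))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ss2
#' @export
read_ss2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^\\s*\\d", lines)]
  if (!length(lines)) stop("no prediction rows in ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(
    seq_id = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    aa = vapply(parts, `[`, "", 2),
    state = vapply(parts, `[`, "", 3),
    pC = vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    pH = vapply(parts, function(p) as.numeric(p[5]), numeric(1)),
    pE = vapply(parts, function(p) as.numeric(p[6]), numeric(1))
  )
}

#' Coordinate RMSD between a model and its native
#'
#' Plain (unsuperposed) CA RMSD over residues shared by chain and seq_id --
#' decoys generated by [perturb_model] stay in the native frame.
#'
#' @param model,native [protein_model]s.
#' @return RMSD in Angstrom.
#' @export
model_rmsd <- function(model, native) {
  a <- model$residues; b <- native$residues
  key <- function(r) paste(r$chain, r$seq_id)
  i <- match(key(a), key(b))
  ok <- !is.na(i)
  if (!any(ok)) return(Inf)
  d2 <- (a$cax[ok] - b$cax[i[ok]])^2 + (a$cay[ok] - b$cay[i[ok]])^2 +
    (a$caz[ok] - b$caz[i[ok]])^2
  sqrt(mean(d2))
}

#' Generate a labelled decoy set for one native
#'
#' `n_near` gentle decoys (one rigid move, rotation <= 8 degrees,
#' translation <= 1 Angstrom) and `n_far` heavy decoys (2-4 random moves at
#' full magnitude). A decoy is labelled native-like when its RMSD100
#' against the native is below `cutoff` Angstrom and it retains at least
#' `coverage` of the native's residues (so that SSE-removal decoys, whose
#' RMSD over the surviving residues can be arbitrarily small, do not count
#' as native-like).
#'
#' @param native a [protein_model].
#' @param n_near,n_far decoy counts.
#' @param cutoff RMSD100 labelling cutoff in Angstrom.
#' @param coverage minimal retained fraction of native residues.
#' @param seed RNG seed.
#' @return list with `models` and logical `labels`.
#' @export
make_decoy_set <- function(native, n_near = 100, n_far = 900, cutoff = 8,
                           coverage = 0.9, seed = NULL) {
  with_seed(seed, {
    near <- lapply(seq_len(n_near), function(i)
      perturb_model(native, move = "rigid", rot_max = 8, trans_max = 1))
    far <- lapply(seq_len(n_far), function(i) {
      m <- native
      for (j in seq_len(sample(2:4, 1))) m <- perturb_model(m)
      m
    })
    models <- c(near, far)
    labels <- vapply(models, function(m) {
      cov <- nrow(m$residues) / nrow(native$residues)
      cov >= coverage &&
        rmsd100(model_rmsd(m, native), native$n_residues) < cutoff
    }, logical(1))
    list(models = models, labels = labels)
  })
}

#' Fixture-trained energy tables
#'
#' Convenience wrapper: builds the fixture database and trains the full
#' table set from it.
#'
#' @param seed fixture database seed.
#' @param n_proteins database size.
#' @return an `energy_table_set`.
#' @export
fixture_tables <- function(seed = 1, n_proteins = 50) {
  train_tables(make_fixture_database(n_proteins, seed = seed))
}
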