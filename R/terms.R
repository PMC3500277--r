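# The twelve scoring terms: eight statistical potentials, three penalty
# terms and the secondary-structure-prediction agreement score.

#' Smoothed neighbour count
#'
#' Burial measure of a residue: the sum over all other modelled residues
#' with sequence separation of at least three (or on another chain) of a
#' half-cosine step-down weight of the anchor-anchor distance, 1 at or
#' below 4.0 Angstrom and 0 at or beyond 11.4 Angstrom.
#'
#' @param model a [protein_model].
#' @param rows residue row indices to evaluate (default: all).
#' @param lo,hi transition thresholds in Angstrom.
#' @return numeric vector of neighbour counts.
#' @export
neighbor_count <- function(model, rows = seq_len(nrow(model$residues)),
                           lo = 4.0, hi = 11.4) {
  res <- model$residues
  a <- anchors(model)
  out <- numeric(length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    d <- sqrt(colSums((t(a) - a[i, ])^2))
    elig <- (res$chain != res$chain[i]) | (abs(res$seq_id - res$seq_id[i]) >= 3)
    out[k] <- sum(transition_down(d[elig], lo, hi))
  }
  out
}

#' Amino acid environment score
#'
#' Sum over SSE residues of the type-specific environment energy evaluated
#' at the residue's smoothed neighbour count.
#'
#' @param model a [protein_model].
#' @param tables an `energy_table_set` (or its `environment` element).
#' @return energy in BCLEU.
#' @export
score_environment <- function(model, tables) {
  env <- tables$environment %||% tables
  f <- env_features(model)
  if (!nrow(f)) return(0)
  s <- 0
  for (aa in unique(f$aa)) {
    s <- s + sum(evaluate_table(env[[aa]], f$nc[f$aa == aa]))
  }
  s
}

#' Amino acid pair distance score
#'
#' Sum over unordered SSE-residue pairs with sequence separation of at
#' least 12 and anchor distance below 20 Angstrom of the type-pair energy.
#'
#' @inheritParams score_environment
#' @export
score_aa_pair <- function(model, tables) {
  pt <- tables$aa_pair %||% tables
  f <- pair_features(model)
  if (!nrow(f)) return(0)
  s <- 0
  for (key in unique(f$key)) {
    s <- s + sum(evaluate_table(pt[[key]], f$d[f$key == key]))
  }
  s
}

#' Loop length score
#'
#' For each pair of consecutive SSEs, evaluates the 2D loop table at (loop
#' residue count, Euclidean distance between the facing main-axis tips).
#'
#' @inheritParams score_environment
#' @export
score_loop_length <- function(model, tables) {
  tab <- if (inherits(tables, "energy_table")) tables else tables$loop_length
  f <- loop_features(model)
  if (!nrow(f)) return(0)
  sum(evaluate_table(tab, f$n, f$d))
}

#' Strand pairing and SSE packing scores
#'
#' Accumulates the interaction-weighted packing energies over the best
#' fragment pair lists of all SSE pairs. Strand-strand entries are
#' apportioned between the backbone-pairing table and the sheet-sandwich
#' table by their offset-derived weights; helix-helix, helix-strand and
#' sandwich contributions make up the SSE packing score, the planar
#' strand-strand contributions the strand pairing score.
#'
#' @inheritParams score_environment
#' @param pt optional precomputed [packing_table] of the model.
#' @return named numeric: `strand_pairing`, `sse_packing` (BCLEU).
#' @export
score_sse_contacts <- function(model, tables, pt = NULL) {
  if (is.null(pt)) pt <- packing_table(model)
  out <- c(strand_pairing = 0, sse_packing = 0)
  if (!nrow(pt)) return(out)
  hh <- pt[pt$type_pair == "HH", , drop = FALSE]
  hs <- pt[pt$type_pair == "HS", , drop = FALSE]
  ss <- pt[pt$type_pair == "SS", , drop = FALSE]
  if (nrow(hh))
    out["sse_packing"] <- out["sse_packing"] +
      sum(hh$w_i * evaluate_table(tables$packing_hh, hh$distance, hh$theta))
  if (nrow(hs))
    out["sse_packing"] <- out["sse_packing"] +
      sum(hs$w_i * evaluate_table(tables$packing_hs, hs$distance, hs$theta))
  if (nrow(ss)) {
    out["strand_pairing"] <- sum(
      ss$w_pair * evaluate_table(tables$strand_pairing, ss$distance, ss$theta))
    out["sse_packing"] <- out["sse_packing"] +
      sum(ss$w_sand * evaluate_table(tables$sheet_sandwich, ss$distance, ss$theta))
  }
  out
}

#' Normalized contact order
#'
#' Mean sequence separation of anchor pairs within 8 Angstrom, squared and
#' divided by the total sequence length; 0 when no contacts exist.
#'
#' @param model a [protein_model].
#' @param cutoff contact distance in Angstrom.
#' @export
contact_order_norm <- function(model, cutoff = 8) {
  res <- model$residues
  if (nrow(res) < 2) return(0)
  dm <- as.matrix(stats::dist(res[, c("ax", "ay", "az")]))
  sep <- abs(outer(res$seq_id, res$seq_id, "-"))
  sel <- upper.tri(dm) & dm <= cutoff & outer(res$chain, res$chain, "==")
  if (!any(sel)) return(0)
  co <- mean(sep[sel])
  co^2 / model$n_residues
}

#' Normalized squared radius of gyration
#'
#' Mean squared anchor distance to the anchor centroid, divided by the
#' total sequence length.
#'
#' @param model a [protein_model].
#' @export
radius_of_gyration_norm <- function(model) {
  a <- anchors(model)
  if (nrow(a) < 1) return(0)
  cen <- colMeans(a)
  r2 <- mean(rowSums(sweep(a, 2, cen)^2))
  r2 / model$n_residues
}

#' Contact order score
#' @inheritParams score_environment
#' @export
score_contact_order <- function(model, tables) {
  tab <- if (inherits(tables, "energy_table")) tables else tables$contact_order
  evaluate_table(tab, contact_order_norm(model))
}

#' Radius of gyration score
#' @inheritParams score_environment
#' @export
score_radius_gyration <- function(model, tables) {
  tab <- if (inherits(tables, "energy_table")) tables else tables$radius_gyration
  evaluate_table(tab, radius_of_gyration_norm(model))
}

#' Secondary structure prediction agreement parameters
#'
#' Mean and standard deviation of the predicted probability of correctly
#' predicted residues, per method and per state.
#'
#' @return nested list `params[[method]][[state]] = c(mu, sigma)`.
#' @export
default_ss_params <- function() {
  list(
    JUFO = list(H = c(mu = 0.67, sigma = 0.21),
                E = c(mu = 0.58, sigma = 0.24),
                C = c(mu = 0.59, sigma = 0.18)),
    PSIPRED = list(H = c(mu = 0.76, sigma = 0.20),
                   E = c(mu = 0.71, sigma = 0.27),
                   C = c(mu = 0.73, sigma = 0.21))
  )
}

#' Secondary structure prediction agreement score
#'
#' Per SSE residue, the standard score `z = (p_assigned - mu) / sigma` of
#' the predicted probability of the residue's assigned state is mapped
#' through minus the error function of `z / sqrt(2)` and summed: negative
#' when prediction and model agree, positive when they disagree.
#'
#' @param model a [protein_model].
#' @param prediction data.frame with columns `seq_id`, `pH`, `pE`, `pC`
#'   (see [read_ss2]).
#' @param method "JUFO" or "PSIPRED" (selects mu/sigma).
#' @param params see [default_ss_params()].
#' @return energy in BCLEU.
#' @export
score_ss_agreement <- function(model, prediction, method = "PSIPRED",
                               params = default_ss_params()) {
  pm <- params[[method]]
  if (is.null(pm)) stop("no agreement parameters for method ", method)
  res <- model$residues
  s <- 0
  for (sse in model$sses) {
    st <- sse$type
    sq <- res$seq_id[sse$rows]
    idx <- match(sq, prediction$seq_id)
    if (anyNA(idx)) stop("missing prediction for residue(s) ",
                         paste(sq[is.na(idx)], collapse = ", "))
    p <- prediction[[paste0("p", st)]][idx]
    z <- (p - pm[[st]]["mu"]) / pm[[st]]["sigma"]
    s <- s + sum(-(2 * stats::pnorm(z) - 1))   # -erf(z / sqrt(2))
  }
  s
}

#' Clash and loop-closure parameters
#'
#' `aa_min_distance`: symmetric 20x20 matrix of shortest allowed
#' anchor-anchor distances (default uniform 3.0 Angstrom; see
#' [derive_aa_min_distance] to train one). `sse_min_distance`: minimal
#' fragment-fragment distances (helix-helix 4, helix-strand 4,
#' strand-strand 3 Angstrom). `ramp_width`: 1 Angstrom to full penalty.
#' `loop_closure_slope`/`intercept`: maximal bridgeable C-N distance per
#' loop residue (Angstrom per residue, Angstrom).
#'
#' @return list of class `clash_params`.
#' @export
default_clash_params <- function() {
  m <- matrix(3.0, 20, 20, dimnames = list(AA_TYPES, AA_TYPES))
  structure(list(aa_min_distance = m,
                 sse_min_distance = c(HH = 4, HS = 4, SS = 3),
                 ramp_width = 1,
                 loop_closure_slope = 2.8,
                 loop_closure_intercept = 4.0,
                 loop_closure_exponent = 2),
            class = "clash_params")
}

# 0 at d >= dmin, linear to 1 at dmin - width, capped at 1
.clash_ramp <- function(d, dmin, width = 1) {
  pmin(1, pmax(0, (dmin - d) / width))
}

#' Amino acid pair clash penalty
#'
#' For every residue pair with sequence separation of at least three, a
#' penalty ramping linearly from 0 at the allowed type-pair distance to a
#' maximum of 1 at 1 Angstrom below it.
#'
#' @param model a [protein_model].
#' @param params a `clash_params` list.
#' @return penalty `>= 0`.
#' @export
score_aa_clash <- function(model, params = default_clash_params()) {
  res <- model$residues
  if (nrow(res) < 2) return(0)
  dm <- as.matrix(stats::dist(res[, c("ax", "ay", "az")]))
  sep <- abs(outer(res$seq_id, res$seq_id, "-"))
  elig <- upper.tri(dm) & (sep >= 3 | !outer(res$chain, res$chain, "=="))
  idx <- which(elig, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  dmin <- params$aa_min_distance[cbind(res$aa[idx[, 1]], res$aa[idx[, 2]])]
  sum(.clash_ramp(dm[elig], dmin, params$ramp_width))
}

#' SSE clash penalty
#'
#' Interaction-weighted ramp penalty over the best fragment pairs of every
#' SSE pair whose shortest connection falls below the type-pair minimum
#' distance (full penalty 1 Angstrom below it).
#'
#' @inheritParams score_aa_clash
#' @param pt optional precomputed [packing_table] of the model.
#' @export
score_sse_clash <- function(model, params = default_clash_params(), pt = NULL) {
  if (is.null(pt)) pt <- packing_table(model)
  if (!nrow(pt)) return(0)
  dmin <- params$sse_min_distance[pt$type_pair]
  sum(pt$w_i * .clash_ramp(pt$distance, dmin, params$ramp_width))
}

#' Loop closure penalty
#'
#' For each pair of consecutive SSEs, the Euclidean distance between the
#' terminal backbone C atom and the next SSE's starting N atom must not
#' exceed `slope * n_loop + intercept`; the excess enters a quadratic
#' penalty. Models without backbone atoms fall back to anchor positions
#' (flagged via a warning).
#'
#' @inheritParams score_aa_clash
#' @export
score_loop_closure <- function(model, params = default_clash_params()) {
  ns <- length(model$sses)
  if (ns < 2) return(0)
  res <- model$residues
  pen <- 0
  warned <- FALSE
  for (k in seq_len(ns - 1)) {
    ra <- model$sses[[k]]$rows
    rb <- model$sses[[k + 1]]$rows
    i <- ra[length(ra)]; j <- rb[1]
    if (res$chain[i] != res$chain[j]) next
    n_loop <- max(0L, res$seq_id[j] - res$seq_id[i] - 1L)
    if (res$has_bb[i] && res$has_bb[j]) {
      p1 <- c(res$cx[i], res$cy[i], res$cz[i])
      p2 <- c(res$nx[j], res$ny[j], res$nz[j])
    } else {
      if (!warned) { warning("backbone missing; loop closure uses anchors"); warned <- TRUE }
      p1 <- c(res$ax[i], res$ay[i], res$az[i])
      p2 <- c(res$ax[j], res$ay[j], res$az[j])
    }
    dmax <- params$loop_closure_slope * n_loop + params$loop_closure_intercept
    excess <- max(0, vnorm(p2 - p1) - dmax)
    pen <- pen + excess^params$loop_closure_exponent
  }
  pen
}

#' Train the minimal allowed amino acid pair distances
#'
#' Collects all anchor pair distances (sequence separation >= 3) per type
#' pair in 0.05 Angstrom bins; the lower edge of the first bin with more
#' than one count, scanning upward, becomes the minimum permitted
#' distance. Pairs never observed keep the fallback.
#'
#' @param models list of [protein_model].
#' @param fallback distance used for unobserved type pairs (Angstrom).
#' @return symmetric 20x20 matrix.
#' @export
derive_aa_min_distance <- function(models, fallback = 3.0) {
  acc <- new.env(parent = emptyenv())
  for (m in models) {
    res <- m$residues
    if (nrow(res) < 2) next
    dm <- as.matrix(stats::dist(res[, c("ax", "ay", "az")]))
    sep <- abs(outer(res$seq_id, res$seq_id, "-"))
    elig <- upper.tri(dm) & sep >= 3
    idx <- which(elig, arr.ind = TRUE)
    key <- aa_pair_key(res$aa[idx[, 1]], res$aa[idx[, 2]])
    d <- dm[elig]
    for (k in unique(key)) {
      acc[[k]] <- c(acc[[k]], d[key == k])
    }
  }
  out <- matrix(fallback, 20, 20, dimnames = list(AA_TYPES, AA_TYPES))
  breaks <- seq(0, 25, by = 0.05)
  for (k in ls(acc)) {
    h <- feature_histogram(acc[[k]], breaks)$counts
    i <- which(h > 1)[1]
    if (!is.na(i)) {
      ab <- strsplit(k, ":", fixed = TRUE)[[1]]
      out[ab[1], ab[2]] <- out[ab[2], ab[1]] <- breaks[i]
    }
  }
  out
}

#' Fit the loop closure regression
#'
#' Reproduces the calibration of the maximal bridgeable loop span: per loop
#' length, the 95th percentile of observed C-to-N distances (the 5th
#' percentile of the longest) is computed and a linear regression over loop
#' lengths gives slope and intercept.
#'
#' @param n integer loop lengths (residues).
#' @param d Euclidean C-N distances (Angstrom).
#' @return named numeric `c(slope, intercept)`.
#' @export
fit_loop_closure <- function(n, d) {
  q <- tapply(d, n, stats::quantile, probs = 0.95, names = FALSE)
  nn <- as.numeric(names(q))
  fit <- stats::lm(as.numeric(q) ~ nn)
  c(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]))
}

#' All twelve term scores of one model
#'
#' @param model a [protein_model].
#' @param tables an `energy_table_set` from [train_tables].
#' @param predictions named list of prediction data.frames (names "JUFO",
#'   "PSIPRED"); missing methods score 0.
#' @param clash_params see [default_clash_params()].
#' @param ss_params see [default_ss_params()].
#' @return named numeric vector of the 12 term scores in BCLEU.
#' @export
score_model <- function(model, tables, predictions = NULL,
                        clash_params = default_clash_params(),
                        ss_params = default_ss_params()) {
  pt <- packing_table(model)
  contacts <- score_sse_contacts(model, tables, pt = pt)
  ss_term <- function(method) {
    pred <- predictions[[method]]
    if (is.null(pred)) 0 else
      score_ss_agreement(model, pred, method, ss_params)
  }
  c(aa_distance = score_aa_pair(model, tables),
    aa_neighbor = score_environment(model, tables),
    loop_length = score_loop_length(model, tables),
    radius_gyration = score_radius_gyration(model, tables),
    loop_closure = score_loop_closure(model, clash_params),
    aa_clash = score_aa_clash(model, clash_params),
    sse_clash = score_sse_clash(model, clash_params, pt = pt),
    sse_packing = unname(contacts["sse_packing"]),
    strand_pairing = unname(contacts["strand_pairing"]),
    contact_order = score_contact_order(model, tables),
    sspred_jufo = ss_term("JUFO"),
    sspred_psipred = ss_term("PSIPRED"))
}
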