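# Histogram -> energy conversion via the inverse Boltzmann relation, table
# evaluation with interpolation, and per-term statistics collection.

REPULSIVE_ENERGY <- 18  # BCLEU assigned to under-populated bins

#' Weighted 1D/2D histogram
#'
#' @param x,y coordinates (y = NULL for 1D); values outside the breaks are
#'   dropped.
#' @param breaks_x,breaks_y strictly increasing bin edges.
#' @param w optional non-negative weights used as counts.
#' @return object of class `feature_histogram` with `counts` (vector or
#'   matrix) and the break vectors.
#' @export
feature_histogram <- function(x, breaks_x, y = NULL, breaks_y = NULL, w = NULL) {
  stopifnot(all(diff(breaks_x) > 0))
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(all(w >= 0), length(w) == length(x))
  ix <- findInterval(x, breaks_x, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= length(breaks_x) - 1
  if (is.null(y)) {
    counts <- numeric(length(breaks_x) - 1)
    t <- tapply(w[ok], ix[ok], sum)
    counts[as.integer(names(t))] <- t
  } else {
    stopifnot(all(diff(breaks_y) > 0), length(y) == length(x))
    iy <- findInterval(y, breaks_y, rightmost.closed = TRUE)
    ok <- ok & iy >= 1 & iy <= length(breaks_y) - 1
    counts <- matrix(0, length(breaks_x) - 1, length(breaks_y) - 1)
    if (any(ok)) {
      t <- tapply(w[ok], list(ix[ok], iy[ok]), sum)
      counts[cbind(as.integer(rownames(t))[row(t)[!is.na(t)]],
                   as.integer(colnames(t))[col(t)[!is.na(t)]])] <- t[!is.na(t)]
    }
  }
  structure(list(counts = counts, breaks_x = breaks_x, breaks_y = breaks_y),
            class = "feature_histogram")
}

#' Convert counts to energies via the inverse Boltzmann relation
#'
#' `E = -ln(p / p_bg)` in BCLEU (`RT = 1`), where `p` is the normalized
#' count distribution and `p_bg` a background distribution of the same
#' shape. Bins whose raw count falls below `min_count` receive the constant
#' repulsive energy of 18 BCLEU.
#'
#' @param hist a [feature_histogram].
#' @param background probability table of the same shape summing to 1; the
#'   default is uniform over the support.
#' @param min_count raw-count threshold below which a bin becomes
#'   repulsive (2 reproduces the "empty or one raw count" rule, 5 the pair
#'   distance rule; any positive value keeps empty bins repulsive).
#' @param pseudo_count added to every bin before normalization (0 = none).
#' @param repulsive_value energy assigned where the count rule fires: 18
#'   BCLEU for the 1D terms; the 2D packing tables use 0 (neutral) instead,
#'   leaving forbidden geometry to the separate clash penalty terms.
#' @param circular_y treat the second axis as periodic when evaluating.
#' @param oob_x,oob_y length-2 character vectors (low, high) choosing the
#'   out-of-range policy per side: "clamp" holds the edge value, "zero"
#'   ramps the energy linearly to 0 at the outermost break and returns 0
#'   beyond it.
#' @return object of class `energy_table`.
#' @export
energy_from_counts <- function(hist, background = NULL, min_count = 1e-9,
                               pseudo_count = 0,
                               repulsive_value = REPULSIVE_ENERGY,
                               oob_x = c("clamp", "clamp"),
                               oob_y = c("clamp", "clamp"),
                               circular_y = FALSE) {
  counts <- hist$counts + pseudo_count
  tot <- sum(counts)
  if (is.null(background)) {
    background <- array(1 / length(counts), dim = dim(counts) %||% length(counts))
  }
  if (!identical(length(background), length(counts)))
    stop("background shape does not match histogram")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  if (any(background <= 0 & counts > 0)) stop("background zero where counts nonzero")
  energy <- counts
  if (tot <= 0) {
    warning("all-zero histogram; returning an all-repulsive table")
    energy[] <- repulsive_value
  } else {
    p <- counts / tot
    e <- -log(p / background)
    e[background <= 0] <- repulsive_value
    energy[] <- e
  }
  energy[hist$counts < min_count] <- repulsive_value
  structure(list(energy = energy, breaks_x = hist$breaks_x,
                 breaks_y = hist$breaks_y, oob_x = oob_x, oob_y = oob_y,
                 circular_y = circular_y, repulsive = REPULSIVE_ENERGY),
            class = "energy_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bin_centers <- function(breaks) (breaks[-1] + breaks[-length(breaks)]) / 2

# 1D interpolation nodes along one axis given a vector of node values.
# Returns list(i1, i2, t): indices into an augmented value lookup where
# index 0 means "virtual zero node"; handled by the caller.
.interp_axis <- function(x, breaks, oob, circular = FALSE) {
  cen <- .bin_centers(breaks)
  nb <- length(cen)
  if (circular) {
    period <- breaks[length(breaks)] - breaks[1]
    # wrap x into [first center, first center + period)
    xx <- ((x - cen[1]) %% period) + cen[1]
    pos <- (xx - cen[1]) / (period / nb)
    i1 <- floor(pos) + 1
    t <- pos - (i1 - 1)
    i2 <- ifelse(i1 >= nb, 1, i1 + 1)
    return(list(i1 = i1, i2 = i2, t = t, zero1 = rep(FALSE, length(x)),
                zero2 = rep(FALSE, length(x)), outside = rep(FALSE, length(x))))
  }
  n <- length(x)
  i1 <- i2 <- integer(n); t <- numeric(n)
  zero1 <- zero2 <- outside <- rep(FALSE, n)
  if (nb == 1L) {
    return(list(i1 = rep(1L, n), i2 = rep(1L, n), t = numeric(n),
                zero1 = rep(FALSE, n), zero2 = rep(FALSE, n),
                outside = rep(FALSE, n)))
  }
  lo <- x < cen[1]; hi <- x > cen[nb]; mid <- !lo & !hi
  if (any(mid)) {
    idx <- findInterval(x[mid], cen)
    idx[idx >= nb] <- nb - 1
    idx[idx < 1] <- 1
    i1[mid] <- idx; i2[mid] <- idx + 1
    t[mid] <- (x[mid] - cen[idx]) / (cen[idx + 1] - cen[idx])
  }
  if (any(lo)) {
    if (oob[1] == "zero") {
      edge <- breaks[1]
      below <- lo & x <= edge
      ramp <- lo & !below
      outside[below] <- TRUE
      i1[ramp] <- 1; i2[ramp] <- 1
      zero1[ramp] <- TRUE
      t[ramp] <- (x[ramp] - edge) / (cen[1] - edge)
    } else {
      i1[lo] <- 1; i2[lo] <- 1; t[lo] <- 0
    }
  }
  if (any(hi)) {
    if (oob[2] == "zero") {
      edge <- breaks[length(breaks)]
      beyond <- hi & x >= edge
      ramp <- hi & !beyond
      outside[beyond] <- TRUE
      i1[ramp] <- nb; i2[ramp] <- nb
      zero2[ramp] <- TRUE
      t[ramp] <- (x[ramp] - cen[nb]) / (edge - cen[nb])
    } else {
      i1[hi] <- nb; i2[hi] <- nb; t[hi] <- 0
    }
  }
  list(i1 = i1, i2 = i2, t = t, zero1 = zero1, zero2 = zero2, outside = outside)
}

#' Evaluate an energy table
#'
#' Linear (1D) or bilinear (2D) interpolation between bin centers; the
#' second axis may be periodic (twist angles). Out-of-range behaviour
#' follows the table's per-side policy.
#'
#' @param table an [energy_table].
#' @param x first-axis values (vectorized).
#' @param y second-axis values for 2D tables.
#' @return energies in BCLEU.
#' @export
evaluate_table <- function(table, x, y = NULL) {
  if (anyNA(x) || (!is.null(y) && anyNA(y))) stop("NaN/NA input to evaluate_table")
  ax <- .interp_axis(x, table$breaks_x, table$oob_x)
  if (is.null(table$breaks_y)) {
    e <- table$energy
    v1 <- ifelse(ax$zero1, 0, e[pmax(ax$i1, 1)])
    v2 <- ifelse(ax$zero2, 0, e[pmax(ax$i2, 1)])
    out <- v1 * (1 - ax$t) + v2 * ax$t
    out[ax$outside] <- 0
    return(out)
  }
  stopifnot(!is.null(y))
  ay <- .interp_axis(y, table$breaks_y, table$oob_y, circular = table$circular_y)
  e <- table$energy
  val <- function(ix, zx, iy, zy) {
    v <- e[cbind(pmax(ix, 1), pmax(iy, 1))]
    v[zx | zy] <- 0
    v
  }
  v11 <- val(ax$i1, ax$zero1, ay$i1, ay$zero1)
  v12 <- val(ax$i1, ax$zero1, ay$i2, ay$zero2)
  v21 <- val(ax$i2, ax$zero2, ay$i1, ay$zero1)
  v22 <- val(ax$i2, ax$zero2, ay$i2, ay$zero2)
  tx <- ax$t; ty <- ay$t
  out <- v11 * (1 - tx) * (1 - ty) + v12 * (1 - tx) * ty +
    v21 * tx * (1 - ty) + v22 * tx * ty
  out[ax$outside | ay$outside] <- 0
  out
}

# ------------------------------------------------------ term statistics

#' Default binning and policies of the statistical terms
#'
#' Pair distances: 0-20 Angstrom in 1 Angstrom bins, repulsive below 5 raw
#' counts, energy ramped to 0 beyond 20 Angstrom. Environment: neighbour
#' count 0-20 in bins of 1, repulsive at <= 1 raw count. Packing/pairing:
#' distance 0-20 Angstrom x twist angle in 15-degree periodic bins,
#' distance-proportional background, empty bins repulsive. Loop length:
#' residue bins 0-20 x Euclidean bins of 2 Angstrom to 60, a pseudo count
#' of 0.01 per bin (small enough that unobserved long spans stay positive at
#' fixture scale) and a quadratic-in-distance background. Contact order / radius
#' of gyration: dimensionless bins of 0.05 with uniform background.
#'
#' @return named list of term configurations.
#' @export
term_config <- function() {
  list(
    environment = list(breaks = seq(0, 20, by = 1), min_count = 2),
    aa_pair = list(breaks = seq(0, 20, by = 1), min_count = 5, min_seq_sep = 12),
    loop_length = list(breaks_n = seq(-0.5, 20.5, by = 1),
                       breaks_d = seq(0, 60, by = 2), pseudo = 0.01),
    packing = list(breaks_d = seq(0, 20, by = 1),
                   breaks_t = seq(-180, 180, by = 15)),
    contact_order = list(breaks = seq(0, 2, by = 0.05)),
    radius_gyration = list(breaks = seq(0, 6, by = 0.05))
  )
}

# Feature collectors (shared between training and scoring). ------------

# per-SSE-residue (aa, neighbour count)
env_features <- function(model) {
  res <- model$residues
  in_sse <- .sse_rows(model)
  if (!length(in_sse)) return(data.frame(aa = character(), nc = numeric()))
  nc <- neighbor_count(model, in_sse)
  data.frame(aa = res$aa[in_sse], nc = nc)
}

# eligible anchor pairs (aa pair key, distance)
pair_features <- function(model, min_seq_sep = 12, max_dist = 20) {
  rows <- .sse_rows(model)
  if (length(rows) < 2)
    return(data.frame(key = character(), d = numeric()))
  res <- model$residues[rows, ]
  dm <- as.matrix(stats::dist(res[, c("ax", "ay", "az")]))
  sep <- abs(outer(res$seq_id, res$seq_id, "-"))
  same <- outer(res$chain, res$chain, "==")
  sel <- upper.tri(dm) & (sep >= min_seq_sep | !same) & dm < max_dist
  idx <- which(sel, arr.ind = TRUE)
  data.frame(key = aa_pair_key(res$aa[idx[, 1]], res$aa[idx[, 2]]),
             d = dm[sel])
}

# consecutive SSE pairs: loop residue count and axis-tip distance
loop_features <- function(model) {
  ns <- length(model$sses)
  out <- data.frame(n = integer(), d = numeric())
  if (ns < 2) return(out)
  res <- model$residues
  for (k in seq_len(ns - 1)) {
    a <- model$sses[[k]]; b <- model$sses[[k + 1]]
    ra <- a$rows[length(a$rows)]; rb <- b$rows[1]
    if (res$chain[ra] != res$chain[rb]) next
    n_loop <- res$seq_id[rb] - res$seq_id[ra] - 1L
    if (is.null(a$frag) || is.null(b$frag)) next
    tip_a <- a$frag$full_end[a$frag$n_frag, ]
    tip_b <- b$frag$full_start[1, ]
    out <- rbind(out, data.frame(n = max(0L, n_loop), d = vnorm(tip_b - tip_a)))
  }
  out
}

.sse_rows <- function(model) {
  unlist(lapply(model$sses, `[[`, "rows"), use.names = FALSE)
}

#' Build the energy table(s) of one statistical term
#'
#' Collects the term's feature counts over a training set of models and
#' converts them to energies with the term's background and pseudo-count
#' rules: environment uses the normalized sum of the per-type exposure
#' distributions as background; pair distances use the frequency of either
#' partner type with any other type at that distance; strand pairing and
#' SSE packing use a distance-proportional background and the interaction
#' weight as the count; the loop background is proportional to the squared
#' Euclidean distance; contact order and radius of gyration use uniform
#' backgrounds.
#'
#' @param models list of [protein_model].
#' @param term one of "environment", "aa_pair", "loop_length",
#'   "strand_pairing", "packing_hh", "packing_hs", "sheet_sandwich",
#'   "contact_order", "radius_gyration".
#' @param config see [term_config()].
#' @return an [energy_table], or a named list of tables for
#'   "environment" (per amino acid type) and "aa_pair" (per unordered type
#'   pair).
#' @export
build_term_statistics <- function(models, term, config = term_config()) {
  switch(term,
    environment = .stat_environment(models, config$environment),
    aa_pair = .stat_aa_pair(models, config$aa_pair),
    loop_length = .stat_loop(models, config$loop_length),
    strand_pairing = .stat_packing(models, "w_pair", "SS", config$packing),
    packing_hh = .stat_packing(models, "w_i", "HH", config$packing),
    packing_hs = .stat_packing(models, "w_i", "HS", config$packing),
    sheet_sandwich = .stat_packing(models, "w_sand", "SS", config$packing),
    contact_order = .stat_scalar(models, contact_order_norm, config$contact_order),
    radius_gyration = .stat_scalar(models, radius_of_gyration_norm,
                                   config$radius_gyration),
    stop("unknown term: ", term)
  )
}

.stat_environment <- function(models, cfg) {
  feats <- do.call(rbind, lapply(models, env_features))
  tabs <- vector("list", length(AA_TYPES))
  names(tabs) <- AA_TYPES
  hists <- lapply(AA_TYPES, function(aa)
    feature_histogram(feats$nc[feats$aa == aa], cfg$breaks))
  names(hists) <- AA_TYPES
  # background: normalized sum of the normalized per-type distributions
  norm1 <- lapply(hists, function(h) {
    s <- sum(h$counts)
    if (s > 0) h$counts / s else h$counts
  })
  bg <- Reduce(`+`, norm1)
  bg <- bg / sum(bg)
  for (aa in AA_TYPES) {
    tabs[[aa]] <- suppressWarnings(
      energy_from_counts(hists[[aa]], background = bg, min_count = cfg$min_count))
  }
  tabs
}

.stat_aa_pair <- function(models, cfg) {
  feats <- do.call(rbind, lapply(models, pair_features,
                                 min_seq_sep = cfg$min_seq_sep,
                                 max_dist = max(cfg$breaks)))
  breaks <- cfg$breaks
  nb <- length(breaks) - 1
  # per-type marginal: counts of (type, d) over all pairs, both partners
  types <- c(sub(":.*", "", feats$key), sub(".*:", "", feats$key))
  dd <- c(feats$d, feats$d)
  marg <- matrix(0, length(AA_TYPES), nb, dimnames = list(AA_TYPES, NULL))
  for (aa in AA_TYPES) {
    marg[aa, ] <- feature_histogram(dd[types == aa], breaks)$counts
  }
  tabs <- list()
  for (i in seq_along(AA_TYPES)) {
    for (j in i:length(AA_TYPES)) {
      a <- AA_TYPES[i]; b <- AA_TYPES[j]
      key <- aa_pair_key(a, b)
      h <- feature_histogram(feats$d[feats$key == key], breaks)
      bgc <- marg[a, ] + marg[b, ]
      bg <- if (sum(bgc) > 0) bgc / sum(bgc) else rep(1 / nb, nb)
      bg[bg <= 0] <- 1e-12
      bg <- bg / sum(bg)
      tabs[[key]] <- suppressWarnings(
        energy_from_counts(h, background = bg, min_count = cfg$min_count,
                           oob_x = c("clamp", "zero")))
    }
  }
  tabs
}

.stat_loop <- function(models, cfg) {
  feats <- do.call(rbind, lapply(models, loop_features))
  h <- feature_histogram(feats$n, cfg$breaks_n, feats$d, cfg$breaks_d)
  dc <- .bin_centers(cfg$breaks_d)
  bg <- matrix(rep(dc^2, each = length(cfg$breaks_n) - 1),
               nrow = length(cfg$breaks_n) - 1)
  bg <- bg / sum(bg)
  suppressWarnings(
    energy_from_counts(h, background = bg, min_count = 0,
                       pseudo_count = cfg$pseudo,
                       oob_x = c("clamp", "clamp"), oob_y = c("clamp", "clamp")))
}

.stat_packing <- function(models, weight_col, tp, cfg) {
  rows <- do.call(rbind, lapply(models, packing_table, stat_only = TRUE))
  rows <- rows[rows$type_pair == tp, , drop = FALSE]
  h <- feature_histogram(rows$distance, cfg$breaks_d, rows$theta, cfg$breaks_t,
                         w = rows[[weight_col]])
  dc <- .bin_centers(cfg$breaks_d)
  bg <- matrix(rep(dc, times = length(cfg$breaks_t) - 1),
               nrow = length(dc))
  bg <- bg / sum(bg)
  suppressWarnings(
    energy_from_counts(h, background = bg, min_count = 1e-9,
                       repulsive_value = 0,
                       oob_x = c("clamp", "zero"), circular_y = TRUE))
}

.stat_scalar <- function(models, fn, cfg) {
  vals <- vapply(models, fn, numeric(1))
  h <- feature_histogram(vals, cfg$breaks)
  suppressWarnings(energy_from_counts(h, min_count = 1e-9))
}

#' Train the full table set
#'
#' @param models list of [protein_model] used as the training database.
#' @param config see [term_config()].
#' @return named list of tables (class `energy_table_set`): `environment`
#'   (20 tables), `aa_pair` (210 tables), `loop_length`, `strand_pairing`,
#'   `packing_hh`, `packing_hs`, `sheet_sandwich`, `contact_order`,
#'   `radius_gyration`.
#' @export
train_tables <- function(models, config = term_config()) {
  terms <- c("environment", "aa_pair", "loop_length", "strand_pairing",
             "packing_hh", "packing_hs", "sheet_sandwich", "contact_order",
             "radius_gyration")
  out <- lapply(terms, function(tm) build_term_statistics(models, tm, config))
  names(out) <- terms
  structure(out, class = "energy_table_set")
}

# ------------------------------------------------------- serialization

.table_to_list <- function(tab) {
  list(energy = unclass(tab$energy), breaks_x = tab$breaks_x,
       breaks_y = tab$breaks_y, oob_x = tab$oob_x, oob_y = tab$oob_y,
       circular_y = tab$circular_y, repulsive = tab$repulsive)
}

.table_from_list <- function(l) {
  energy <- if (!is.null(l$breaks_y)) {
    # JSON stores matrices row-major (one array per row)
    matrix(unlist(l$energy), nrow = length(l$breaks_x) - 1, byrow = TRUE)
  } else as.numeric(l$energy)
  structure(list(energy = energy, breaks_x = as.numeric(l$breaks_x),
                 breaks_y = if (is.null(l$breaks_y)) NULL else as.numeric(l$breaks_y),
                 oob_x = as.character(l$oob_x), oob_y = as.character(l$oob_y),
                 circular_y = isTRUE(l$circular_y),
                 repulsive = as.numeric(l$repulsive)),
            class = "energy_table")
}

#' Serialize / restore an energy table set as JSON
#'
#' Versioned plain-text representation so trained potentials are portable
#' and diffable.
#'
#' @param tables an `energy_table_set` from [train_tables].
#' @param path JSON file path.
#' @return `read_tables` returns the table set; `write_tables` the path.
#' @export
write_tables <- function(tables, path) {
  enc <- function(x) {
    if (inherits(x, "energy_table")) .table_to_list(x) else lapply(x, enc)
  }
  obj <- list(format = "ssescore-tables", version = 1L,
              tables = lapply(tables, enc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tables
#' @export
read_tables <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "ssescore-tables"))
    stop("not an ssescore table file: ", path)
  dec <- function(x) {
    if (!is.null(x$energy)) .table_from_list(x) else lapply(x, dec)
  }
  structure(lapply(obj$tables, dec), class = "energy_table_set")
}
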