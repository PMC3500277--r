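# Consensus scoring, native-likeness labelling, enrichment statistics and
# Monte-Carlo weight optimization.

#' Names of the twelve scoring terms
#' @export
TERM_NAMES <- c("aa_distance", "aa_neighbor", "loop_length", "radius_gyration",
                "loop_closure", "aa_clash", "sse_clash", "sse_packing",
                "strand_pairing", "contact_order", "sspred_jufo",
                "sspred_psipred")

#' Consensus weight set
#'
#' The default weights of the consensus scoring function: amino acid
#' distance 0.35, neighbour count 50, loop length 10, radius of gyration 5,
#' loop closure 500, amino acid pair clash 500, SSE clash 500, SSE packing
#' 8, strand pairing 20, contact order 0.5, prediction agreement 5 (JUFO)
#' and 20 (PSIPRED).
#'
#' @return named non-negative numeric vector over the 12 terms.
#' @export
default_weights <- function() {
  c(aa_distance = 0.35, aa_neighbor = 50, loop_length = 10,
    radius_gyration = 5, loop_closure = 500, aa_clash = 500,
    sse_clash = 500, sse_packing = 8, strand_pairing = 20,
    contact_order = 0.5, sspred_jufo = 5, sspred_psipred = 20)
}

#' Weighted consensus energy
#'
#' @param term_scores named numeric vector (or matrix with term columns).
#' @param weights named non-negative weights; names must cover the scores.
#' @return total energy in BCLEU (vector for matrix input).
#' @export
weighted_sum <- function(term_scores, weights) {
  if (any(weights < 0)) stop("weights must be >= 0")
  if (is.matrix(term_scores)) {
    w <- weights[colnames(term_scores)]
    if (anyNA(w)) stop("missing weight for some term")
    return(as.numeric(term_scores %*% w))
  }
  w <- weights[names(term_scores)]
  if (anyNA(w)) stop("missing weight for some term")
  sum(w * term_scores)
}

#' Length-normalized RMSD
#'
#' `rmsd / (1 + ln(sqrt(n / 100)))`: the C-alpha RMSD scaled to what it
#' would be for a 100-residue protein, making the native-likeness cutoff
#' comparable across chain lengths.
#'
#' @param rmsd RMSD in Angstrom.
#' @param n number of residues.
#' @return RMSD100 in Angstrom.
#' @export
rmsd100 <- function(rmsd, n) {
  rmsd / (1 + log(sqrt(n / 100)))
}

#' Enrichment of native-like models among the best-scored fraction
#'
#' Ratio of the fraction of positives among the best `fraction` of models
#' (by increasing score; lower is better) to the base rate of positives;
#' capped at `1/fraction` by construction. Ties are broken by stable input
#' order.
#'
#' @param scores numeric scores, lower = better.
#' @param labels logical (TRUE = native-like).
#' @param fraction selected fraction, default 0.1.
#' @return dimensionless enrichment in `[0, 1/fraction]`.
#' @export
enrichment <- function(scores, labels, fraction = 0.1) {
  stopifnot(length(scores) == length(labels), fraction > 0, fraction < 1)
  if (!any(labels)) stop("no positive models")
  n <- length(scores)
  ncut <- ceiling(fraction * n)
  top <- order(scores)[seq_len(ncut)]
  tp <- sum(labels[top])
  (tp / ncut) / (sum(labels) / n)
}

#' Balanced cross-validation subsets
#'
#' Builds ten subsets at a 1:9 positive:negative ratio: the class
#' over-represented relative to that ratio is split into ten equally large
#' random subsets without reuse; the under-represented class is completed
#' by random draws (re-used across subsets).
#'
#' @param labels logical vector.
#' @param seed RNG seed for reproducibility.
#' @param n_subsets number of subsets.
#' @return list of integer index vectors.
#' @export
build_balanced_subsets <- function(labels, seed = NULL, n_subsets = 10L) {
  pos <- which(labels); neg <- which(!labels)
  if (!length(pos) || !length(neg)) stop("need both classes")
  with_seed(seed, {
    pos_over <- length(pos) / length(labels) > 0.1
    over <- if (pos_over) pos else neg
    under <- if (pos_over) neg else pos
    ratio <- if (pos_over) 9 else 1 / 9   # needed under per over
    over <- sample(over)
    size <- floor(length(over) / n_subsets)
    lapply(seq_len(n_subsets), function(k) {
      ov <- over[((k - 1) * size + 1):(k * size)]
      need <- max(1L, round(length(ov) * ratio))
      un <- if (need >= length(under)) under else sample(under, need)
      sort(c(ov, un))
    })
  })
}

#' Cross-validated enrichment with significance
#'
#' Computes the enrichment on each balanced subset, their mean and standard
#' deviation, and the Z-score `(mean - 1) / sd` against the expectation of
#' 1 for a non-discriminating score.
#'
#' @param scores numeric scores, lower = better.
#' @param labels logical labels.
#' @param fraction selected fraction.
#' @param seed subset construction seed.
#' @return list of class `enrichment_result`: `enrichments`, `mean`, `sd`,
#'   `z`, `significant` (`z > 1`).
#' @export
subset_enrichment <- function(scores, labels, fraction = 0.1, seed = NULL) {
  subs <- build_balanced_subsets(labels, seed = seed)
  e <- vapply(subs, function(ix) enrichment(scores[ix], labels[ix], fraction),
              numeric(1))
  m <- mean(e); s <- stats::sd(e)
  z <- if (s > 0) (m - 1) / s else Inf * sign(m - 1)
  structure(list(enrichments = e, mean = m, sd = s, z = z,
                 significant = is.finite(z) && z > 1 || is.infinite(z) && m > 1),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> mean %.3f (sd %.3f) over %d subsets, Z = %.2f%s\n",
              x$mean, x$sd, length(x$enrichments), x$z,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Monte-Carlo/Metropolis weight optimization
#'
#' Maximizes the sum over model sets of the square root of the consensus
#' enrichment by simulated annealing: weights start at the inverse standard
#' deviation of each term over all models (degenerate terms start at 0
#' with a warning); each step adds or subtracts 10% of the starting weight
#' to two randomly chosen weights (floored at 0); moves are accepted by the
#' Metropolis criterion under a geometrically decaying temperature; the
#' search runs at most `max_iter` steps and stops after `patience` steps
#' without improvement of the best objective.
#'
#' @param sets list of `list(scores = <matrix with term columns>,
#'   labels = <logical>)`.
#' @param fraction enrichment fraction.
#' @param seed RNG seed (reproducible).
#' @param max_iter,patience iteration budget and stop criterion.
#' @param t0 start temperature; `NULL` calibrates it so that roughly half
#'   of early worsening moves would be accepted.
#' @param cooling geometric decay factor per step.
#' @return list: `weights` (best found), `objective`, `start_weights`,
#'   `trace` (best objective per step).
#' @export
optimize_weights <- function(sets, fraction = 0.1, seed = NULL,
                             max_iter = 10000L, patience = 250L,
                             t0 = NULL, cooling = 0.999) {
  stopifnot(length(sets) >= 1)
  terms <- colnames(sets[[1]]$scores)
  all_scores <- do.call(rbind, lapply(sets, `[[`, "scores"))
  sds <- apply(all_scores, 2, stats::sd)
  start <- ifelse(sds > 0, 1 / sds, 0)
  if (any(sds == 0)) warning("degenerate term(s) with zero sd start at weight 0")
  names(start) <- terms
  objective <- function(w) {
    sum(vapply(sets, function(s)
      sqrt(enrichment(as.numeric(s$scores %*% w), s$labels, fraction)),
      numeric(1)))
  }
  with_seed(seed, {
    step <- 0.1 * start
    cur <- start
    f_cur <- objective(cur)
    best <- cur; f_best <- f_cur
    if (is.null(t0)) {
      # probe: median worsening among 25 random moves from the start
      drops <- replicate(25, {
        w <- cur
        i <- sample(length(w), 2)
        w[i] <- pmax(0, w[i] + sample(c(-1, 1), 2, replace = TRUE) * step[i])
        max(0, f_cur - objective(w))
      })
      md <- stats::median(drops[drops > 0])
      t0 <- if (is.finite(md) && md > 0) md / log(2) else 0.1
    }
    temp <- t0
    stale <- 0L
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      cand <- cur
      i <- sample(length(cand), 2)
      cand[i] <- pmax(0, cand[i] + sample(c(-1, 1), 2, replace = TRUE) * step[i])
      f_cand <- objective(cand)
      accept <- f_cand >= f_cur ||
        stats::runif(1) < exp((f_cand - f_cur) / max(temp, 1e-12))
      if (accept) { cur <- cand; f_cur <- f_cand }
      if (f_cand > f_best + 1e-12) {
        best <- cand; f_best <- f_cand; stale <- 0L
      } else stale <- stale + 1L
      trace[it] <- f_best
      if (stale >= patience) break
      temp <- temp * cooling
    }
    list(weights = best, objective = f_best, start_weights = start,
         trace = trace)
  })
}
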