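# Fragment-pair packing geometry: contact weight, twist dihedral, offset
# angles and interaction-weight-maximal fragment pair lists.

#' Contact weight from connection angles
#'
#' Downgrades fragment pairs whose shortest connection is not orthogonal to
#' both main axes. Each angle in `[0, 90]` degrees is mapped through the
#' half-cosine ramp `h(a) = (1 - cos(pi * a / 90)) / 2` (so `h(90) = 1`,
#' `h(0) = 0`) and the two weights are multiplied.
#'
#' @param angle_a,angle_b angles between the shortest connection and each
#'   axis, degrees in `[0, 90]`; values outside are clamped with a warning.
#' @return weight in `[0, 1]`.
#' @export
contact_weight <- function(angle_a, angle_b) {
  cl <- function(a) {
    if (any(a < -1e-9 | a > 90 + 1e-9)) warning("connection angle clamped to [0, 90]")
    pmin(90, pmax(0, a))
  }
  h <- function(a) (1 - cos(pi * cl(a) / 90)) / 2
  h(angle_a) * h(angle_b)
}

# half-cosine ramps on the offset angle:
#   .w_face(0) = 1  -> partner sits on the strand face (side chains)
#   .w_edge(90) = 1 -> partner along the pleat plane (backbone pairing)
.w_face <- function(omega) (1 + cos(pi * omega / 90)) / 2
.w_edge <- function(omega) (1 - cos(pi * omega / 90)) / 2

#' Packing descriptors of one fragment pair
#'
#' Computes the shortest connection between the trimmed (effective) main
#' axis segments, the contact weight, the twist dihedral `theta` (dihedral
#' main axis A - shortest connection - main axis B, right-handed looking
#' along the connection from A to B), the offset angles `omega` measured on
#' strand fragments (angle between the connection and the strand face
#' vector, folded into `[0, 90]`: 0 = partner on the face, 90 = partner at
#' the backbone edge), and the interaction weight `w_I`:
#' helix-helix `w_I = w_contact`; helix-strand `w_I = w_contact *
#' w_face(omega_strand)`; strand-strand contributions are apportioned into
#' a backbone-pairing part `w_contact * w_edge(omega1) * w_edge(omega2)`
#' and a sheet-sandwich part `w_contact * w_face(omega1) * w_face(omega2)`,
#' with `w_I` their sum.
#'
#' @param frag_a,frag_b fragment sets from [fragment_decompose].
#' @param i,j fragment indices within each set.
#' @return one-row data.frame (class `fragment_packing`): `type_pair`
#'   (HH/HS/SS), `distance`, `theta`, `omega1`, `omega2`, `w_contact`,
#'   `w_pair`, `w_sand`, `w_i`, `degenerate`.
#' @export
packing_descriptors <- function(frag_a, frag_b, i = 1L, j = 1L) {
  v <- .pack_pair(frag_a, frag_b, i, j)
  out <- data.frame(type_pair = .pack_type(frag_a$type, frag_b$type),
                    distance = v[1], theta = v[2],
                    omega1 = v[3], omega2 = v[4], w_contact = v[5],
                    w_pair = v[6], w_sand = v[7], w_i = v[8],
                    degenerate = v[9] > 0)
  class(out) <- c("fragment_packing", class(out))
  out
}

.pack_type <- function(ta, tb) {
  if (ta == "H" && tb == "H") "HH" else if (ta == "E" && tb == "E") "SS" else "HS"
}

# numeric hot path: c(distance, theta, omega1, omega2, w_contact, w_pair,
# w_sand, w_i, degenerate)
.pack_pair <- function(frag_a, frag_b, i, j) {
  sc <- shortest_connection(frag_a$eff_start[i, ], frag_a$eff_end[i, ],
                            frag_b$eff_start[j, ], frag_b$eff_end[j, ])
  axa <- frag_a$axis[i, ]; axb <- frag_b$axis[j, ]
  w_c <- contact_weight(sc$angle_a, sc$angle_b)
  conn <- sc$point_b - sc$point_a
  degen <- sc$degenerate
  theta <- 0
  if (!degen) {
    cu <- conn / sc$distance
    # theta undefined when an axis is parallel to the connection
    if (vnorm(vcross(axa, cu)) > 1e-8 && vnorm(vcross(axb, cu)) > 1e-8) {
      # p1/p4 on the axis-direction side of each fragment: parallel
      # same-direction fragments give 0, antiparallel ones +/-180
      theta <- dihedral_angle(sc$point_a + axa, sc$point_a,
                              sc$point_b, sc$point_b + axb)
    } else degen <- TRUE
  }
  om <- function(frag, k, cdir) {
    acos(min(1, abs(sum(vunit(cdir) * frag$face[k, ])))) * .DEG
  }
  ta <- frag_a$type; tb <- frag_b$type
  omega1 <- omega2 <- NA_real_
  w_pair <- w_sand <- 0
  if (ta == "H" && tb == "H") {
    w_i <- w_c
  } else if (ta == "E" && tb == "E") {
    omega1 <- if (degen) 0 else om(frag_a, i, conn)
    omega2 <- if (degen) 0 else om(frag_b, j, -conn)
    w_pair <- w_c * .w_edge(omega1) * .w_edge(omega2)
    w_sand <- w_c * .w_face(omega1) * .w_face(omega2)
    w_i <- w_pair + w_sand
  } else {
    omega1 <- if (degen) 0 else if (ta == "E") om(frag_a, i, conn) else
      om(frag_b, j, -conn)
    w_i <- w_c * .w_face(omega1)
  }
  c(sc$distance, theta, omega1, omega2, w_c, w_pair, w_sand, w_i,
    as.numeric(degen))
}

#' Interaction-weight-maximal fragment pairs of two SSEs
#'
#' For every fragment of the shorter SSE (fewer fragments; on a tie the SSE
#' given first, i.e. earlier in sequence) the partner fragment of the
#' longer SSE with the highest interaction weight `w_I` is selected, so the
#' list has as many entries as the shorter SSE has fragments.
#'
#' @param sse_a,sse_b SSE entries of a [protein_model] (`sse_a` earlier in
#'   sequence), each carrying a `frag` set and a `type`.
#' @return data.frame of packing descriptors with columns `frag_short`,
#'   `frag_long` appended; zero rows when either SSE has no fragments.
#'   Columns `omega1`/`omega2` refer to the first/second strand argument in
#'   the order (shorter, longer).
#' @export
best_fragment_pairs <- function(sse_a, sse_b) {
  fa <- sse_a$frag; fb <- sse_b$frag
  empty <- data.frame(type_pair = character(), distance = numeric(),
                      theta = numeric(), omega1 = numeric(), omega2 = numeric(),
                      w_contact = numeric(), w_pair = numeric(),
                      w_sand = numeric(), w_i = numeric(),
                      degenerate = logical(),
                      frag_short = integer(), frag_long = integer())
  if (is.null(fa) || is.null(fb)) return(empty)
  swap <- fb$n_frag < fa$n_frag
  fs <- if (swap) fb else fa
  fl <- if (swap) fa else fb
  tp <- .pack_type(fs$type, fl$type)
  vals <- matrix(NA_real_, fs$n_frag, 9)
  jbest <- integer(fs$n_frag)
  for (i in seq_len(fs$n_frag)) {
    for (j in seq_len(fl$n_frag)) {
      v <- .pack_pair(fs, fl, i, j)
      if (j == 1L || v[8] > vals[i, 8]) { vals[i, ] <- v; jbest[i] <- j }
    }
  }
  data.frame(type_pair = tp, distance = vals[, 1], theta = vals[, 2],
             omega1 = vals[, 3], omega2 = vals[, 4], w_contact = vals[, 5],
             w_pair = vals[, 6], w_sand = vals[, 7], w_i = vals[, 8],
             degenerate = vals[, 9] > 0,
             frag_short = seq_len(fs$n_frag), frag_long = jbest)
}

#' Packing descriptor table of a whole model
#'
#' Debug/statistics dump: the best fragment pair list of every SSE pair.
#'
#' @param model a [protein_model].
#' @param stat_only keep only SSE pairs where both SSEs meet the minimum
#'   length for packing statistics (helix >= 7, strand >= 5 residues).
#' @return data.frame with `sse_a`, `sse_b` (indices) and the descriptor
#'   columns of [best_fragment_pairs].
#' @export
packing_table <- function(model, stat_only = FALSE) {
  ns <- length(model$sses)
  rows <- list()
  if (ns >= 2) {
    for (a in seq_len(ns - 1)) {
      for (b in (a + 1):ns) {
        sa <- model$sses[[a]]; sb <- model$sses[[b]]
        if (stat_only && !(sa$stat_ok && sb$stat_ok)) next
        bp <- best_fragment_pairs(sa, sb)
        if (nrow(bp)) {
          bp$sse_a <- a; bp$sse_b <- b
          rows[[length(rows) + 1L]] <- bp
        }
      }
    }
  }
  if (!length(rows)) {
    out <- best_fragment_pairs(list(frag = NULL), list(frag = NULL))
    out$sse_a <- integer(); out$sse_b <- integer()
    return(out)
  }
  do.call(rbind, rows)
}
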