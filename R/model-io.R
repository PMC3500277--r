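# SSE-only reduced protein models: containers, ideal fragment templates,
# fragment decomposition and PDB I/O.

FRAGMENT_LENGTH <- c(H = 5L, E = 3L)   # residues per fragment window
SSE_MIN_STAT    <- c(H = 7L, E = 5L)   # below this the SSE is excluded
                                       # from packing statistics
AXIS_TRIM <- 2.0                       # Angstrom trimmed from each axis end

# Ideal backbone dihedrals used for the templates (the reference data the
# fragment superposition is anchored to).
.IDEAL_PHI_PSI <- list(H = c(phi = -60, psi = -45),
                       E = c(phi = -120, psi = 135))

# Standard backbone covalent geometry (Engh-Huber-like).
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
            a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7)

# Place atom D given A, B, C with bond |CD|, angle BCD (deg), dihedral
# ABCD (deg) -- natural extension reference frame construction.
.nerf <- function(a, b, c, bond, angle, dihedral) {
  th <- (180 - angle) / .DEG
  ph <- dihedral / .DEG
  d2 <- c(bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  as.numeric(m %*% d2 + c)
}

# Build an ideal backbone chain (N, CA, C per residue) from repeated
# phi/psi, omega = 180. Returns list of n x 3 matrices.
build_ideal_backbone <- function(type, n) {
  pp <- .IDEAL_PHI_PSI[[type]]
  N <- CA <- C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BB$b_n_ca, 0, 0)
  th <- (180 - .BB$a_n_ca_c) / .DEG
  C[1, ] <- CA[1, ] + .BB$b_ca_c * c(cos(pi - th) * -1, sin(th), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                      .BB$b_c_n, .BB$a_ca_c_n, pp["psi"])
      CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ],
                       .BB$b_n_ca, .BB$a_c_n_ca, 180)    # omega
      C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ],
                      .BB$b_ca_c, .BB$a_n_ca_c, pp["phi"])
    }
  }
  list(N = N, CA = CA, C = C)
}

# Cached ideal fragment templates: CA coordinates plus the screw-derived
# main axis (direction, a point on it, rise per residue).
.tpl_cache <- new.env(parent = emptyenv())

fragment_template <- function(type) {
  key <- type
  if (!is.null(.tpl_cache[[key]])) return(.tpl_cache[[key]])
  len <- FRAGMENT_LENGTH[[type]]
  bb <- build_ideal_backbone(type, len + 2L)  # extra residues stabilize axis
  ca <- bb$CA[seq_len(len) + 1L, , drop = FALSE]
  # screw transform between consecutive windows of the periodic chain
  m <- nrow(bb$CA)
  fit <- kabsch(bb$CA[1:(m - 1), , drop = FALSE], bb$CA[2:m, , drop = FALSE])
  sc <- screw_axis(fit$R, fit$t)
  cen <- colMeans(ca)
  axis_center <- sc$point + sum((cen - sc$point) * sc$axis) * sc$axis
  tpl <- list(type = type, len = len, ca = ca,
              axis = sc$axis, center = axis_center, rise = sc$rise)
  .tpl_cache[[key]] <- tpl
  tpl
}

#' Decompose an SSE into oriented overlapping fragments
#'
#' Slides a 5-residue (helix) or 3-residue (strand) window along the SSE and
#' superimposes the ideal template onto each window's CA coordinates to
#' obtain an oriented main-axis segment per fragment. The full axis segment
#' spans `len * rise` Angstrom centred on the window; the effective segment
#' is trimmed by 2 Angstrom at each end so that two fragments must share a
#' minimal 4 Angstrom interface to make an orthogonal contact.
#'
#' For strand fragments a unit "face" vector (the pleat direction of the
#' central residue, orthogonalized against the axis) is stored; offset
#' angles are measured against it.
#'
#' @param ca n x 3 CA coordinate matrix of the SSE (sequence order).
#' @param type "H" or "E".
#' @return list with per-fragment matrices (`origin`, `axis`, `full_start`,
#'   `full_end`, `eff_start`, `eff_end`, `face`) and scalars `len`, `rise`,
#'   `n_frag`; `NULL` when the SSE is shorter than one window.
#' @export
fragment_decompose <- function(ca, type) {
  tpl <- fragment_template(type)
  len <- tpl$len
  n <- nrow(ca)
  if (is.null(n) || n < len) return(NULL)
  k <- n - len + 1L
  origin <- axis <- face <- matrix(NA_real_, k, 3)
  half_full <- len * tpl$rise / 2
  half_eff <- max(0, half_full - AXIS_TRIM)
  for (i in seq_len(k)) {
    w <- ca[i:(i + len - 1L), , drop = FALSE]
    fit <- kabsch(tpl$ca, w)
    axis[i, ] <- as.numeric(fit$R %*% tpl$axis)
    origin[i, ] <- as.numeric(fit$R %*% tpl$center + fit$t)
    if (type == "E") {
      j <- i + (len - 1L) %/% 2L          # central residue of the window
      if (j > 1 && j < n) {
        v <- ca[j - 1L, ] + ca[j + 1L, ] - 2 * ca[j, ]
        v <- v - sum(v * axis[i, ]) * axis[i, ]
        if (vnorm(v) > 1e-8) face[i, ] <- vunit(v)
      }
    }
  }
  # fall back for terminal strand windows without a pleat neighbour
  if (type == "E" && anyNA(face)) {
    ok <- which(!is.na(face[, 1]))
    if (length(ok)) {
      for (i in which(is.na(face[, 1]))) {
        j <- ok[which.min(abs(ok - i))]
        v <- face[j, ] - sum(face[j, ] * axis[i, ]) * axis[i, ]
        face[i, ] <- if (vnorm(v) > 1e-8) vunit(v) else .any_perp(axis[i, ])
      }
    } else {
      for (i in seq_len(k)) face[i, ] <- .any_perp(axis[i, ])
    }
  }
  list(type = type, len = len, n_frag = k, rise = tpl$rise,
       half_full = half_full, half_eff = half_eff,
       origin = origin, axis = axis,
       full_start = origin - half_full * axis,
       full_end = origin + half_full * axis,
       eff_start = origin - max(half_eff, 1e-3) * axis,
       eff_end = origin + max(half_eff, 1e-3) * axis,
       face = if (type == "E") face else NULL)
}

.any_perp <- function(a) {
  v <- vcross(a, c(1, 0, 0))
  if (vnorm(v) < 1e-6) v <- vcross(a, c(0, 1, 0))
  vunit(v)
}

#' Construct an SSE-only protein model
#'
#' @param residues data.frame with columns `chain`, `seq_id`, `aa`
#'   (three-letter code), anchor coordinates `ax`, `ay`, `az`, logical
#'   `has_bb` and backbone columns `nx..oz` (NA allowed when `has_bb` is
#'   FALSE), and `sse` (integer SSE index or NA).
#' @param sses list of `list(type, rows)` in sequence order; fragments are
#'   derived here.
#' @param n_residues total sequence length including unmodelled loop
#'   residues.
#' @param chains chain identifiers.
#' @return object of class `protein_model`.
#' @export
protein_model <- function(residues, sses, n_residues = NULL, chains = NULL) {
  stopifnot(is.data.frame(residues))
  if (anyDuplicated(residues[, c("chain", "seq_id")]))
    stop("duplicate seq_id within a chain")
  if (is.null(chains)) chains <- unique(residues$chain)
  if (is.null(n_residues)) {
    n_residues <- sum(vapply(split(residues$seq_id, residues$chain),
                             function(s) diff(range(s)) + 1L, numeric(1)))
  }
  sses <- lapply(sses, function(s) {
    rows <- s$rows
    sq <- residues$seq_id[rows]
    if (length(rows) > 1 && any(diff(sq) != 1L))
      stop("SSE residues must be contiguous in seq_id")
    ca <- as.matrix(residues[rows, c("cax", "cay", "caz")])
    frag <- if (all(residues$has_bb[rows])) fragment_decompose(ca, s$type) else NULL
    list(type = s$type, rows = rows,
         stat_ok = length(rows) >= SSE_MIN_STAT[[s$type]],
         frag = frag)
  })
  if (n_residues < sum(lengths(lapply(sses, `[[`, "rows"))))
    stop("n_residues smaller than the number of SSE residues")
  structure(list(residues = residues, sses = sses,
                 n_residues = as.integer(n_residues), chains = chains),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  tys <- vapply(x$sses, `[[`, "", "type")
  cat(sprintf("<protein_model> %d modelled residues / %d total, %d SSEs (%d H, %d E)\n",
              nrow(x$residues), x$n_residues, length(x$sses),
              sum(tys == "H"), sum(tys == "E")))
  invisible(x)
}

#' Anchor coordinates of a model
#' @param model a `protein_model`.
#' @return n x 3 matrix of side-chain anchor coordinates.
#' @export
anchors <- function(model) {
  as.matrix(model$residues[, c("ax", "ay", "az")])
}

# ---------------------------------------------------------------- PDB I/O

.pdb_num <- function(lines, from, to) {
  suppressWarnings(as.numeric(substr(lines, from, to)))
}

#' Read a PDB file into an SSE-only model
#'
#' Parses ATOM records (N, CA, C, O, CB, and HA2 for glycine) and assigns
#' one side-chain anchor per residue: the CB atom, HA2 for glycine, or an
#' ideal CB rebuilt from the backbone when the anchor atom is absent.
#' Residues with neither anchor atom nor complete backbone are skipped with
#' a warning. Secondary structure comes from HELIX/SHEET records or, with
#' priority, from an external per-residue assignment file (two whitespace
#' separated columns: seq_id and H/E/C).
#'
#' @param path PDB file.
#' @param ss_assignment optional path to an external assignment file.
#' @return a [protein_model].
#' @export
read_pdb <- function(path, ss_assignment = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  at <- lines[rec == "ATOM  "]
  if (!length(at)) stop("no ATOM records in ", path)
  name <- trimws(substr(at, 13, 16))
  alt <- substr(at, 17, 17)
  keep <- alt %in% c(" ", "A") & name %in% c("N", "CA", "C", "O", "CB", "HA2", "2HA")
  at <- at[keep]; name <- name[keep]
  name[name == "2HA"] <- "HA2"
  resn <- trimws(substr(at, 18, 20))
  chain <- substr(at, 22, 22)
  seqn <- as.integer(substr(at, 23, 26))
  icode <- substr(at, 27, 27)
  if (any(icode != " ")) stop("insertion codes are not supported")
  xyz <- cbind(.pdb_num(at, 31, 38), .pdb_num(at, 39, 46), .pdb_num(at, 47, 54))
  key <- paste(chain, seqn)
  ord <- order(chain, seqn)
  ukey <- unique(key[ord])
  res <- vector("list", length(ukey))
  skipped <- 0L
  for (i in seq_along(ukey)) {
    sel <- which(key == ukey[i])
    get <- function(nm) {
      j <- sel[match(nm, name[sel])]
      if (is.na(j)) rep(NA_real_, 3) else xyz[j, ]
    }
    aa <- resn[sel[1]]
    if (!aa %in% AA_TYPES) { skipped <- skipped + 1L; next }
    n <- get("N"); ca <- get("CA"); cc <- get("C"); o <- get("O")
    has_bb <- !anyNA(c(n, ca, cc))
    anc <- if (aa == "GLY") get("HA2") else get("CB")
    if (anyNA(anc)) {
      if (!has_bb) { skipped <- skipped + 1L; next }
      anc <- reconstruct_cbeta(n, ca, cc,
                               length = if (aa == "GLY") 1.09 else NULL)
    }
    res[[i]] <- data.frame(chain = chain[sel[1]], seq_id = seqn[sel[1]],
                           aa = aa, ax = anc[1], ay = anc[2], az = anc[3],
                           has_bb = has_bb,
                           nx = n[1], ny = n[2], nz = n[3],
                           cax = ca[1], cay = ca[2], caz = ca[3],
                           cx = cc[1], cy = cc[2], cz = cc[3],
                           ox = o[1], oy = o[2], oz = o[3])
  }
  if (skipped > 0)
    warning(sprintf("%d residue(s) skipped (no anchor atom and no backbone)", skipped))
  residues <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(residues) || !nrow(residues)) stop("no usable residues in ", path)
  rownames(residues) <- NULL

  ranges <- if (!is.null(ss_assignment)) {
    .ranges_from_assignment(ss_assignment, residues)
  } else {
    .ranges_from_records(lines, rec)
  }
  sses <- .build_sse_list(residues, ranges)

  n_res <- NULL
  sq <- lines[rec == "SEQRES"]
  if (length(sq)) {
    per <- tapply(as.integer(substr(sq, 14, 17)), substr(sq, 12, 12), max)
    n_res <- sum(per)
  }
  protein_model(residues, sses, n_residues = n_res)
}

.ranges_from_records <- function(lines, rec) {
  out <- list()
  for (l in lines[rec == "HELIX "]) {
    out[[length(out) + 1L]] <- list(type = "H", chain = substr(l, 20, 20),
                                    from = as.integer(substr(l, 22, 25)),
                                    to = as.integer(substr(l, 34, 37)))
  }
  for (l in lines[rec == "SHEET "]) {
    out[[length(out) + 1L]] <- list(type = "E", chain = substr(l, 22, 22),
                                    from = as.integer(substr(l, 23, 26)),
                                    to = as.integer(substr(l, 34, 37)))
  }
  out
}

.ranges_from_assignment <- function(path, residues) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("seq_id", "state"),
                           colClasses = c("integer", "character"))
  tab <- tab[tab$state %in% c("H", "E"), , drop = FALSE]
  if (!nrow(tab)) return(list())
  tab <- tab[order(tab$seq_id), ]
  brk <- c(0L, which(diff(tab$seq_id) != 1L | tab$state[-1] != tab$state[-nrow(tab)]),
           nrow(tab))
  out <- list()
  ch <- residues$chain[1]
  for (i in seq_len(length(brk) - 1L)) {
    seg <- tab[(brk[i] + 1L):brk[i + 1L], ]
    out[[i]] <- list(type = seg$state[1], chain = ch,
                     from = min(seg$seq_id), to = max(seg$seq_id))
  }
  out
}

.build_sse_list <- function(residues, ranges) {
  sses <- list()
  claimed <- rep(FALSE, nrow(residues))
  ord <- order(vapply(ranges, function(r) r$from, numeric(1)))
  for (r in ranges[ord]) {
    rows <- which(residues$chain == r$chain &
                    residues$seq_id >= r$from & residues$seq_id <= r$to &
                    !claimed)
    if (!length(rows)) next
    # split on gaps in the observed residues so SSEs stay contiguous
    runs <- split(rows, cumsum(c(1L, diff(residues$seq_id[rows]) != 1L)))
    for (run in runs) {
      claimed[run] <- TRUE
      sses[[length(sses) + 1L]] <- list(type = r$type, rows = run)
    }
  }
  first <- vapply(sses, function(s) min(residues$seq_id[s$rows]), numeric(1))
  sses[order(first)]
}

#' Write a model to a PDB file
#'
#' Emits HELIX/SHEET records followed by ATOM records (N, CA, C, CB or HA2
#' for glycine, plus O when present).
#'
#' @param model a [protein_model].
#' @param path output file.
#' @export
write_pdb <- function(model, path) {
  res <- model$residues
  out <- character(0)
  hel <- 0L; sht <- 0L
  for (s in model$sses) {
    r0 <- res[s$rows[1], ]; r1 <- res[s$rows[length(s$rows)], ]
    if (s$type == "H") {
      hel <- hel + 1L
      out <- c(out, sprintf(
        "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1%36d    ",
        hel, sprintf("%3d", hel), r0$aa, r0$chain, r0$seq_id,
        r1$aa, r1$chain, r1$seq_id, length(s$rows)))
    } else {
      sht <- sht + 1L
      out <- c(out, sprintf(
        "SHEET  %3d %3s 1 %3s %1s%4d  %3s %1s%4d  0",
        sht, sprintf("%3s", paste0("S", sht)), r0$aa, r0$chain, r0$seq_id,
        r1$aa, r1$chain, r1$seq_id))
    }
  }
  ser <- 0L
  fmt <- function(nm, aa, ch, sq, p, el) {
    ser <<- ser + 1L
    sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            ser, ifelse(nchar(nm) < 4, paste0(" ", nm), nm), aa, ch, sq,
            p[1], p[2], p[3], el)
  }
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    if (r$has_bb) {
      out <- c(out, fmt("N", r$aa, r$chain, r$seq_id, c(r$nx, r$ny, r$nz), "N"),
               fmt("CA", r$aa, r$chain, r$seq_id, c(r$cax, r$cay, r$caz), "C"),
               fmt("C", r$aa, r$chain, r$seq_id, c(r$cx, r$cy, r$cz), "C"))
      if (!is.na(r$ox))
        out <- c(out, fmt("O", r$aa, r$chain, r$seq_id, c(r$ox, r$oy, r$oz), "O"))
    }
    nm <- if (r$aa == "GLY") "HA2" else "CB"
    el <- if (r$aa == "GLY") "H" else "C"
    out <- c(out, fmt(nm, r$aa, r$chain, r$seq_id, c(r$ax, r$ay, r$az), el))
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
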