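# Low-level 3D geometry shared by fragment decomposition and packing.

.DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix (right-handed).
#' @export
rotation_about <- function(axis, angle) {
  u <- vunit(axis)
  th <- angle / .DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds rotation `R` and translation `t` minimizing `||P R' + t - Q||`
#' so that `x_new = R %*% x + t` maps points of `P` onto `Q`.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, non-collinear for a unique
#'   rotation).
#' @return list with `R` (3x3) and `t` (length-3).
#' @keywords internal
kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

#' Screw axis of a rigid transform
#'
#' Decomposes `x -> R x + t` into a rotation axis, a point on that axis and
#' the translation (rise) along it. Used to recover the main axis of ideal
#' helical/extended templates from the transform relating consecutive
#' residue windows.
#'
#' @keywords internal
screw_axis <- function(R, t) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  a <- Re(e$vectors[, i])
  a <- vunit(a)
  rise <- sum(a * t)
  if (rise < 0) { a <- -a; rise <- -rise }
  # point on the axis: (I - R) p = t_perp, solved in the plane orthogonal to a
  tp <- t - rise * a
  M <- diag(3) - R
  p <- tryCatch(qr.solve(qr(M, tol = 1e-10), tp), error = function(e) {
    # least squares fallback via pseudo-inverse
    sv <- svd(M)
    pos <- sv$d > 1e-8
    dinv <- ifelse(pos, 1 / sv$d, 0)
    as.numeric(sv$v %*% (dinv * crossprod(sv$u, tp)))
  })
  p <- as.numeric(p)
  p <- p - sum(p * a) * a + 0 * a   # arbitrary reference along a
  list(axis = a, point = p, rise = rise)
}

#' Signed dihedral angle of four points
#'
#' Right-handed dihedral p1-p2-p3-p4 in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * .DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Shortest connection between two line segments
#'
#' Analytic closest approach between segments `a0->a1` and `b0->b1`,
#' with endpoint clamping. `angle_a`/`angle_b` are the angles between the
#' connection and each segment direction, folded into `[0, 90]` degrees so
#' that 90 means orthogonal and 0 collinear.
#'
#' @param a0,a1,b0,b1 3-vectors; segment endpoints.
#' @return list: `point_a`, `point_b`, `distance`, `angle_a`, `angle_b`,
#'   `degenerate` (TRUE when the two closest points coincide and the angles
#'   are conventionally set to 90).
#' @export
shortest_connection <- function(a0, a1, b0, b1) {
  d1 <- a1 - a0
  d2 <- b1 - b0
  L1 <- vnorm(d1); L2 <- vnorm(d2)
  if (L1 < 1e-9 || L2 < 1e-9) stop("zero-length segment")
  r <- a0 - b0
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  b <- sum(d1 * d2); cc <- sum(d1 * r)
  denom <- a * e - b * b
  s <- if (denom > 1e-12 * a * e) clamp01((b * f - cc * e) / denom) else 0
  tt <- (b * s + f) / e
  if (tt < 0) { tt <- 0; s <- clamp01(-cc / a) }
  else if (tt > 1) { tt <- 1; s <- clamp01((b - cc) / a) }
  pa <- a0 + s * d1
  pb <- b0 + tt * d2
  conn <- pb - pa
  d <- vnorm(conn)
  if (d < 1e-9) {
    return(list(point_a = pa, point_b = pb, distance = d,
                angle_a = 90, angle_b = 90, degenerate = TRUE))
  }
  cu <- conn / d
  fold <- function(dir) acos(min(1, abs(sum(cu * dir)))) * .DEG
  list(point_a = pa, point_b = pb, distance = d,
       angle_a = fold(d1 / L1), angle_b = fold(d2 / L2), degenerate = FALSE)
}

clamp01 <- function(x) min(1, max(0, x))

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
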