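#' Torsion angle of four points
#'
#' IUPAC sign convention (right-hand rule about the central B-C bond): the
#' angle is positive when, looking from B towards C, the far bond C-D is
#' rotated clockwise from the near bond B-A. For the quadruple
#' (0,1,0), (0,0,0), (1,0,0), (1,0,1) this convention yields +pi/2.
#' Returns values in (-pi, pi]; NA when either bonded triple is collinear
#' (the torsion is undefined there).
#'
#' @param a,b,c,d numeric matrices n x 3 (or length-3 vectors).
#' @return numeric vector of torsions, radians.
#' @export
torsionAngle <- function(a, b, c, d) {
  asMat <- function(x) if (is.matrix(x)) x else matrix(x, 1, 3)
  a <- asMat(a); b <- asMat(b); c <- asMat(c); d <- asMat(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- rowCross(b1, b2)
  n2 <- rowCross(b2, b3)
  x <- rowSums(n1 * n2)
  y <- sqrt(rowSums(b2 * b2)) * rowSums(b1 * n2)
  ang <- atan2(y, x)
  # collinearity: either cross product vanishes relative to bond scale
  s1 <- rowSums(n1 * n1)
  s2 <- rowSums(n2 * n2)
  sc <- rowSums(b2 * b2)
  bad <- s1 < 1e-18 * sc | s2 < 1e-18 * sc | sc < 1e-18
  ang[bad] <- NA_real_
  # map -pi to +pi so the range is (-pi, pi]
  ang[!is.na(ang) & ang <= -pi + 1e-15] <- pi
  ang
}

rowCross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# wrap radians into (-pi, pi]
wrapAngle <- function(x) {
  y <- x - 2 * pi * floor((x + pi) / (2 * pi))
  y[y <= -pi + 1e-15] <- pi
  y
}

# NeRF atom placement: position D such that |C-D| = bond, angle(B,C,D) =
# angle, and torsionAngle(A,B,C,D) = torsion (same convention as above)
placeAtom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + cbind(bc, m, n) %*% d2
}

# Kabsch: optimal rotation (and translation) superposing P onto Q,
# minimising the weighted RMSD. P, Q: n x 3; w: atom weights.
kabschAlign <- function(P, Q, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- w / sum(w)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc * w, Qc)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, s))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(Pc %*% t(R), 2, cq, "+")
}
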