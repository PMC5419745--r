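# Small 3-D geometry kernel: dihedrals, internal-coordinate atom
# placement (NeRF) and weighted Kabsch superposition.

.vnorm <- function(v) sqrt(sum(v * v))

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Signed dihedral (degrees) for points a-b-c-d.
.dihedral <- function(a, b, c_, d) {
  b1 <- b - a; b2 <- c_ - b; b3 <- d - c_
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, b2 / .vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# NeRF: place atom D at distance `bond` from C, angle `theta` (deg) for
# B-C-D and dihedral `chi` (deg) for A-B-C-D.
.place_atom <- function(a, b, c_, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- -chi * pi / 180  # sign matches the .dihedral convention
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch),
          bond * sin(th) * sin(ch))
  bc <- c_ - b
  bc <- bc / .vnorm(bc)
  n <- .vcross(b - a, bc)
  n <- n / .vnorm(n)
  m <- .vcross(n, bc)
  M <- cbind(bc, m, n)
  c_ + as.vector(M %*% d2)
}

# Optimal rotation (Kabsch) aligning `mob` onto `ref` (n x 3 matrices)
# with per-point weights; returns the transformed mobile coordinates.
.kabsch_align <- function(mob, ref, w = NULL) {
  n <- nrow(mob)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cm <- colSums(mob * w)
  cr <- colSums(ref * w)
  A <- sweep(mob, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A * w) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  sweep(A %*% t(R), 2, cr, "+")
}
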