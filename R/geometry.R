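# Internal 3D geometry helpers (base-R, used by builders and analysis).

.vnorm <- function(v) sqrt(sum(v * v))

.vangle <- function(a, b, c) {
  # angle a-b-c in radians
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(pmin(1, pmax(-1, cosang)))
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.vdihedral <- function(p1, p2, p3, p4) {
  # IUPAC-signed torsion p1-p2-p3-p4 in radians
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .vcross(b1, b2); n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, b2 / .vnorm(b2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# NeRF placement: new atom at bond length b from a3, with angle(a2,a3,new)
# = theta and torsion(a1,a2,a3,new) = phi (radians).
.place_atom <- function(a1, a2, a3, b, theta, phi) {
  bc <- a3 - a2; bc <- bc / .vnorm(bc)
  ab <- a2 - a1
  n <- .vcross(ab, bc); n <- n / .vnorm(n)
  m <- .vcross(n, bc)
  d <- c(-b * cos(theta), b * cos(phi) * sin(theta), -b * sin(phi) * sin(theta))
  a3 + d[1] * bc + d[2] * m + d[3] * n
}

.deg2rad <- function(x) x * pi / 180
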