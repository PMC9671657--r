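# Small 3-D geometry helpers (internal).

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural extension reference frame (NeRF): place atom D given three
# previous atoms A-B-C, bond length |CD|, angle B-C-D (deg) and torsion
# A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# rotation matrix mapping unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- unitv(u); v <- unitv(v)
  w <- cross3(u, v)
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitv(cross3(u, p))
    return(2 * outer(ax, ax) - diag(3))
  }
  w <- w / s
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
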