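# Small 3D vector helpers shared by the generator and morphometry layers.

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize the zero vector")
  v / n
}

# Rodrigues rotation of vector v about unit axis k by angle (degrees).
rotate_about <- function(v, k, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit(k)
  v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Angle between two vectors in degrees, in [0, 180].
vec_angle_deg <- function(a, b) {
  na <- vnorm(a)
  nb <- vnorm(b)
  if (na == 0 || nb == 0) return(NA_real_)
  cosang <- sum(a * b) / (na * nb)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# An arbitrary unit vector perpendicular to d.
perpendicular_to <- function(d) {
  d <- unit(d)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(d, ref))
}

# A rotation matrix about a unit axis (Rodrigues, matrix form).
rotation_matrix <- function(axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- unit(axis)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
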