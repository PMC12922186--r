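# small rigid-body geometry helpers (internal)

rot_z <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(a) {
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# uniform-ish random proper rotation from the current RNG stream
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}

# coords: n x 3 matrix; R: 3x3; t: length-3 translation
rigid_transform <- function(coords, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

# minimum-image displacement for an orthorhombic box (A); dx: n x 3
min_image <- function(dx, box) {
  for (k in 1:3) {
    dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  }
  dx
}

# minimum-image distances between rows of a (n x 3) and b (m x 3): n*m vector-free
# returns n x m matrix
min_image_dist <- function(a, b, box = NULL) {
  n <- nrow(a); m <- nrow(b)
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  dz <- outer(a[, 3], b[, 3], `-`)
  if (!is.null(box)) {
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

deg2rad <- function(x) x * pi / 180
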