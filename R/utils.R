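# internal small-vector helpers; 3-vectors as numeric(3), point sets as n x 3

.norm3 <- function(v) sqrt(sum(v * v))

.unit3 <- function(v) {
  n <- .norm3(v)
  if (n < 1e-12) stop("cannot normalise a near-zero vector", call. = FALSE)
  v / n
}

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

# Rodrigues rotation matrix: right-handed rotation by `deg` degrees about unit
# axis u (rotates column vectors: x' = R %*% x).
rotation_matrix <- function(axis, deg) {
  u <- .unit3(axis)
  th <- .rad(deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3L], u[2L],
                 u[3L], 0, -u[1L],
                 -u[2L], u[1L], 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

# rotate rows of an n x 3 matrix about an axis line through `origin`
.rotate_about <- function(xyz, origin, axis, deg) {
  R <- rotation_matrix(axis, deg)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, `+`)
}

# wrap angles (degrees) into (-180, 180]
wrap_angle <- function(x) {
  w <- x - 360 * round(x / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("non-finite values in %s", what)
  invisible(x)
}
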