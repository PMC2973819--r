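# Small internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Torsion angle a-b-c-d in degrees, in (-180, 180].
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Signed cube root (base ^ operator returns NaN for negative bases).
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
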