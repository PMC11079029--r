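# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stopf("non-finite values in %s", what)
  invisible(x)
}

# Run `expr` under a locally seeded RNG without disturbing the caller's
# stream; every public generator routes its randomness through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stopf("a seed is required for reproducible generation")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stopf("cannot normalise a zero-length vector")
  v / n
}
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}
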