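#' @keywords internal
"_PACKAGE"

## Run code with a local RNG state seeded by `seed`, restoring the caller's
## stream afterwards so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
  }
  force(code)
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

## Spherical linear interpolation between two unit vectors.
slerp <- function(p, q, t) {
  p <- p / sqrt(sum(p^2)); q <- q / sqrt(sum(q^2))
  d <- max(-1, min(1, sum(p * q)))
  om <- acos(d)
  if (om < 1e-12) return(p)
  (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
}
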