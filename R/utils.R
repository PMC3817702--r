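# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards.  All stochastic operations in the package go
## through this so a single run seed controls everything.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## Deterministic 32-bit sub-seed derived from a run seed and a character key;
## keeps derived seeds inside R's integer range.
deriveSeed <- function(seed, key) {
  h <- 97531
  for (ch in utf8ToInt(paste0(key, ":", seed))) {
    h <- bitwXor(as.integer(h), ch)
    h <- (h * 16777619) %% 2147483629
  }
  as.integer(h %% 2147483587 + 1)
}

## Wrap fractional coordinates into [0, 1).
fracWrap <- function(x) x - floor(x)

## Minimum-image wrap of a fractional delta into [-0.5, 0.5).
fracMin <- function(x) x - round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

isOrthonormal <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}
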