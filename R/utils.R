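## Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))

## Clip beta values away from {0,1} so the logit is finite.
.clipUnit <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one integer master seed. Each
#' generator component draws from its own named substream so that adding or
#' reordering components does not perturb the draws of the others. The
#' substream seed is a deterministic 31-bit hash of the master seed and the
#' component name.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the substream.
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @examples
#' substreamSeed(1L, "noise")
#' @export
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

## Evaluate expr with a temporary RNG state seeded from (seed, name).
.withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  expr
}

## Population (1/n) standard deviation.
.popSD <- function(x) {
  x <- x[!is.na(x)]
  sqrt(mean((x - mean(x))^2))
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name,
                 format(lower), format(upper), format(x)), call. = FALSE)
  invisible(x)
}

## Format a numeric matrix/vector at 6 significant digits for deterministic
## writers (strict-writer policy).
.fmtNum <- function(x) {
  out <- formatC(x, format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}
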