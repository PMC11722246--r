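#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run `fn()` under a temporary RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

## log(sum(exp(x))) without overflow; -Inf entries are harmless.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

DNA_BASES <- c("A", "C", "G", "T")

## Watson-Crick complement of allele strings ("AG" -> "TC").
complement_alleles <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(a1, a2) complement_alleles(a1) == a2

## Spawn a reproducible stream of sub-seeds from one user seed, kept within
## 32-bit integer range.
derive_seeds <- function(seed, n) {
  with_seed(seed, function() sample.int(.Machine$integer.max - 1L, n))
}
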