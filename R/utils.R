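`%||%` <- function(a, b) if (is.null(a)) b else a

# bit population count, vectorized over integer masks (<= 30 leaves);
# 16-bit lookup table built on first use
.pc_env <- new.env(parent = emptyenv())

popcount <- function(x) {
  tab <- .pc_env$tab
  if (is.null(tab)) {
    tab <- integer(65536L)
    for (i in 0:15) {
      tab <- tab + bitwAnd(bitwShiftR(0:65535, i), 1L)
    }
    .pc_env$tab <- tab
  }
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) set.seed(seed)
  code
}
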