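# Internal bitmask representation used by the exact distance searches.
#
# All trees in one computation share a label universe (the union of their
# leafsets, sorted); leaf i maps to bit i-1. A splitset is an integer vector
# of canonical side masks: for a split with sides m and alive&~m, the smaller
# of the two integers is stored. Canonical masks of trees restricted to the
# same alive set are directly comparable, so R-F and restriction become
# vectorized integer arithmetic. Limited to 30 leaves per computation, far
# above the exponential algorithms' practical range.

fd_universe <- function(trees) {
  u <- sort(unique(unlist(lapply(trees, function(t) t$leaves))))
  if (length(u) > 30) {
    stop("exact search limited to 30 distinct labels", call. = FALSE)
  }
  u
}

fd_bits <- function(universe) {
  stats::setNames(bitwShiftL(1L, seq_along(universe) - 1L), universe)
}

fd_mask <- function(labels, bits) {
  Reduce(bitwOr, bits[labels], 0L)
}

fd_labels <- function(mask, universe) {
  universe[bitwAnd(bitwShiftR(mask, seq_along(universe) - 1L), 1L) == 1L]
}

fd_tree <- function(t, bits) {
  alive <- fd_mask(t$leaves, bits)
  splits <- vapply(t$splits, function(s) {
    m <- fd_mask(s$a, bits)
    min(m, bitwAnd(alive, bitwNot(m)))
  }, integer(1))
  list(alive = alive, splits = unname(splits))
}

# restrict a canonical splitset to a smaller alive mask; fc = non-trivial
# splits lost to degeneration, trivialization or duplication
fd_restrict <- function(splits, alive) {
  if (length(splits) == 0) {
    return(list(splits = integer(0), fc = 0L))
  }
  a <- bitwAnd(splits, alive)
  b <- bitwAnd(alive, bitwNot(splits))
  keep <- popcount(a) >= 2L & popcount(b) >= 2L
  a <- a[keep]
  b <- b[keep]
  sw <- b < a
  a[sw] <- b[sw]
  u <- unique(a)
  list(splits = u, fc = length(splits) - length(u))
}

fd_rf <- function(s1, s2) {
  sum(!s1 %in% s2) + sum(!s2 %in% s1)
}

fd_bit_list <- function(alive) {
  b <- bitwShiftL(1L, 0:30)
  b[bitwAnd(alive, b) != 0L]
}
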