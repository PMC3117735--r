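# Brute-force reference implementations, independent of the package's
# memoized searches: flat enumeration over leaf subsets / candidate splits.

all_subsets <- function(x) {
  unlist(
    lapply(0:length(x), function(k) utils::combn(x, k, simplify = FALSE)),
    recursive = FALSE
  )
}

# non-trivial splits lost when restricting t to x
oracle_fc <- function(t, x) {
  length(t$splits) - length(restrict_tree(t, x)$splits)
}

oracle_mast_distance <- function(t1, t2) {
  common <- intersect(t1$leaves, t2$leaves)
  best <- 0L
  for (x in all_subsets(common)) {
    if (length(x) <= best) next
    if (tree_equal(restrict_tree(t1, x), restrict_tree(t2, x))) {
      best <- length(x)
    }
  }
  length(union(t1$leaves, t2$leaves)) - best
}

# minimum over all kept-leafset choices of prune-then-contract scripts
oracle_edit_dist <- function(t1, t2, cost_c = 1, cost_p = 1, count_fc = TRUE) {
  cost_fc <- if (count_fc) cost_c else 0
  common <- intersect(t1$leaves, t2$leaves)
  best <- Inf
  for (x in all_subsets(common)) {
    if (length(x) == 0) next
    r1 <- restrict_tree(t1, x)
    r2 <- restrict_tree(t2, x)
    cost <- cost_p * (length(t1$leaves) - length(x) +
      length(t2$leaves) - length(x)) +
      cost_fc * (oracle_fc(t1, x) + oracle_fc(t2, x)) +
      cost_c * rf_dist(r1, r2)
    best <- min(best, cost)
  }
  best
}

oracle_p_distance <- function(t1, t2, cost_p = 1, cost_c = 1) {
  common <- intersect(t1$leaves, t2$leaves)
  best <- Inf
  for (x in all_subsets(common)) {
    if (length(x) == 0) next
    if (!tree_equal(restrict_tree(t1, x), restrict_tree(t2, x))) next
    cost <- cost_p * (length(t1$leaves) - length(x) +
      length(t2$leaves) - length(x)) +
      cost_c * (oracle_fc(t1, x) + oracle_fc(t2, x))
    best <- min(best, cost)
  }
  best
}

# frequent-subsplit mining by exhaustive restriction of observed splits
oracle_sfs <- function(trees, min_count) {
  universe <- sort(unique(unlist(lapply(trees, function(t) t$leaves))))
  cands <- list()
  for (t in trees) {
    for (s in all_splits(t)) {
      for (z in all_subsets(split_leafset(s))) {
        if (length(z) < 2) next
        r <- restrict_split(s, z)
        if (!is.null(r)) cands[[split_key(r)]] <- r
      }
    }
  }
  freq <- Filter(
    function(s) split_support(s, trees)$support_count >= min_count,
    cands
  )
  keep <- Filter(function(s) {
    !any(vapply(freq, function(o) {
      split_key(o) != split_key(s) && is_subsplit(s, o)
    }, logical(1)))
  }, freq)
  sort(unname(vapply(keep, split_key, character(1))))
}

random_tree_pair <- function(n, ...) {
  list(random_tree(n, ...), random_tree(n, ...))
}
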