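#' Robinson-Foulds distance
#'
#' The cardinality of the symmetric difference of the two trees' non-trivial
#' splitsets. Defined only for trees on the same leafset; a tree differs from
#' another by the edges present in exactly one of them.
#'
#' @param t1,t2 `leaf_tree` objects on the same leafset.
#' @return Integer count of splits.
#' @examples
#' t1 <- leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abcd|ef"))
#' t2 <- leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abce|df"))
#' rf_dist(t1, t2)
#' @export
rf_dist <- function(t1, t2) {
  if (!identical(t1$leaves, t2$leaves)) {
    stop("rf_dist() requires trees on the same leafset", call. = FALSE)
  }
  k1 <- split_keys(t1)
  k2 <- split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Maximum agreement subtree distance
#'
#' Finds a maximum-cardinality leafset `x` within the common leafset on which
#' the two restricted trees coincide (`T1|x = T2|x`), and counts the leaves of
#' the union leafset outside `x`. On free leafsets each removed leaf is
#' counted once, whether it had to leave one tree or both. The search is
#' exact: a memoized top-down leaf-removal over subsets of the common leafset,
#' practical for the desk scales this package targets (up to ~17 leaves).
#' Among equally large agreement leafsets the lexicographically smallest is
#' reported; the distance itself is tie-free.
#'
#' @param t1,t2 `leaf_tree` objects with at least one common leaf.
#' @return An object of class `mast_result`: list with `agreement_leafset`,
#'   `distance`, and `tree` (the agreement subtree).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' t3 <- leaf_tree(c("a", "b", "c", "e"), "ab|ce")
#' mast(t1, t3)$distance
#' @export
mast <- function(t1, t2) {
  common <- intersect(t1$leaves, t2$leaves)
  if (length(common) == 0) {
    stop("mast() requires a non-empty common leafset", call. = FALSE)
  }
  universe <- fd_universe(list(t1, t2))
  bits <- fd_bits(universe)
  f1 <- fd_tree(t1, bits)
  f2 <- fd_tree(t2, bits)
  memo <- new.env(parent = emptyenv())
  rec <- function(alive) {
    key <- as.character(alive)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    r1 <- fd_restrict(f1$splits, alive)$splits
    r2 <- fd_restrict(f2$splits, alive)$splits
    if (length(r1) == length(r2) && all(r1 %in% r2)) {
      res <- list(size = popcount(alive), set = alive)
    } else {
      res <- list(size = -1L, set = 0L)
      for (b in fd_bit_list(alive)) {
        cand <- rec(alive - b)
        better <- cand$size > res$size ||
          (cand$size == res$size &&
            mask_label_key(cand$set, universe) <
              mask_label_key(res$set, universe))
        if (better) res <- cand
      }
    }
    memo[[key]] <- res
    res
  }
  best <- rec(fd_mask(common, bits))
  x <- fd_labels(best$set, universe)
  structure(
    list(
      agreement_leafset = x,
      distance = length(union(t1$leaves, t2$leaves)) - length(x),
      tree = restrict_tree(t1, x)
    ),
    class = "mast_result"
  )
}

mask_label_key <- function(mask, universe) {
  paste(fd_labels(mask, universe), collapse = ",")
}

#' @export
print.mast_result <- function(x, ...) {
  cat(
    "<mast_result> distance ", x$distance, ", agreement {",
    paste(x$agreement_leafset, collapse = ","), "}\n",
    sep = ""
  )
  invisible(x)
}

#' Pruning-only unification cost (p-distance)
#'
#' The minimal cost of making two trees identical using pruning operations
#' only, charging `cost_p` per leaf removal per tree and `cost_c` per forced
#' contraction. Leaves outside the common leafset must be pruned from the tree
#' carrying them; common leaves, when pruned, leave both trees. The exact
#' search runs over agreement leafsets, mirroring [mast()] but minimizing cost
#' rather than maximizing retained leaves.
#'
#' @param t1,t2 `leaf_tree` objects with at least one common leaf.
#' @param cost_p Positive cost per pruning operation.
#' @param cost_c Positive cost per (forced) contraction.
#' @return Numeric cost.
#' @export
p_distance <- function(t1, t2, cost_p = 1, cost_c = 1) {
  check_costs(cost_c, cost_p)
  common <- intersect(t1$leaves, t2$leaves)
  if (length(common) == 0) {
    stop("p_distance() requires a non-empty common leafset", call. = FALSE)
  }
  universe <- fd_universe(list(t1, t2))
  bits <- fd_bits(universe)
  f1 <- fd_tree(t1, bits)
  f2 <- fd_tree(t2, bits)
  alive0 <- fd_mask(common, bits)
  d1 <- length(setdiff(t1$leaves, common))
  d2 <- length(setdiff(t2$leaves, common))
  p1 <- fd_restrict(f1$splits, alive0)
  p2 <- fd_restrict(f2$splits, alive0)
  phase1 <- cost_p * (d1 + d2) + cost_c * (p1$fc + p2$fc)
  memo <- new.env(parent = emptyenv())
  rec <- function(alive, s1, s2) {
    key <- as.character(alive)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    if (length(s1) == length(s2) && all(s1 %in% s2)) {
      memo[[key]] <- 0
      return(0)
    }
    best <- Inf
    for (b in fd_bit_list(alive)) {
      al2 <- alive - b
      r1 <- fd_restrict(s1, al2)
      r2 <- fd_restrict(s2, al2)
      cost <- 2 * cost_p + cost_c * (r1$fc + r2$fc) +
        rec(al2, r1$splits, r2$splits)
      if (cost < best) best <- cost
    }
    memo[[key]] <- best
    best
  }
  phase1 + rec(alive0, p1$splits, p2$splits)
}

#' Contraction-only unification cost (c-distance)
#'
#' `cost_c` times the Robinson-Foulds distance: unifying two same-leafset
#' trees by contracting every split present in exactly one of them. Undefined
#' (an error) for trees on different leafsets, where no contraction-only
#' script exists.
#'
#' @inheritParams p_distance
#' @return Numeric cost.
#' @export
c_distance <- function(t1, t2, cost_c = 1) {
  check_costs(cost_c, 1)
  if (!identical(t1$leaves, t2$leaves)) {
    stop("c_distance() is undefined for trees on different leafsets",
      call. = FALSE
    )
  }
  cost_c * rf_dist(t1, t2)
}

check_costs <- function(cost_c, cost_p) {
  if (!is.numeric(cost_c) || length(cost_c) != 1 || cost_c <= 0 ||
    !is.numeric(cost_p) || length(cost_p) != 1 || cost_p <= 0) {
    stop("operation costs must be positive scalars", call. = FALSE)
  }
  invisible(TRUE)
}
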