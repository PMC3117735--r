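#' Contraction: remove an internal edge
#'
#' Contracting a tree removes one non-trivial split (one internal edge),
#' merging the edge's endpoints. Only non-trivial splits can be contracted;
#' trivial splits are pendant edges and removing them would delete a leaf.
#'
#' @param t A `leaf_tree`.
#' @param s The split to remove: a `leaf_split` or parseable string. Must be
#'   present in `t`.
#' @return The contracted `leaf_tree` (same leafset).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' contract(t1, "abe|cd")
#' @export
contract <- function(t, s) {
  s <- as_split(s)
  if (is_trivial_split(s)) {
    stop("cannot contract a trivial split: ", split_key(s), call. = FALSE)
  }
  k <- split_key(s)
  if (!k %in% names(t$splits)) {
    stop("split not present in tree: ", k, call. = FALSE)
  }
  leaf_tree(t$leaves, t$splits[setdiff(names(t$splits), k)])
}

#' Pruning: remove a leaf, with forced-contraction accounting
#'
#' Pruning deletes a leaf and suppresses the resulting degree-2 node. On the
#' splitset this removes the leaf from every split and then discards splits
#' that degenerated (one side emptied), became trivial, or became duplicates
#' of a surviving split. Each non-trivial split lost this way is a *forced
#' contraction*: a contraction triggered as a side effect of the pruning
#' rather than chosen. The edit distance charges forced contractions at the
#' contraction cost; its NFC variant ignores them.
#'
#' @param t A `leaf_tree` with at least two leaves.
#' @param leaf A leaf label present in `t`.
#' @return An object of class `prune_result`: a list with `tree` (the pruned
#'   `leaf_tree`), `forced_contractions` (count of non-trivial splits lost),
#'   and `removed` (their keys, in post-pruning restricted form -- for a
#'   duplicated pair this is the shared restricted key).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' prune(t1, "d") # abe|cd degenerates: one forced contraction
#' @export
prune <- function(t, leaf) {
  stopifnot(is.character(leaf), length(leaf) == 1)
  if (!leaf %in% t$leaves) {
    stop("leaf not present in tree: ", leaf, call. = FALSE)
  }
  if (length(t$leaves) < 2) {
    stop("cannot prune the only leaf of a tree", call. = FALSE)
  }
  z <- setdiff(t$leaves, leaf)
  kept <- list()
  removed <- character(0)
  for (s in t$splits) {
    r <- restrict_split(s, z) # non-NULL: only one leaf was removed
    k <- split_key(r)
    if (is_trivial_split(r) || k %in% names(kept)) {
      removed <- c(removed, k)
    } else {
      kept[[k]] <- r
    }
  }
  before <- length(t$splits)
  tree <- leaf_tree(z, kept)
  fc <- before - length(tree$splits)
  stopifnot(fc == length(removed))
  structure(
    list(tree = tree, forced_contractions = fc, removed = removed),
    class = "prune_result"
  )
}

#' @export
print.prune_result <- function(x, ...) {
  cat("<prune_result> forced contractions:", x$forced_contractions, "\n")
  print(x$tree)
  invisible(x)
}

#' @rdname prune
#' @param leaves Character vector of leaves to prune in sequence. The final
#'   tree and total forced-contraction count are independent of the order.
#' @export
prune_leaves <- function(t, leaves) {
  fc <- 0L
  removed <- character(0)
  for (l in leaves) {
    pr <- prune(t, l)
    t <- pr$tree
    fc <- fc + pr$forced_contractions
    removed <- c(removed, pr$removed)
  }
  structure(
    list(tree = t, forced_contractions = fc, removed = removed),
    class = "prune_result"
  )
}

#' Restrict a tree to a leafset (induced subtree)
#'
#' The `z`-restricted tree `T|z` retains exactly the leaves in `z`; it equals
#' pruning the leaves outside `z` in any order.
#'
#' @param t A `leaf_tree`.
#' @param z Non-empty subset of the tree's leafset.
#' @return A `leaf_tree` on `z`.
#' @export
restrict_tree <- function(t, z) {
  z <- sort(unique(as.character(z)))
  if (length(z) == 0) stop("z must be non-empty", call. = FALSE)
  if (!all(z %in% t$leaves)) {
    stop("z must be a subset of the tree leafset", call. = FALSE)
  }
  kept <- list()
  for (s in t$splits) {
    r <- restrict_split(s, z)
    if (!is.null(r) && !is_trivial_split(r)) kept[[split_key(r)]] <- r
  }
  leaf_tree(z, kept)
}
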