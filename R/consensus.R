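#' Strict and majority-rule consensus
#'
#' For a profile of trees on one shared leafset, the strict consensus tree
#' carries the splits present in every tree; the majority-rule consensus tree
#' carries those present in strictly more than half of the trees (such splits
#' are automatically pairwise compatible).
#'
#' @param trees A non-empty list of `leaf_tree` objects on one leafset.
#' @return A `leaf_tree`.
#' @examples
#' t1 <- leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abcd|ef"))
#' t2 <- leaf_tree(letters[1:6], c("ab|cdef", "abc|def", "abce|df"))
#' consensus_strict(list(t1, t2))
#' @export
consensus_strict <- function(trees) {
  check_profile(trees, same_leafset = TRUE)
  keys <- Reduce(intersect, lapply(trees, split_keys))
  leaf_tree(trees[[1]]$leaves, trees[[1]]$splits[keys])
}

#' @rdname consensus_strict
#' @export
consensus_majority <- function(trees) {
  check_profile(trees, same_leafset = TRUE)
  counts <- table(unlist(lapply(trees, split_keys)))
  keys <- names(counts)[counts > length(trees) / 2]
  pool <- do.call(c, lapply(trees, function(t) t$splits))
  leaf_tree(trees[[1]]$leaves, pool[unique(keys)])
}

check_profile <- function(trees, same_leafset = FALSE) {
  if (!is.list(trees) || length(trees) < 1 ||
    !all(vapply(trees, inherits, logical(1), "leaf_tree"))) {
    stop("expected a non-empty list of leaf_tree objects", call. = FALSE)
  }
  if (same_leafset) {
    for (t in trees[-1]) {
      if (!identical(t$leaves, trees[[1]]$leaves)) {
        stop("all trees in the profile must share one leafset", call. = FALSE)
      }
    }
  }
  invisible(trees)
}

#' Tree edit consensus (PC-consensus)
#'
#' The tree edit consensus of a profile is the common tree reached by the
#' minimal-cost edit script unifying all the trees, under the same cost model
#' as [tree_edit()]. A pruning, when used, must remove the leaf from every
#' input tree; contractions only ever remove splits absent from the strict
#' consensus of the current (restricted) profile. Leaves outside the
#' intersection of all leafsets are pruned first from each tree that carries
#' them, at `cost_p` per carrying tree plus forced contractions. The
#' consensus tree is not unique in general; ties are broken exactly as in
#' [tree_edit()] (contraction-only base case first, then the smallest leaf),
#' so for two trees the score equals the edit distance and the returned tree
#' matches the pairwise unification.
#'
#' @inheritParams tree_edit
#' @param trees A non-empty list of `leaf_tree` objects whose leafsets have a
#'   non-empty intersection.
#' @return An object of class `tree_edit_consensus`: list with `score`, `tree`
#'   (the consensus `leaf_tree`), and `script` (tibble: `tree`, `op`,
#'   `target`, with one subscript per input tree).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' t2 <- leaf_tree(letters[1:5], "ab|cde")
#' tree_edit_consensus(list(t1, t2))$score
#' @export
tree_edit_consensus <- function(trees, cost_c = 1, cost_p = 1,
                                count_fc = TRUE) {
  check_profile(trees)
  check_costs(cost_c, cost_p)
  cost_fc <- if (isTRUE(count_fc)) cost_c else 0
  n <- length(trees)
  common <- Reduce(intersect, lapply(trees, function(t) t$leaves))
  if (length(common) == 0) {
    stop("profile leafsets have an empty intersection", call. = FALSE)
  }
  universe <- fd_universe(trees)
  bits <- fd_bits(universe)
  fts <- lapply(trees, fd_tree, bits = bits)
  alive0 <- fd_mask(common, bits)
  outside <- lapply(trees, function(t) setdiff(t$leaves, common))
  restr0 <- lapply(fts, function(f) fd_restrict(f$splits, alive0))
  phase1 <- cost_p * sum(lengths(outside)) +
    cost_fc * sum(vapply(restr0, `[[`, integer(1), "fc"))

  memo <- new.env(parent = emptyenv())
  rec <- function(alive, ss) {
    key <- as.character(alive)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    sc <- Reduce(intersect, ss)
    base <- cost_c * sum(lengths(ss) - length(sc))
    res <- list(cost = base, choice = 0L)
    if (base > 0 && popcount(alive) > 1L) {
      for (b in fd_bit_list(alive)) {
        al2 <- alive - b
        rs <- lapply(ss, fd_restrict, alive = al2)
        child <- rec(al2, lapply(rs, `[[`, "splits"))
        cost <- child$cost + n * cost_p +
          cost_fc * sum(vapply(rs, `[[`, integer(1), "fc"))
        if (cost < res$cost - 1e-9) res <- list(cost = cost, choice = b)
      }
    }
    memo[[key]] <- res
    res
  }
  top <- rec(alive0, lapply(restr0, `[[`, "splits"))

  pruned_common <- character(0)
  alive <- alive0
  ss <- lapply(restr0, `[[`, "splits")
  repeat {
    ch <- memo[[as.character(alive)]]$choice
    if (ch == 0L) break
    pruned_common <- c(pruned_common, fd_labels(ch, universe))
    alive <- alive - ch
    ss <- lapply(ss, function(s) fd_restrict(s, alive)$splits)
  }

  subs <- lapply(seq_len(n), function(i) {
    build_subscript(trees[[i]], c(sort(outside[[i]]), pruned_common))
  })
  finals <- lapply(subs, `[[`, "tree")
  shared <- Reduce(intersect, lapply(finals, split_keys))
  script <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::bind_rows(
      subs[[i]]$ops,
      tibble::tibble(
        op = "contract",
        target = sort(setdiff(split_keys(finals[[i]]), shared))
      )
    ) |> dplyr::mutate(tree = i)
  }))
  script <- script[, c("tree", "op", "target")]
  tree <- leaf_tree(finals[[1]]$leaves, finals[[1]]$splits[shared])

  score <- phase1 + top$cost
  check <- cost_p * sum(script$op == "prune") +
    cost_c * sum(script$op == "contract") +
    cost_fc * sum(script$op == "forced_contract")
  stopifnot(isTRUE(all.equal(check, score, tolerance = 1e-9)))

  structure(
    list(
      score = score, tree = tree, script = script,
      cost_c = cost_c, cost_p = cost_p, count_fc = isTRUE(count_fc)
    ),
    class = "tree_edit_consensus"
  )
}

#' @export
print.tree_edit_consensus <- function(x, ...) {
  cat("<tree_edit_consensus> score ", format(x$score), "\n", sep = "")
  print(x$tree)
  invisible(x)
}

#' @param x A `tree_edit_consensus` object.
#' @param ... Unused.
#' @rdname tree_edit_consensus
#' @export
tidy.tree_edit_consensus <- function(x, ...) x$script

#' @rdname tree_edit_consensus
#' @export
glance.tree_edit_consensus <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_leaves = length(x$tree$leaves),
    n_splits = length(x$tree$splits),
    cost_c = x$cost_c,
    cost_p = x$cost_p,
    count_fc = x$count_fc
  )
}
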