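#' Tree edit distance for leaf-labelled trees on free leafsets
#'
#' The edit distance between two unrooted leaf-labelled trees is the minimal
#' cost of an *edit script*: a pair of per-tree operation sequences built from
#' contractions (cost `cost_c` each) and prunings (cost `cost_p` each) that
#' transform both trees into one common tree. Forced contractions -- non-trivial
#' splits lost as a side effect of pruning -- are charged at `cost_c` when
#' `count_fc = TRUE` (the default; with this accounting the distance is a
#' metric) and are free when `count_fc = FALSE` (the NFC dissimilarity, whose
#' metric status is open).
#'
#' The search exploits two facts: the order of operations within a subscript
#' does not change the resulting tree, and no optimal script contracts a split
#' shared by both trees. Phase 1 prunes the leafset symmetric difference from
#' the respective trees. Phase 2, on a common leafset, takes the minimum of
#' the contraction-only cost (`cost_c` times the Robinson-Foulds distance) and,
#' for each remaining leaf, the cost of pruning it from both trees
#' (`2 * cost_p` plus forced contractions) and recursing; states are memoized
#' on the set of remaining leaves. Exponential in the leaf count, exact, and
#' practical to ~17 leaves. Ties are broken toward the contraction-only base
#' case, then the lexicographically smallest pruned leaf: the distance is
#' tie-free, the reported script is one optimum among possibly several.
#'
#' @param t1,t2 `leaf_tree` objects with at least one common leaf.
#' @param cost_c Positive contraction cost.
#' @param cost_p Positive pruning cost.
#' @param count_fc Charge forced contractions at `cost_c`?
#' @return `tree_edit()`: an object of class `tree_edit` with fields
#'   `distance`, `script` (a tibble with columns `tree`, `op`, `target`),
#'   `unified` (the common `leaf_tree` the optimal script reaches), and the
#'   cost model. `edit_dist()` and `nfc_dist()` return the bare numeric
#'   distance (`nfc_dist()` with forced contractions free).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' t2 <- leaf_tree(letters[1:5], "ab|cde")
#' edit_dist(t1, t2) # one contraction
#' fit <- tree_edit(t1, leaf_tree(c("a", "b", "c", "e"), "ab|ce"))
#' fit$distance # prune d + forced contraction
#' tidy(fit)
#' @export
tree_edit <- function(t1, t2, cost_c = 1, cost_p = 1, count_fc = TRUE) {
  check_costs(cost_c, cost_p)
  cost_fc <- if (isTRUE(count_fc)) cost_c else 0
  common <- intersect(t1$leaves, t2$leaves)
  if (length(common) == 0) {
    stop("tree_edit() requires a non-empty common leafset", call. = FALSE)
  }
  universe <- fd_universe(list(t1, t2))
  bits <- fd_bits(universe)
  f1 <- fd_tree(t1, bits)
  f2 <- fd_tree(t2, bits)
  alive0 <- fd_mask(common, bits)
  d1 <- setdiff(t1$leaves, common)
  d2 <- setdiff(t2$leaves, common)
  p1 <- fd_restrict(f1$splits, alive0)
  p2 <- fd_restrict(f2$splits, alive0)
  phase1 <- cost_p * (length(d1) + length(d2)) + cost_fc * (p1$fc + p2$fc)

  memo <- new.env(parent = emptyenv())
  rec <- function(alive, s1, s2) {
    key <- as.character(alive)
    hit <- memo[[key]]
    if (!is.null(hit)) {
      return(hit)
    }
    rf <- fd_rf(s1, s2)
    res <- list(cost = rf * cost_c, choice = 0L)
    if (rf > 0L && popcount(alive) > 1L) {
      for (b in fd_bit_list(alive)) { # ascending bit = ascending label
        al2 <- alive - b
        r1 <- fd_restrict(s1, al2)
        r2 <- fd_restrict(s2, al2)
        child <- rec(al2, r1$splits, r2$splits)
        cost <- child$cost + 2 * cost_p + cost_fc * (r1$fc + r2$fc)
        if (cost < res$cost - 1e-9) res <- list(cost = cost, choice = b)
      }
    }
    memo[[key]] <- res
    res
  }
  top <- rec(alive0, p1$splits, p2$splits)

  # recover the pruned common leaves along the argmin path
  pruned_common <- character(0)
  alive <- alive0
  s1 <- p1$splits
  s2 <- p2$splits
  repeat {
    ch <- memo[[as.character(alive)]]$choice
    if (ch == 0L) break
    pruned_common <- c(pruned_common, fd_labels(ch, universe))
    alive <- alive - ch
    s1 <- fd_restrict(s1, alive)$splits
    s2 <- fd_restrict(s2, alive)$splits
  }

  script1 <- build_subscript(t1, c(sort(d1), pruned_common))
  script2 <- build_subscript(t2, c(sort(d2), pruned_common))
  final1 <- script1$tree
  final2 <- script2$tree
  shared <- intersect(split_keys(final1), split_keys(final2))
  contr1 <- sort(setdiff(split_keys(final1), shared))
  contr2 <- sort(setdiff(split_keys(final2), shared))
  script <- dplyr::bind_rows(
    script1$ops |> dplyr::mutate(tree = 1L),
    tibble::tibble(tree = 1L, op = "contract", target = contr1),
    script2$ops |> dplyr::mutate(tree = 2L),
    tibble::tibble(tree = 2L, op = "contract", target = contr2)
  )
  script <- script[, c("tree", "op", "target")]
  unified <- leaf_tree(final1$leaves, final1$splits[shared])

  n_fc <- sum(script$op == "forced_contract")
  cost <- cost_p * sum(script$op == "prune") +
    cost_c * sum(script$op == "contract") + cost_fc * n_fc
  distance <- phase1 + top$cost
  stopifnot(isTRUE(all.equal(cost, distance, tolerance = 1e-9)))

  structure(
    list(
      distance = distance, script = script, unified = unified,
      cost_c = cost_c, cost_p = cost_p, count_fc = isTRUE(count_fc)
    ),
    class = "tree_edit"
  )
}

# prune leaves in order, logging prune and forced_contract operations
build_subscript <- function(t, leaves) {
  ops <- tibble::tibble(op = character(0), target = character(0))
  for (l in leaves) {
    pr <- prune(t, l)
    t <- pr$tree
    ops <- dplyr::bind_rows(
      ops,
      tibble::tibble(op = "prune", target = l),
      tibble::tibble(op = "forced_contract", target = sort(pr$removed))
    )
  }
  list(tree = t, ops = ops)
}

#' @rdname tree_edit
#' @export
edit_dist <- function(t1, t2, cost_c = 1, cost_p = 1, count_fc = TRUE) {
  tree_edit(t1, t2, cost_c, cost_p, count_fc)$distance
}

#' @rdname tree_edit
#' @export
nfc_dist <- function(t1, t2, cost_c = 1, cost_p = 1) {
  tree_edit(t1, t2, cost_c, cost_p, count_fc = FALSE)$distance
}

#' @export
print.tree_edit <- function(x, ...) {
  cat(
    "<tree_edit> distance ", format(x$distance),
    "  (cost_c=", x$cost_c, ", cost_p=", x$cost_p,
    ", forced contractions ",
    if (x$count_fc) "counted" else "free", ")\n",
    sep = ""
  )
  cat("unified tree: ", format(x$unified), "\n", sep = "")
  for (i in 1:2) {
    ops <- x$script[x$script$tree == i, ]
    cat("subscript T", i, ": ", paste0(
      ifelse(ops$op == "prune", "p",
        ifelse(ops$op == "contract", "c", "fc")
      ),
      "(", ops$target, ")",
      collapse = ", "
    ), "\n", sep = "")
  }
  invisible(x)
}

#' @param x A `tree_edit` object.
#' @param ... Unused.
#' @rdname tree_edit
#' @export
tidy.tree_edit <- function(x, ...) x$script

#' @rdname tree_edit
#' @export
glance.tree_edit <- function(x, ...) {
  tibble::tibble(
    distance = x$distance,
    n_prune = sum(x$script$op == "prune"),
    n_contract = sum(x$script$op == "contract"),
    n_forced = sum(x$script$op == "forced_contract"),
    cost_c = x$cost_c,
    cost_p = x$cost_p,
    count_fc = x$count_fc
  )
}

#' Apply an edit subscript to a tree
#'
#' Replays a sequence of operations (one tree's half of an edit script).
#' Prunings perform their forced contractions implicitly, so a later
#' `forced_contract` entry naming an already-removed split is a no-op;
#' conversely, applying the operations in any other applicable order reaches
#' the same tree. Contraction targets are matched up to restriction: a target
#' split named on a smaller leafset (the notation used in recovered scripts)
#' matches the unique current split whose restriction to the target's leafset
#' equals the target; among several equally matching duplicates the
#' lexicographically smallest is contracted (they are interchangeable).
#'
#' @param t A `leaf_tree`.
#' @param ops A tibble/data frame with columns `op`
#'   (`"prune"`, `"contract"`, `"forced_contract"`) and `target` (a leaf label
#'   or split string); e.g. one tree's rows of a [tree_edit()] script.
#' @return The resulting `leaf_tree`.
#' @export
apply_script <- function(t, ops) {
  ops <- as.data.frame(ops)
  stopifnot(all(c("op", "target") %in% names(ops)))
  pending <- character(0) # removals auto-performed by prunings
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    target <- ops$target[i]
    if (op == "prune") {
      pr <- prune(t, target)
      t <- pr$tree
      pending <- c(pending, pr$removed)
    } else if (op %in% c("contract", "forced_contract")) {
      s <- as_split(target)
      if (op == "forced_contract" && length(pending) > 0) {
        # consume a removal already realized by an earlier pruning
        hit <- which(vapply(pending, function(k) {
          p <- as_split(k)
          split_key(p) == split_key(s) || is_subsplit(s, p) || is_subsplit(p, s)
        }, logical(1)))
        if (length(hit) > 0) {
          pending <- pending[-hit[1]]
          next
        }
      }
      hits <- Filter(
        function(cur) {
          r <- restrict_split(cur, split_leafset(s))
          !is.null(r) && split_key(r) == split_key(s)
        },
        t$splits
      )
      if (length(hits) == 0) {
        if (op == "forced_contract") next # realized by an earlier pruning
        stop(
          "step ", i, ": no split of the current tree matches ",
          split_key(s),
          call. = FALSE
        )
      }
      t <- contract(t, hits[[1]]) # splits are key-sorted: smallest key
    } else {
      stop("step ", i, ": unknown operation ", sQuote(op), call. = FALSE)
    }
  }
  t
}
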