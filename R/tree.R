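#' Unrooted leaf-labelled trees as splitsets
#'
#' A `leaf_tree` is an unrooted tree in which only leaves carry labels,
#' encoded by its leafset plus the set of *non-trivial* splits (one per
#' internal edge). Trivial splits -- one per leaf -- are implied by the leafset
#' and never stored, which keeps split counting in the distance measures
#' unambiguous. The stored splits must all live on the tree's leafset, be
#' non-trivial, and be pairwise compatible; a tree with `n` leaves carries at
#' most `n - 3` non-trivial splits, with equality exactly for binary trees.
#'
#' @param leaves Character vector of distinct leaf labels (length >= 1).
#' @param splits Non-trivial splits: a list of `leaf_split` objects and/or
#'   strings parseable by [parse_split()]. Duplicates collapse.
#' @return An object of class `leaf_tree` with fields `leaves` (sorted) and
#'   `splits` (a list named by [split_key()]).
#' @examples
#' t1 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
#' t1
#' star_tree(letters[1:5])
#' @export
leaf_tree <- function(leaves, splits = list()) {
  leaves <- as.character(leaves)
  check_labels(leaves)
  if (length(leaves) < 1) stop("a tree needs at least one leaf", call. = FALSE)
  if (anyDuplicated(leaves)) {
    stop("duplicate leaf labels: ",
      paste(unique(leaves[duplicated(leaves)]), collapse = ", "),
      call. = FALSE
    )
  }
  leaves <- sort(leaves)
  if (is.character(splits)) splits <- as.list(splits)
  splits <- lapply(splits, as_split)
  keys <- vapply(splits, split_key, character(1))
  splits <- splits[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  for (s in splits) {
    if (!identical(split_leafset(s), leaves)) {
      stop("split ", split_key(s), " is not on the tree leafset", call. = FALSE)
    }
    if (is_trivial_split(s)) {
      stop("trivial split ", split_key(s),
        " must not be stored explicitly",
        call. = FALSE
      )
    }
  }
  if (length(splits) > 1) {
    for (i in seq_len(length(splits) - 1)) {
      for (j in seq(i + 1, length(splits))) {
        if (!is_compatible(splits[[i]], splits[[j]])) {
          stop("incompatible splits: ", keys[i], " and ", keys[j],
            call. = FALSE
          )
        }
      }
    }
  }
  if (length(splits) > max(0L, length(leaves) - 3L)) {
    stop("too many non-trivial splits for ", length(leaves), " leaves",
      call. = FALSE
    )
  }
  ord <- order(keys)
  structure(
    list(leaves = leaves, splits = stats::setNames(splits[ord], keys[ord])),
    class = "leaf_tree"
  )
}

#' @rdname leaf_tree
#' @export
star_tree <- function(leaves) leaf_tree(leaves)

#' @rdname leaf_tree
#' @param t A `leaf_tree`.
#' @export
n_leaves <- function(t) length(t$leaves)

#' Splits of a tree including the implied trivial ones
#'
#' Returns the full splitset of a tree: the stored non-trivial splits plus one
#' trivial split per leaf (for trees with at least two leaves). This is the
#' splitset over which subsplit support is counted.
#'
#' @param t A `leaf_tree`.
#' @return A list of `leaf_split` objects.
#' @export
all_splits <- function(t) {
  trivial <- list()
  if (length(t$leaves) >= 2) {
    trivial <- lapply(t$leaves, function(l) {
      new_split(l, setdiff(t$leaves, l))
    })
  }
  c(unname(t$splits), trivial)
}

split_keys <- function(t) names(t$splits) %||% character(0)

#' Structural equality of trees
#'
#' Two trees are equal when they share the leafset and the non-trivial
#' splitset.
#'
#' @param t1,t2 `leaf_tree` objects.
#' @return Logical scalar.
#' @export
tree_equal <- function(t1, t2) {
  identical(t1$leaves, t2$leaves) && setequal(split_keys(t1), split_keys(t2))
}

#' @export
print.leaf_tree <- function(x, ...) {
  cat(
    "<leaf_tree> ", length(x$leaves), " leaves {",
    paste(x$leaves, collapse = ","), "}, ",
    length(x$splits), " non-trivial split(s)\n",
    sep = ""
  )
  for (k in names(x$splits)) cat("  ", k, "\n", sep = "")
  invisible(x)
}

#' @export
format.leaf_tree <- function(x, ...) {
  paste0(
    "{", paste(x$leaves, collapse = ","), "}: ",
    paste(names(x$splits), collapse = "  ")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tree into its split table
#'
#' @param x A `leaf_tree`.
#' @param trivial Include the implied trivial splits?
#' @param ... Unused.
#' @return A tibble with one row per split: `split`, `side_a`, `side_b`,
#'   `trivial`.
#' @export
tidy.leaf_tree <- function(x, trivial = FALSE, ...) {
  sp <- if (trivial) all_splits(x) else unname(x$splits)
  tibble::tibble(
    split = vapply(sp, split_key, character(1)),
    side_a = vapply(sp, function(s) paste(s$a, collapse = ","), character(1)),
    side_b = vapply(sp, function(s) paste(s$b, collapse = ","), character(1)),
    trivial = vapply(sp, is_trivial_split, logical(1))
  )
}

#' Plot a tree via ape
#'
#' Converts the splitset to Newick and draws it with
#' \code{\link[ape]{plot.phylo}} as an unrooted cladogram.
#'
#' @param x A `leaf_tree`.
#' @param ... Passed to \code{\link[ape]{plot.phylo}}.
#' @export
plot.leaf_tree <- function(x, ...) {
  if (length(x$leaves) < 2) {
    stop("cannot plot a single-leaf tree", call. = FALSE)
  }
  phy <- ape::read.tree(text = tree_to_newick(x))
  ape::plot.phylo(phy, type = "unrooted", ...)
}
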