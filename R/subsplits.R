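#' Subsplit support in a profile
#'
#' The support of a split is the number of *trees* (not splits) in which it
#' occurs as a subsplit of at least one split, the tree's implied trivial
#' splits included among the candidate supersplits.
#'
#' @param s A `leaf_split` or parseable string.
#' @param trees A non-empty list of `leaf_tree` objects.
#' @return A tibble with one row: `split`, `support_count`,
#'   `support_fraction`.
#' @export
split_support <- function(s, trees) {
  check_profile(trees)
  s <- as_split(s)
  count <- sum(vapply(trees, function(t) {
    any(vapply(all_splits(t), function(x) is_subsplit(s, x), logical(1)))
  }, logical(1)))
  tibble::tibble(
    split = split_key(s),
    support_count = count,
    support_fraction = count / length(trees)
  )
}

# keep only splits with no proper supersplit in the set; dedupe by key
maximalize_splits <- function(splits) {
  keys <- vapply(splits, split_key, character(1))
  splits <- splits[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  n <- length(splits)
  if (n <= 1) {
    return(splits)
  }
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && keys[i] != keys[j] &&
        is_subsplit(splits[[i]], splits[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  splits[keep]
}

# all maximal common subsplits of every choice of one split per tree,
# folded left-to-right: for splits A|B and C|D the only maximal common
# subsplit candidates are (A&C)|(B&D) and (A&D)|(B&C)
mine_unanimous <- function(trees) {
  cands <- all_splits(trees[[1]])
  for (t in trees[-1]) {
    st <- all_splits(t)
    found <- list()
    for (cc in cands) {
      for (s in st) {
        for (sw in 1:2) {
          xa <- intersect(cc$a, if (sw == 1) s$a else s$b)
          xb <- intersect(cc$b, if (sw == 1) s$b else s$a)
          if (length(xa) > 0 && length(xb) > 0) {
            cand <- new_split(xa, xb)
            found[[split_key(cand)]] <- cand
          }
        }
      }
    }
    cands <- maximalize_splits(unname(found))
    if (length(cands) == 0) break
  }
  cands
}

#' Representative splitsets (SFS / MRFS)
#'
#' Mines the *maximal frequent subsplits* of a profile: splits that occur as a
#' subsplit in at least `minsup` trees and have no frequent proper supersplit.
#' `minsup = 1` (100%) gives the strict representative splitset (SFS);
#' `minsup = 0.5` the majority-rule representative splitset (MRFS). Trivial
#' frequent subsplits are first-class members. Candidates are generated by
#' closure under pairwise maximal common restriction, folded across the trees
#' for the unanimous case and unioned over qualifying tree subsets for
#' general `minsup`, then maximalized; subsplit support is anti-monotone, so
#' no maximal frequent subsplit escapes the closure.
#'
#' @param trees A non-empty list of `leaf_tree` objects (leafsets may
#'   differ).
#' @param minsup Minimal support: a fraction in (0, 1] (relative, "at least
#'   this share of trees") or an integer >= 2 (absolute tree count).
#' @return An object of class `representative_splitset`: list with `splits`
#'   (list of `leaf_split`), `support_count`, `support_fraction`, `minsup`,
#'   `n_trees`.
#' @export
representative_splitset <- function(trees, minsup = 1) {
  check_profile(trees)
  n <- length(trees)
  if (!is.numeric(minsup) || length(minsup) != 1 || minsup <= 0) {
    stop("minsup must be a positive scalar", call. = FALSE)
  }
  k <- if (minsup <= 1) ceiling(minsup * n) else as.integer(minsup)
  k <- max(1L, min(n, k))
  if (k == n) {
    members <- mine_unanimous(trees)
  } else {
    found <- list()
    for (idx in utils::combn(n, k, simplify = FALSE)) {
      for (s in mine_unanimous(trees[idx])) {
        found[[split_key(s)]] <- s
      }
    }
    members <- maximalize_splits(unname(found))
  }
  support <- vapply(members, function(s) {
    split_support(s, trees)$support_count
  }, integer(1))
  stopifnot(all(support >= k))
  ord <- order(vapply(members, split_key, character(1)))
  structure(
    list(
      splits = members[ord],
      support_count = support[ord],
      support_fraction = support[ord] / n,
      minsup = minsup,
      n_trees = n
    ),
    class = "representative_splitset"
  )
}

#' @export
print.representative_splitset <- function(x, ...) {
  cat(
    "<representative_splitset> minsup ", x$minsup, ", ",
    length(x$splits), " maximal frequent subsplit(s) from ",
    x$n_trees, " tree(s)\n",
    sep = ""
  )
  for (i in seq_along(x$splits)) {
    cat(
      "  ", split_key(x$splits[[i]]),
      "   # support=", x$support_count[i], "/", x$n_trees, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @param x A `representative_splitset`.
#' @param ... Unused.
#' @rdname representative_splitset
#' @export
tidy.representative_splitset <- function(x, ...) {
  tibble::tibble(
    split = vapply(x$splits, split_key, character(1)),
    leafset_size = vapply(
      x$splits, function(s) length(split_leafset(s)), integer(1)
    ),
    trivial = vapply(x$splits, is_trivial_split, logical(1)),
    support_count = x$support_count,
    support_fraction = x$support_fraction
  )
}

#' @rdname representative_splitset
#' @export
glance.representative_splitset <- function(x, ...) {
  tibble::tibble(
    n_splits = length(x$splits),
    n_trivial = sum(vapply(x$splits, is_trivial_split, logical(1))),
    n_leafsets = length(unique(vapply(
      x$splits, function(s) paste(split_leafset(s), collapse = ","),
      character(1)
    ))),
    minsup = x$minsup,
    n_trees = x$n_trees
  )
}

#' @rdname representative_splitset
#' @param object A `representative_splitset` (for `autoplot`).
#' @export
autoplot.representative_splitset <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(split, support_count),
      y = support_fraction
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "support fraction")
}

#' Visualise a representative splitset as trees
#'
#' For minsup above 50% the members restricted to any common leafset are
#' pairwise compatible, so the splitset can be drawn as one tree per distinct
#' member leafset (built from the restrictions of all members whose leafset
#' contains it) plus one tree on the intersection of those leafsets. Every
#' member reappears, in restricted form, in at least one output tree; for a
#' same-leafset profile the intersection tree refines the strict consensus.
#'
#' @param rs A `representative_splitset` mined at minsup > 0.5.
#' @return A list of `leaf_tree`, largest leafset first, the intersection
#'   leafset last.
#' @export
splitset_to_trees <- function(rs) {
  stopifnot(inherits(rs, "representative_splitset"))
  rel <- if (rs$minsup <= 1) rs$minsup else rs$minsup / rs$n_trees
  if (rel <= 0.5) {
    stop("tree visualisation requires minsup > 50%", call. = FALSE)
  }
  members <- rs$splits
  if (length(members) == 0) {
    stop("empty splitset cannot be visualised", call. = FALSE)
  }
  leafsets <- unique(lapply(members, split_leafset))
  inter <- Reduce(intersect, leafsets)
  if (length(inter) == 0) {
    stop("member leafsets have an empty intersection", call. = FALSE)
  }
  zs <- unique(c(leafsets, list(sort(inter))))
  ord <- order(-lengths(zs), vapply(zs, paste, character(1), collapse = ","))
  zs <- zs[ord]
  out <- lapply(zs, function(z) {
    kept <- list()
    for (m in members) {
      if (!all(z %in% split_leafset(m))) next
      r <- restrict_split(m, z)
      if (!is.null(r) && !is_trivial_split(r)) kept[[split_key(r)]] <- r
    }
    leaf_tree(z, kept)
  })
  for (m in members) { # every member must reappear restricted (internal check)
    ok <- any(vapply(out, function(t) {
      if (!all(t$leaves %in% split_leafset(m))) {
        return(FALSE)
      }
      r <- restrict_split(m, t$leaves)
      !is.null(r) &&
        any(vapply(
          all_splits(t), function(x) split_key(x) == split_key(r), logical(1)
        ))
    }, logical(1)))
    if (!ok) {
      stop("internal error: member ", split_key(m),
        " not represented in any output tree",
        call. = FALSE
      )
    }
  }
  out
}

#' Frequent-subsplit dissimilarity between two trees
#'
#' `1 - |SFS| / |S1 (+) S2|`, where SFS is the strict representative splitset
#' of the pair, both counts include trivial splits, and `(+)` is the modified
#' union that keeps only the supersplit of any sub/supersplit pair. Zero for
#' identical splitsets, at most one, symmetric, and defined for trees on
#' different leafsets. Not a metric; useful as a shared-structure score.
#'
#' @param t1,t2 `leaf_tree` objects.
#' @return A number in `[0, 1]`.
#' @export
fs_dissimilarity <- function(t1, t2) {
  sfs <- representative_splitset(list(t1, t2), minsup = 1)
  denom <- maximalize_splits(c(all_splits(t1), all_splits(t2)))
  1 - length(sfs$splits) / length(denom)
}
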