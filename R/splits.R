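#' Splits (bipartitions) of a leafset
#'
#' A split `A|B` is an unordered bipartition of a leafset, the canonical
#' identifier of an edge of an unrooted leaf-labelled tree: deleting the edge
#' disconnects the tree into the two leaf groups. Splits with a single leaf on
#' one side are *trivial*; they correspond to pendant edges and carry no
#' topological information. `split_bipartition()` builds a validated split from
#' two label vectors; `parse_split()` reads the compact text forms used
#' throughout the package (`"ab|cde"` for single-character labels,
#' `"t1 t2 | t3 t4"` with whitespace-separated labels otherwise).
#'
#' Splits are unordered: `split_bipartition(a, b)` and
#' `split_bipartition(b, a)` compare equal and print identically. The side
#' whose sorted, comma-joined label string is lexicographically smaller is
#' stored first, and [split_key()] returns that canonical printable form, used
#' for hashing and set operations.
#'
#' @param a,b Character vectors of leaf labels, disjoint and both non-empty.
#'   Labels must be non-empty and must not contain whitespace or any of
#'   `| ( ) , ;`.
#' @return An object of class `leaf_split`.
#' @examples
#' s <- split_bipartition(c("a", "b"), c("c", "d", "e"))
#' split_key(s)
#' parse_split("cde|ab") == s
#' @export
split_bipartition <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  check_labels(c(a, b))
  if (length(a) == 0 || length(b) == 0) {
    stop("both sides of a split must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(c(a, b))) {
    stop("split sides must be disjoint sets of distinct labels", call. = FALSE)
  }
  new_split(a, b)
}

# internal constructor: trusts disjointness, canonicalizes side order
new_split <- function(a, b) {
  a <- sort(unique(a))
  b <- sort(unique(b))
  if (paste(b, collapse = ",") < paste(a, collapse = ",")) {
    tmp <- a
    a <- b
    b <- tmp
  }
  structure(list(a = a, b = b), class = "leaf_split")
}

check_labels <- function(labels) {
  bad <- !nzchar(labels) | grepl("[[:space:]|(),;]", labels)
  if (any(bad)) {
    stop(
      "invalid leaf label(s): ",
      paste(sQuote(unique(labels[bad])), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(labels)
}

#' @rdname split_bipartition
#' @param text A single string such as `"ab|cde"`. If either side contains
#'   whitespace or commas, labels are separated by those; otherwise every
#'   character is a label.
#' @export
parse_split <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  parts <- strsplit(text, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("a split must contain exactly one '|': ", sQuote(text), call. = FALSE)
  }
  side <- function(x) {
    x <- trimws(x)
    if (grepl("[,[:space:]]", x)) {
      strsplit(x, "[,[:space:]]+")[[1]]
    } else {
      strsplit(x, "")[[1]]
    }
  }
  split_bipartition(side(parts[1]), side(parts[2]))
}

as_split <- function(x) {
  if (inherits(x, "leaf_split")) x else parse_split(x)
}

#' Canonical key of a split
#'
#' @param s A `leaf_split`.
#' @return A single string, `"a,b|c,d,e"`, identical for `A|B` and `B|A`.
#' @export
split_key <- function(s) {
  paste(paste(s$a, collapse = ","), paste(s$b, collapse = ","), sep = "|")
}

#' @rdname split_key
#' @export
split_leafset <- function(s) sort(c(s$a, s$b))

#' @rdname split_key
#' @export
is_trivial_split <- function(s) min(length(s$a), length(s$b)) == 1L

#' @export
format.leaf_split <- function(x, ...) split_key(x)

#' @export
print.leaf_split <- function(x, ...) {
  cat("<split> ", split_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.leaf_split` <- function(e1, e2) split_key(e1) == split_key(e2)

#' Restrict a split to a smaller leafset
#'
#' The `z`-restriction of `A|B` is `(A intersect z)|(B intersect z)`, the split
#' induced on the subtree retaining only the leaves in `z`. If either side
#' empties, the split leaves no trace on `z` and `NULL` is returned. The result
#' may be trivial.
#'
#' @param s A `leaf_split` (or parseable string).
#' @param z Character vector of labels.
#' @return A `leaf_split`, or `NULL` when one side has empty intersection
#'   with `z`.
#' @examples
#' restrict_split(parse_split("ab|cde"), c("a", "b", "c", "e"))
#' restrict_split(parse_split("ab|cd"), c("a", "b")) # NULL
#' @export
restrict_split <- function(s, z) {
  s <- as_split(s)
  a <- intersect(s$a, z)
  b <- intersect(s$b, z)
  if (length(a) == 0 || length(b) == 0) {
    return(NULL)
  }
  new_split(a, b)
}

#' Restricted equality and the subsplit relation
#'
#' Two splits are *restrictedly equal* on a leafset `z` when both have a
#' non-degenerate `z`-restriction and the restrictions coincide. `s1` is a
#' *subsplit* of `s2` when the leafset of `s1` is contained in that of `s2`
#' and `s2` restricted to it equals `s1`; the subsplit relation is the partial
#' order under which representative splitsets are maximalized.
#'
#' @param s1,s2 `leaf_split` objects (or parseable strings).
#' @param z Character vector of labels.
#' @return Logical scalar.
#' @examples
#' restricted_equal("abcd|efghi", "abcd|efghj", c(letters[1:8]))
#' is_subsplit("abcd|efgh", "abcd|efghi")
#' @export
restricted_equal <- function(s1, s2, z) {
  r1 <- restrict_split(as_split(s1), z)
  r2 <- restrict_split(as_split(s2), z)
  !is.null(r1) && !is.null(r2) && split_key(r1) == split_key(r2)
}

#' @rdname restricted_equal
#' @export
is_subsplit <- function(s1, s2) {
  s1 <- as_split(s1)
  s2 <- as_split(s2)
  l1 <- split_leafset(s1)
  all(l1 %in% split_leafset(s2)) && restricted_equal(s1, s2, l1)
}

#' Pairwise compatibility of splits on one leafset
#'
#' Two splits of the same leafset can coexist in one unrooted tree exactly
#' when at least one of the four pairwise side intersections is empty. Every
#' splitset stored in a [leaf_tree()] is pairwise compatible.
#'
#' @param s1,s2 `leaf_split` objects (or parseable strings) on the same
#'   leafset.
#' @return Logical scalar.
#' @export
is_compatible <- function(s1, s2) {
  s1 <- as_split(s1)
  s2 <- as_split(s2)
  if (!identical(split_leafset(s1), split_leafset(s2))) {
    stop("is_compatible() requires splits on the same leafset", call. = FALSE)
  }
  length(intersect(s1$a, s2$a)) == 0 ||
    length(intersect(s1$a, s2$b)) == 0 ||
    length(intersect(s1$b, s2$a)) == 0 ||
    length(intersect(s1$b, s2$b)) == 0
}
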