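#' Newick input and output
#'
#' `newick_to_tree()` parses one Newick string into a [leaf_tree()];
#' `tree_to_newick()` writes one back. The dialect is unrooted: branch lengths
#' and internal node labels are parsed and discarded, polytomies are allowed,
#' a rooted input is unrooted (a degree-2 root contributes no extra split),
#' and the round trip preserves the splitset. `read_newick()` /
#' `write_newick()` handle files with one tree per line.
#'
#' Parsing is delegated to \code{\link[ape]{read.tree}}; the bipartitions of
#' the resulting `phylo` object become the splitset.
#'
#' @param text A Newick string.
#' @return `newick_to_tree()`: a `leaf_tree`. `tree_to_newick()`: a string
#'   ending in `";"`. `read_newick()`: a list of `leaf_tree`.
#' @examples
#' t <- newick_to_tree("((a,b),(c,d),e);")
#' tidy(t)
#' tree_to_newick(t)
#' @export
newick_to_tree <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick string", call. = FALSE)
  if (!startsWith(text, "(")) {
    # single-leaf tree, e.g. "a;" -- below ape's radar
    lab <- sub(";$", "", text)
    lab <- sub(":[^:]*$", "", lab)
    return(leaf_tree(lab))
  }
  if (!grepl(";[[:space:]]*$", text)) text <- paste0(text, ";")
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(phy)) stop("malformed Newick: ", sQuote(text), call. = FALSE)
  as_leaf_tree(phy)
}

#' Convert an ape \code{phylo} object
#'
#' @param phy A \code{phylo} object (rooted or not; branch lengths ignored).
#' @return A `leaf_tree` with the same bipartitions.
#' @export
as_leaf_tree <- function(phy) {
  labels <- phy$tip.label
  if (anyDuplicated(labels)) {
    stop("duplicate leaf labels in Newick input", call. = FALSE)
  }
  check_labels(labels)
  if (length(labels) < 2) {
    return(leaf_tree(labels))
  }
  clades <- lapply(ape::prop.part(phy), function(i) labels[i])
  splits <- list()
  for (cl in clades) {
    if (length(cl) <= 1 || length(cl) >= length(labels) - 1) next
    s <- new_split(cl, setdiff(labels, cl))
    splits[[split_key(s)]] <- s
  }
  leaf_tree(labels, splits)
}

#' @rdname newick_to_tree
#' @param t A `leaf_tree`.
#' @export
tree_to_newick <- function(t) {
  lv <- t$leaves
  if (length(lv) == 1) {
    return(paste0(lv, ";"))
  }
  r <- lv[1]
  clades <- lapply(t$splits, function(s) if (r %in% s$a) s$b else s$a)
  emit <- function(members, inner) {
    # inner: clades that are proper subsets of members (laminar family)
    if (length(inner) == 0) {
      if (length(members) == 1) {
        return(members)
      }
      return(paste0("(", paste(sort(members), collapse = ","), ")"))
    }
    is_max <- vapply(seq_along(inner), function(i) {
      !any(vapply(seq_along(inner), function(j) {
        j != i && all(inner[[i]] %in% inner[[j]])
      }, logical(1)))
    }, logical(1))
    maxc <- inner[is_max]
    covered <- unlist(maxc)
    free <- sort(setdiff(members, covered))
    parts <- c(
      lapply(maxc, function(cl) {
        sub <- Filter(
          function(x) all(x %in% cl) && length(x) < length(cl),
          inner
        )
        emit(cl, sub)
      }),
      as.list(free)
    )
    first_label <- vapply(parts, function(p) {
      labs <- strsplit(gsub("[(),]", " ", p), "[[:space:]]+")[[1]]
      min(labs[nzchar(labs)])
    }, character(1))
    paste0("(", paste(unlist(parts)[order(first_label)], collapse = ","), ")")
  }
  body <- emit(setdiff(lv, r), unname(clades))
  inner <- sub("^\\((.*)\\)$", "\\1", body)
  if (identical(inner, body)) inner <- body # single free leaf
  paste0("(", r, ",", inner, ");")
}

#' @rdname newick_to_tree
#' @param path File path; one Newick tree per line, blank lines and `#`
#'   comment lines ignored.
#' @export
read_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, newick_to_tree)
}

#' @rdname newick_to_tree
#' @param trees A `leaf_tree` or list of them.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "leaf_tree")) trees <- list(trees)
  writeLines(vapply(trees, tree_to_newick, character(1)), path)
}

#' Split-file input and output
#'
#' A split file is a plain-text profile: one split per line with the two
#' sides separated by `" | "` and labels whitespace-separated; lines starting
#' with `#` are comments; a blank line separates consecutive trees. Trivial
#' splits may be listed (and are written) so that the leafset of a star tree
#' is recoverable; each tree's leafset is the union of the leafsets of its
#' listed splits.
#'
#' @param path File path.
#' @return `read_split_file()`: a list of `leaf_tree`.
#' @export
read_split_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[!startsWith(lines, "#")]
  blocks <- split(lines, cumsum(!nzchar(lines)))
  trees <- list()
  for (b in blocks) {
    b <- b[nzchar(b)]
    if (length(b) == 0) next
    b <- sub("#.*$", "", b) # trailing annotations, e.g. support
    splits <- lapply(trimws(b), parse_split)
    leaves <- sort(unique(unlist(lapply(splits, split_leafset))))
    nontrivial <- Filter(Negate(is_trivial_split), splits)
    for (s in nontrivial) {
      if (!identical(split_leafset(s), leaves)) {
        stop(
          "split ", split_key(s),
          " is not on the tree leafset {", paste(leaves, collapse = ","), "}",
          call. = FALSE
        )
      }
    }
    trees[[length(trees) + 1]] <- leaf_tree(leaves, nontrivial)
  }
  trees
}

#' @rdname read_split_file
#' @param trees A `leaf_tree` or list of them.
#' @export
write_split_file <- function(trees, path) {
  if (inherits(trees, "leaf_tree")) trees <- list(trees)
  out <- character(0)
  for (t in trees) {
    lines <- vapply(all_splits(t), function(s) {
      paste(paste(s$a, collapse = " "), paste(s$b, collapse = " "), sep = " | ")
    }, character(1))
    out <- c(out, lines, "")
  }
  writeLines(out[-length(out)], path)
}

#' Read trees, auto-detecting the format
#'
#' Files whose first non-comment character is `(` are read as Newick
#' (one tree per line), anything else as a split file.
#'
#' @param path File path.
#' @return A list of `leaf_tree`.
#' @export
read_trees <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no trees in ", path, call. = FALSE)
  if (startsWith(lines[1], "(")) read_newick(path) else read_split_file(path)
}
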