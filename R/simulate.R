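default_labels <- function(n) {
  if (n <= 26) letters[seq_len(n)] else sprintf("t%03d", seq_len(n))
}

#' Random unrooted leaf-labelled trees
#'
#' Binary trees are drawn uniformly over labelled unrooted binary topologies
#' by sequential uniform edge attachment: starting from the three-leaf star,
#' each further leaf subdivides an edge chosen uniformly at random.
#' "Unconstrained" trees are binary trees whose internal edges are then each
#' contracted independently with probability `contraction_prob`, giving
#' polytomies. Draws are deterministic per seed.
#'
#' @param n_leaves Number of leaves (>= 1; non-trivial topology from 4).
#' @param model `"binary"` or `"unconstrained"`.
#' @param labels Leaf labels (default `letters`-based, length `n_leaves`).
#' @param contraction_prob Per-edge contraction probability in `[0, 1)`,
#'   unconstrained model only.
#' @param seed Optional integer seed (`set.seed()` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @return A `leaf_tree`; binary trees have exactly `n_leaves - 3`
#'   non-trivial splits.
#' @examples
#' random_tree(8, seed = 1)
#' @export
random_tree <- function(n_leaves, model = c("binary", "unconstrained"),
                        labels = NULL, contraction_prob = 0.25, seed = NULL) {
  model <- match.arg(model)
  labels <- labels %||% default_labels(n_leaves)
  stopifnot(length(labels) == n_leaves, n_leaves >= 1)
  if (!is.numeric(contraction_prob) || contraction_prob < 0 ||
    contraction_prob >= 1) {
    stop("contraction_prob must lie in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    t <- random_binary_tree(labels)
    if (model == "unconstrained" && length(t$splits) > 0) {
      drop <- stats::runif(length(t$splits)) < contraction_prob
      t <- leaf_tree(t$leaves, t$splits[!drop])
    }
    t
  })
}

random_binary_tree <- function(labels) {
  n <- length(labels)
  if (n <= 3) {
    return(leaf_tree(labels))
  }
  # nodes: 1..n tips, n+1.. internal; start with the 3-leaf star
  edges <- rbind(c(n + 1L, 1L), c(n + 1L, 2L), c(n + 1L, 3L))
  nxt <- n + 2L
  for (tip in seq(4L, n)) {
    j <- sample.int(nrow(edges), 1L)
    a <- edges[j, 1]
    b <- edges[j, 2]
    edges <- rbind(
      edges[-j, , drop = FALSE],
      c(a, nxt), c(nxt, b), c(nxt, tip)
    )
    nxt <- nxt + 1L
  }
  graph_to_tree(edges, labels, n)
}

# splits from an explicit edge list: tips 1..n carry labels
graph_to_tree <- function(edges, labels, n) {
  adj <- vector("list", max(edges))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  side_tips <- function(from, avoid) {
    seen <- integer(0)
    stack <- from
    visited <- rep(FALSE, length(adj))
    visited[avoid] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[v]) next
      visited[v] <- TRUE
      if (v <= n) seen <- c(seen, v)
      stack <- c(stack, adj[[v]])
    }
    seen
  }
  splits <- list()
  internal <- edges[edges[, 1] > n & edges[, 2] > n, , drop = FALSE]
  for (i in seq_len(nrow(internal))) {
    a <- internal[i, 1]
    b <- internal[i, 2]
    tips <- side_tips(a, b)
    if (length(tips) >= 2 && length(tips) <= n - 2) {
      s <- new_split(labels[tips], labels[setdiff(seq_len(n), tips)])
      splits[[split_key(s)]] <- s
    }
  }
  leaf_tree(labels, splits)
}

#' Tree mutations
#'
#' Applies `k` mutation steps of one kind, the elementary changes used to
#' study distance dynamics:
#' * `contraction` removes `k` distinct uniformly chosen non-trivial splits;
#' * `pruning` prunes `k` uniformly chosen leaves (the tree must keep at
#'   least 4 leaves, i.e. start with at least `k + 4`);
#' * `nnbi` (nearest non-brother interchange) performs `k` label swaps, each
#'   between a uniformly chosen pair of non-sibling leaves at minimal
#'   topological distance among non-sibling pairs. An NNBI step can be undone
#'   by one contraction or one pruning in each tree when the swapped cousins
#'   sit three edges apart, so it probes both operation types at once while
#'   preserving the leafset.
#'
#' @param t A `leaf_tree`.
#' @param kind `"contraction"`, `"pruning"` or `"nnbi"`.
#' @param k Number of mutation steps (`k = 0` returns the tree unchanged).
#' @param seed Optional integer seed.
#' @return The mutated `leaf_tree`.
#' @export
mutate_tree <- function(t, kind = c("contraction", "pruning", "nnbi"),
                        k = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  if (k == 0) {
    return(t)
  }
  with_seed(seed, {
    if (kind == "contraction") {
      if (length(t$splits) < k) {
        stop("not enough non-trivial splits to contract", call. = FALSE)
      }
      drop <- sample(names(t$splits), k)
      leaf_tree(t$leaves, t$splits[setdiff(names(t$splits), drop)])
    } else if (kind == "pruning") {
      if (length(t$leaves) < k + 4) {
        stop("pruning mutation requires at least k + 4 leaves", call. = FALSE)
      }
      for (i in seq_len(k)) {
        t <- prune(t, sample(t$leaves, 1))$tree
      }
      t
    } else {
      for (i in seq_len(k)) t <- nnbi_step(t)
      t
    }
  })
}

nnbi_step <- function(t) {
  if (length(t$leaves) < 4) {
    stop("nnbi requires at least 4 leaves", call. = FALSE)
  }
  phy <- ape::read.tree(text = tree_to_newick(t))
  phy$edge.length <- rep(1, nrow(phy$edge))
  dm <- stats::cophenetic(phy) # leaf-to-leaf edge counts
  dm <- dm[t$leaves, t$leaves, drop = FALSE]
  dm[upper.tri(dm, diag = TRUE)] <- NA
  dm[dm <= 2] <- NA # siblings share a neighbour node
  if (all(is.na(dm))) {
    stop("no non-sibling leaf pair available (star tree)", call. = FALSE)
  }
  idx <- which(dm == min(dm, na.rm = TRUE), arr.ind = TRUE)
  pick <- idx[sample.int(nrow(idx), 1L), ]
  swap_labels(t, rownames(dm)[pick[1]], colnames(dm)[pick[2]])
}

swap_labels <- function(t, x, y) {
  sw <- function(v) {
    v[v == x] <- ".tmp."
    v[v == y] <- x
    v[v == ".tmp."] <- y
    v
  }
  leaf_tree(t$leaves, lapply(t$splits, function(s) new_split(sw(s$a), sw(s$b))))
}

measure_catalog <- function(spec, cost_c = 1, cost_p = 1) {
  spec0 <- trimws(spec)
  m <- regmatches(
    spec0,
    regexec("^(E|NFC)\\(([0-9.]+),[[:space:]]*([0-9.]+)\\)$", spec0)
  )[[1]]
  if (length(m) == 4) {
    cc <- as.numeric(m[3])
    cp <- as.numeric(m[4])
    fc <- m[2] == "E"
    return(list(
      label = spec0,
      fn = function(t1, t2) edit_dist(t1, t2, cc, cp, count_fc = fc)
    ))
  }
  fn <- switch(tolower(spec0),
    rf = function(t1, t2) {
      if (identical(t1$leaves, t2$leaves)) {
        rf_dist(t1, t2)
      } else {
        # undefined on free leafsets: record the maximum possible value
        length(t1$splits) + length(t2$splits)
      }
    },
    mast = function(t1, t2) mast(t1, t2)$distance,
    edit = function(t1, t2) edit_dist(t1, t2, cost_c, cost_p),
    nfc = function(t1, t2) nfc_dist(t1, t2, cost_c, cost_p),
    fs = fs_dissimilarity,
    pdist = function(t1, t2) p_distance(t1, t2, cost_p, cost_c),
    cdist = function(t1, t2) c_distance(t1, t2, cost_c),
    stop("unknown measure: ", sQuote(spec0), call. = FALSE)
  )
  list(label = spec0, fn = fn)
}

safe_measure <- function(fn, t1, t2) {
  tryCatch(fn(t1, t2), error = function(e) NA_real_)
}

#' Distance distribution experiment
#'
#' Generates `n_pairs` independent random tree pairs under one model and
#' evaluates each measure on the identical pair stream, to compare the shapes
#' and discriminative power of the distance distributions. Measures are named
#' `"rf"`, `"mast"`, `"fs"`, `"pdist"`, `"cdist"`, or parametrized edit
#' distances `"E(c,p)"` / `"NFC(c,p)"` (contraction cost first). On pairs
#' with different leafsets R-F records the maximum possible value
#' `|S1| + |S2|`; measures undefined on a pair (empty common leafset) record
#' `NA`.
#'
#' @param n_pairs Number of tree pairs.
#' @param n_leaves Leaves per tree (the maximum, under `free_leafset`).
#' @param measures Character vector of measure specifications.
#' @param model Tree model, see [random_tree()].
#' @param free_leafset Draw each tree's leaf count uniformly from
#'   `4:n_leaves` and its labels from `label_universe`?
#' @param label_universe Labels sampled under `free_leafset` (default: the
#'   `n_leaves` default labels).
#' @param contraction_prob See [random_tree()].
#' @param seed Optional integer seed.
#' @return A tibble of class `dist_distribution` with columns `pair`,
#'   `measure`, `value`; `tidy()` tabulates it into a histogram
#'   (`measure`, `value`, `count`), `glance()` summarises discriminative
#'   power per measure, `autoplot()` draws the histograms.
#' @examples
#' d <- distance_distribution(20, 8, c("rf", "mast", "E(3,1)"), seed = 1)
#' glance(d)
#' @export
distance_distribution <- function(n_pairs, n_leaves = 8,
                                  measures = c("rf", "mast", "E(1,1)"),
                                  model = "binary", free_leafset = FALSE,
                                  label_universe = NULL,
                                  contraction_prob = 0.25, seed = NULL) {
  stopifnot(n_pairs >= 0)
  ms <- lapply(measures, measure_catalog)
  label_universe <- label_universe %||% default_labels(n_leaves)
  gen <- function() {
    if (free_leafset) {
      k <- sample(4:n_leaves, 1)
      random_tree(k,
        model = model, labels = sort(sample(label_universe, k)),
        contraction_prob = contraction_prob
      )
    } else {
      random_tree(n_leaves, model = model, contraction_prob = contraction_prob)
    }
  }
  rows <- with_seed(seed, purrr::map(seq_len(n_pairs), function(p) {
    t1 <- gen()
    t2 <- gen()
    tibble::tibble(
      pair = p,
      measure = vapply(ms, `[[`, character(1), "label"),
      value = vapply(ms, function(m) {
        as.numeric(safe_measure(m$fn, t1, t2))
      }, numeric(1))
    )
  }))
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      pair = integer(0), measure = character(0), value = numeric(0)
    )
  }
  structure(out,
    class = c("dist_distribution", class(out)),
    seed = seed, n_pairs = n_pairs
  )
}

#' @rdname distance_distribution
#' @param x A `dist_distribution`.
#' @param ... Unused.
#' @export
tidy.dist_distribution <- function(x, ...) {
  dplyr::count(
    tibble::as_tibble(x)[!is.na(x$value), ],
    measure, value,
    name = "count"
  )
}

#' @rdname distance_distribution
#' @export
glance.dist_distribution <- function(x, ...) {
  d <- tibble::as_tibble(x)[!is.na(x$value), ]
  dplyr::summarise(
    dplyr::group_by(d, measure),
    n = dplyr::n(),
    n_unique = dplyr::n_distinct(value),
    mean = mean(value),
    sd = stats::sd(value),
    .groups = "drop"
  )
}

#' @rdname distance_distribution
#' @param object A `dist_distribution`.
#' @export
autoplot.dist_distribution <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d, ggplot2::aes(x = value, y = count)
  ) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = "distance value", y = "pairs")
}

#' Distance dynamics experiment
#'
#' For each repetition a base tree is generated and compared against its
#' `k`-step mutants, `k = 0..k_max`, under each measure; the mean distance as
#' a function of `k` shows how each measure scales with the number and type
#' of changes. With unit costs the edit distance under contraction mutations
#' equals `k` exactly, and the MAST distance under pruning mutations equals
#' `k` exactly.
#'
#' @inheritParams distance_distribution
#' @param mutation Mutation kind, see [mutate_tree()].
#' @param k_max Largest mutation count.
#' @param n_reps Repetitions per `k`.
#' @return A tibble of class `dist_dynamics` with columns `rep`, `k`,
#'   `measure`, `value`; `tidy()` averages over repetitions, `autoplot()`
#'   draws mean distance against `k`.
#' @examples
#' d <- distance_dynamics("contraction", 3, 5, measures = "E(1,1)", seed = 1)
#' tidy(d)
#' @export
distance_dynamics <- function(mutation, k_max, n_reps, n_leaves = 8,
                              measures = c("rf", "mast", "E(1,1)"),
                              model = "binary", contraction_prob = 0.25,
                              seed = NULL) {
  ms <- lapply(measures, measure_catalog)
  rows <- with_seed(seed, purrr::map(seq_len(n_reps), function(r) {
    base <- random_tree(
      n_leaves,
      model = model, contraction_prob = contraction_prob
    )
    dplyr::bind_rows(lapply(0:k_max, function(k) {
      mut <- mutate_tree(base, mutation, k)
      tibble::tibble(
        rep = r, k = k,
        measure = vapply(ms, `[[`, character(1), "label"),
        value = vapply(ms, function(m) {
          as.numeric(safe_measure(m$fn, base, mut))
        }, numeric(1))
      )
    }))
  }))
  out <- dplyr::bind_rows(rows)
  structure(out,
    class = c("dist_dynamics", class(out)),
    seed = seed, mutation = mutation
  )
}

#' @rdname distance_dynamics
#' @param x A `dist_dynamics`.
#' @param ... Unused.
#' @export
tidy.dist_dynamics <- function(x, ...) {
  d <- tibble::as_tibble(x)[!is.na(x$value), ]
  dplyr::summarise(
    dplyr::group_by(d, measure, k),
    mean_value = mean(value),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
}

#' @rdname distance_dynamics
#' @param object A `dist_dynamics`.
#' @export
autoplot.dist_dynamics <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = k, y = mean_value, colour = measure, group = measure
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mutations k", y = "mean distance", colour = "measure")
}
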