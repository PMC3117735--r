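test_that("subsplit support counts trees, not splits", {
  prof <- list(fig6_t1(), fig6_t2())
  s <- split_support("abcd|efgh", prof)
  expect_identical(s$support_count, 2L)
  expect_identical(s$support_fraction, 1)
  expect_identical(split_support("xy|zw", prof)$support_count, 0L)
  # any split of a member tree is supported at least once
  expect_gte(split_support("cd|abefghi", prof)$support_count, 1L)
  # trivial subsplits are minable via implied trivial supersplits
  expect_identical(split_support("h|abcdefg", prof)$support_count, 2L)
})

test_that("the strict representative splitset of the 9-leaf pair is exact", {
  rs <- representative_splitset(list(fig6_t1(), fig6_t2()), minsup = 1)
  expected <- c(
    "abcd|efgh", "gh|abcdef", "fgh|abcde", "bc|aefgh", "h|abcdefg",
    "a|bcdefgh", "b|acdefgh", "c|abdefgh", "d|abcefgh", "e|abcdfgh",
    "f|abcdegh", "g|abcdefh"
  )
  expect_setequal(
    vapply(rs$splits, split_key, character(1)),
    vapply(expected, skey, character(1))
  )
  expect_true(all(rs$support_count == 2L))
  expect_true(all(rs$support_fraction == 1))
  td <- tidy(rs)
  expect_identical(nrow(td), 12L)
  expect_identical(sum(td$trivial), 8L)
})

test_that("representative splitsets handle degenerate profiles", {
  t <- fig1_t1()
  single <- representative_splitset(list(t), minsup = 1)
  expect_setequal(
    vapply(single$splits, split_key, character(1)),
    vapply(all_splits(t), split_key, character(1))
  )
  with_star <- representative_splitset(
    list(t, star_tree(t$leaves)),
    minsup = 1
  )
  expect_true(all(vapply(with_star$splits, is_trivial_split, logical(1))))
  expect_identical(length(with_star$splits), 5L)
})

test_that("mining equals the brute-force restriction oracle", {
  set.seed(71)
  for (i in 1:4) {
    prof <- lapply(1:3, function(j) {
      kk <- sample(5:6, 1)
      random_tree(
        kk,
        model = "unconstrained",
        labels = sort(sample(letters[1:7], kk))
      )
    })
    for (minsup in c(1, 0.5)) {
      rs <- representative_splitset(prof, minsup)
      expect_identical(
        sort(vapply(rs$splits, split_key, character(1))),
        oracle_sfs(prof, ceiling(minsup * length(prof)))
      )
    }
  }
})

test_that("members are maximal: every one-leaf extension is infrequent", {
  prof <- list(fig6_t1(), fig6_t2())
  rs <- representative_splitset(prof, minsup = 1)
  universe <- sort(unique(unlist(lapply(prof, function(t) t$leaves))))
  for (s in rs$splits) {
    for (l in setdiff(universe, split_leafset(s))) {
      for (side in 1:2) {
        ext <- if (side == 1) {
          split_bipartition(c(s$a, l), s$b)
        } else {
          split_bipartition(s$a, c(s$b, l))
        }
        expect_lt(split_support(ext, prof)$support_count, 2L)
      }
    }
  }
})

test_that("splitset visualisation yields one tree per leafset plus intersection", {
  rs <- representative_splitset(list(fig6_t1(), fig6_t2()), minsup = 1)
  trees <- splitset_to_trees(rs)
  expect_length(trees, 2)
  expect_identical(trees[[1]]$leaves, letters[1:8])
  expect_identical(trees[[2]]$leaves, c("a", "b", "c", "e", "f", "g", "h"))
  expect_same_splits(trees[[1]], c("abcd|efgh", "gh|abcdef", "fgh|abcde"))
  expect_same_splits(
    trees[[2]],
    c("abc|efgh", "gh|abcef", "fgh|abce", "bc|aefgh")
  )

  single <- representative_splitset(list(fig1_t1()), minsup = 1)
  out <- splitset_to_trees(single)
  expect_length(out, 1)
  expect_true(tree_equal(out[[1]], fig1_t1()))

  expect_error(
    splitset_to_trees(representative_splitset(
      list(fig4_t1(), fig4_t2(), fig12_t1()),
      minsup = 0.4
    )),
    "minsup"
  )
})

test_that("the intersection tree refines the strict consensus (same leafset)", {
  p <- list(fig4_t1(), fig4_t2())
  rs <- representative_splitset(p, minsup = 1)
  trees <- splitset_to_trees(rs)
  inter <- trees[[length(trees)]]
  sc <- consensus_strict(p)
  r <- restrict_tree(inter, sc$leaves)
  expect_true(all(names(sc$splits) %in% names(r$splits)))
})

test_that("fs dissimilarity matches the derived worked value and its bounds", {
  expect_equal(fs_dissimilarity(fig6_t1(), fig6_t2()), 0.6)
  expect_equal(fs_dissimilarity(fig1_t1(), fig1_t1()), 0)
  # sharing a non-trivial subsplit scores strictly lower than sharing none,
  # other things equal
  t1 <- leaf_tree(letters[1:5], c("ab|cde", "abc|de"))
  t2 <- leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))
  t3 <- leaf_tree(letters[1:5], c("ac|bde", "acd|be"))
  expect_identical(rf_dist(t1, t3), rf_dist(t2, t3))
  expect_lt(fs_dissimilarity(t1, t2), fs_dissimilarity(t2, t3))
  set.seed(73)
  for (i in 1:6) {
    a <- random_tree(sample(5:7, 1), model = "unconstrained")
    kb <- sample(5:7, 1)
    b <- random_tree(
      kb,
      model = "unconstrained",
      labels = sample(letters[1:8], kb)
    )
    d <- fs_dissimilarity(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, fs_dissimilarity(b, a)) # symmetric
    expect_equal(fs_dissimilarity(a, a), 0)
  }
})
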