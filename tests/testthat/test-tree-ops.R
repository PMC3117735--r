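test_that("leaf_tree enforces its invariants", {
  expect_error(leaf_tree(c("a", "a", "b")), "duplicate")
  expect_error(leaf_tree(letters[1:4], "ab|c(d"), "invalid leaf label")
  expect_error(leaf_tree(letters[1:5], "ab|cd"), "not on the tree leafset")
  expect_error(leaf_tree(letters[1:5], "a|bcde"), "trivial")
  expect_error(
    leaf_tree(letters[1:6], c("ab|cdef", "ac|bdef")),
    "incompatible"
  )
  # a binary tree carries exactly n - 3 non-trivial splits
  expect_length(leaf_tree(letters[1:5], c("ab|cde", "abe|cd"))$splits, 2)
  expect_length(star_tree(letters[1:7])$splits, 0)
  expect_length(all_splits(star_tree(letters[1:4])), 4) # trivial only
  expect_length(all_splits(leaf_tree("a")), 0)
})

test_that("contraction removes exactly the chosen internal edge", {
  t2 <- contract(fig1_t1(), "abe|cd")
  expect_true(tree_equal(t2, fig1_t2()))
  expect_error(contract(t2, "abe|cd"), "not present")
  expect_error(contract(t2, "a|bcde"), "trivial")
  expect_error(contract(star_tree(letters[1:5]), "ab|cde"), "not present")
  # contracting everything yields the star
  t <- fig12_t1()
  for (k in names(t$splits)) t <- contract(t, k)
  expect_true(tree_equal(t, star_tree(letters[1:8])))
})

test_that("pruning drops degenerate splits and counts forced contractions", {
  pr <- prune(fig1_t1(), "d")
  expect_true(tree_equal(pr$tree, fig2_t3()))
  expect_identical(pr$forced_contractions, 1L)
  expect_identical(pr$removed, skey("abe|c")) # post-pruning name

  pr12 <- prune(fig12_t1(), "d")
  expect_same_splits(
    pr12$tree,
    c("gh|abcef", "fgh|abce", "efgh|abc", "aefgh|bc")
  )
  expect_identical(pr12$forced_contractions, 1L)

  star <- star_tree(letters[1:5])
  prs <- prune(star, "c")
  expect_true(tree_equal(prs$tree, star_tree(c("a", "b", "d", "e"))))
  expect_identical(prs$forced_contractions, 0L)

  expect_error(prune(fig1_t1(), "z"), "not present")
  expect_error(prune(leaf_tree("a"), "a"), "only leaf")
})

test_that("forced contractions equal the drop in non-trivial split count", {
  set.seed(11)
  for (i in 1:20) {
    t <- random_tree(sample(5:9, 1), model = "unconstrained")
    leaf <- sample(t$leaves, 1)
    pr <- prune(t, leaf)
    expect_identical(
      pr$forced_contractions,
      length(t$splits) - length(pr$tree$splits)
    )
  }
})

test_that("restriction equals iterated pruning in every order", {
  t <- fig12_t1()
  z <- c("a", "b", "c", "e", "f", "h")
  direct <- restrict_tree(t, z)
  expect_same_splits(direct, c("fh|abce", "efh|abc", "aefh|bc"))
  drop <- setdiff(t$leaves, z)
  for (ord in list(drop, rev(drop))) {
    expect_true(tree_equal(prune_leaves(t, ord)$tree, direct))
  }
  # exhaustive over orders for up to 3 dropped leaves, random trees
  set.seed(23)
  for (i in 1:10) {
    t <- random_tree(7, model = "unconstrained")
    drop <- sample(t$leaves, 3)
    keep <- setdiff(t$leaves, drop)
    target <- restrict_tree(t, keep)
    perms <- list(
      drop, drop[c(1, 3, 2)], drop[c(2, 1, 3)],
      drop[c(2, 3, 1)], drop[c(3, 1, 2)], drop[c(3, 2, 1)]
    )
    for (p in perms) {
      res <- prune_leaves(t, p)
      expect_true(tree_equal(res$tree, target))
      expect_identical(
        res$forced_contractions,
        length(t$splits) - length(target$splits)
      )
    }
  }
  expect_true(tree_equal(restrict_tree(t, t$leaves), t))
  expect_length(restrict_tree(fig12_t1(), c("a", "d", "g"))$splits, 0)
  expect_error(restrict_tree(fig1_t1(), character(0)), "non-empty")
  expect_error(restrict_tree(fig1_t1(), c("a", "z")), "subset")
})

test_that("edit subscripts reach the same tree in any shuffled order", {
  # the order of operations within a subscript does not affect the result;
  # recorded scripts carry their forced contractions explicitly
  set.seed(31)
  for (i in 1:20) {
    t1 <- random_tree(sample(6:8, 1), model = "unconstrained")
    t2 <- random_tree(
      length(t1$leaves),
      model = "unconstrained", labels = t1$leaves
    )
    fit <- tree_edit(t1, t2, cost_c = 1, cost_p = 1)
    ops <- fit$script[fit$script$tree == 1, ]
    if (nrow(ops) < 2) next
    reference <- apply_script(t1, ops)
    expect_true(tree_equal(reference, fit$unified))
    for (j in 1:3) {
      shuffled <- ops[sample(nrow(ops)), ]
      expect_true(tree_equal(apply_script(t1, shuffled), reference))
    }
  }
})
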