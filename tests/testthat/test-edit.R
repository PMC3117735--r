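test_that("edit distance reproduces the worked examples", {
  expect_equal(edit_dist(fig1_t1(), fig1_t2()), 1)
  expect_equal(edit_dist(fig1_t1(), fig2_t3()), 2)
  expect_equal(edit_dist(fig1_t2(), fig2_t3()), 1)
  expect_equal(edit_dist(fig12_t1(), fig12_t2()), 6)
  expect_equal(edit_dist(fig12_t1(), fig12_t2(), cost_c = 1, cost_p = 2), 8)
  # raising the pruning cost to 3 leaves contraction-only optimal
  expect_equal(edit_dist(fig12_t1(), fig12_t2(), cost_c = 1, cost_p = 3), 10)
  expect_error(
    edit_dist(leaf_tree(c("a", "b")), leaf_tree(c("c", "d"))),
    "common leafset"
  )
})

test_that("the recovered script is valid, minimal-cost and reaches the unified tree", {
  fit <- tree_edit(fig12_t1(), fig12_t2())
  expect_equal(fit$distance, 6)
  expect_same_splits(fit$unified, c("fgh|abce", "efgh|abc", "aefgh|bc"))
  ops1 <- fit$script[fit$script$tree == 1, ]
  ops2 <- fit$script[fit$script$tree == 2, ]
  expect_true(tree_equal(apply_script(fig12_t1(), ops1), fit$unified))
  expect_true(tree_equal(apply_script(fig12_t2(), ops2), fit$unified))
  # one pruning, one forced contraction, one contraction per subscript
  expect_identical(
    sort(ops1$op), c("contract", "forced_contract", "prune")
  )
  expect_identical(ops1$target[ops1$op == "prune"], "d")
  g <- glance(fit)
  expect_identical(g$n_prune, 2L)
  expect_identical(g$n_forced, 2L)
  expect_identical(g$n_contract, 2L)
})

test_that("apply_script matches the documented worked subscript", {
  ops <- tibble::tibble(
    op = c("prune", "forced_contract", "contract"),
    target = c("d", "c|abefgh", "gh|abcef")
  )
  res <- apply_script(fig12_t1(), ops)
  expect_same_splits(res, c("fgh|abce", "efgh|abc", "aefgh|bc"))
  # any applicable permutation reaches the same tree
  for (perm in list(c(2, 1, 3), c(1, 3, 2), c(3, 1, 2), c(2, 3, 1))) {
    expect_true(tree_equal(apply_script(fig12_t1(), ops[perm, ]), res))
  }
  # empty script is the identity
  expect_true(tree_equal(
    apply_script(fig12_t1(), ops[0, ]),
    fig12_t1()
  ))
  expect_error(
    apply_script(fig12_t1(), tibble::tibble(op = "contract", target = "ac|bd")),
    "no split"
  )
})

test_that("NFC variant ignores forced contractions", {
  expect_equal(nfc_dist(fig12_t1(), fig12_t2()), 4)
  expect_equal(nfc_dist(fig1_t1(), fig2_t3()), 1)
  expect_equal(nfc_dist(fig12_t1(), fig12_t1(), 3, 2), 0)
  set.seed(5)
  for (i in 1:6) {
    pair <- random_tree_pair(6, model = "unconstrained")
    expect_equal(
      nfc_dist(pair[[1]], pair[[2]]),
      oracle_edit_dist(pair[[1]], pair[[2]], count_fc = FALSE)
    )
    expect_lte(
      nfc_dist(pair[[1]], pair[[2]]),
      edit_dist(pair[[1]], pair[[2]]) + 1e-12
    )
  }
})

test_that("edit distance equals the brute-force prune-subset oracle", {
  set.seed(47)
  for (i in 1:10) {
    t1 <- random_tree(sample(5:7, 1), model = "unconstrained")
    k2 <- sample(5:7, 1)
    t2 <- random_tree(k2,
      model = "unconstrained",
      labels = sample(letters[1:8], k2)
    )
    if (length(intersect(t1$leaves, t2$leaves)) == 0) next
    for (costs in list(c(1, 1), c(1, 2), c(3, 1), c(2.5, 1.5))) {
      expect_equal(
        edit_dist(t1, t2, costs[1], costs[2]),
        oracle_edit_dist(t1, t2, costs[1], costs[2])
      )
    }
  }
})

test_that("edit distance satisfies the metric axioms on random triples", {
  set.seed(53)
  for (i in 1:40) {
    n <- sample(5:7, 1)
    ts <- lapply(1:3, function(j) random_tree(n, model = "unconstrained"))
    d12 <- edit_dist(ts[[1]], ts[[2]])
    d23 <- edit_dist(ts[[2]], ts[[3]])
    d13 <- edit_dist(ts[[1]], ts[[3]])
    expect_equal(d12, edit_dist(ts[[2]], ts[[1]])) # symmetry
    expect_gte(d12 + d23 - d13, -1e-9) # triangle
    expect_equal(edit_dist(ts[[1]], ts[[1]]), 0) # identity
    if (!tree_equal(ts[[1]], ts[[2]])) expect_gt(d12, 0)
  }
})

test_that("with prohibitive pruning cost the edit distance is cost_c * R-F", {
  set.seed(59)
  for (i in 1:10) {
    pair <- random_tree_pair(7, model = "unconstrained")
    t1 <- pair[[1]]
    t2 <- pair[[2]]
    big <- 2 * (length(t1$splits) + length(t2$splits)) + 5
    expect_equal(
      edit_dist(t1, t2, cost_c = 2, cost_p = big),
      2 * rf_dist(t1, t2)
    )
  }
})

test_that("distance is monotone in the operation costs", {
  t1 <- fig12_t1()
  t2 <- fig12_t2()
  for (cc in c(1, 2)) {
    d <- vapply(
      c(0.5, 1, 2, 4),
      function(cp) edit_dist(t1, t2, cc, cp), numeric(1)
    )
    expect_true(all(diff(d) >= -1e-9))
  }
  d <- vapply(c(0.5, 1, 2), function(cc) edit_dist(t1, t2, cc, 1), numeric(1))
  expect_true(all(diff(d) >= -1e-9))
})
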