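test_that("newick parsing preserves labels and lengths, auto-names nodes", {
  t1 <- parse_newick("(A:1,B:1);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_equal(t1$edge.length, c(1, 1))
  expect_equal(t1$node.label, "n2")

  t2 <- parse_newick("((A,B)n3,C)n2;")
  expect_equal(t2$node.label[order(t2$node.label)], c("n2", "n3"))

  # partially labeled: unlabeled nodes named by preorder position
  t3 <- parse_newick("((A,B),(C,D)inner);")
  expect_setequal(t3$node.label, c("n2", "n3", "inner"))

  expect_error(parse_newick(""), "empty")
  expect_error(parse_newick("((A,B);"), "malformed")
  expect_error(parse_newick("(A,A);"), "duplicate")
})

test_that("newick round-trips through write and parse", {
  for (s in 1:20) {
    phy <- random_binary_tree(sample(4:15, 1), seed = 400 + s)
    back <- parse_newick(write_newick(phy))
    expect_equal(write_newick(back), write_newick(phy))
    expect_equal(back$tip.label, phy$tip.label)
    expect_equal(back$node.label, phy$node.label)
  }
})

test_that("Farris intervals and costs follow the down-pass rules", {
  ch <- parse_newick("(A,B);")
  d0 <- wagner_down_pass(ch, c(A = 0, B = 0))
  expect_equal(unname(d0$interval["n2", ]), c(0L, 0L))
  expect_equal(d0$cost, 0L)

  d2 <- wagner_down_pass(ch, c(A = 0, B = 2))
  expect_equal(unname(d2$interval["n2", ]), c(0L, 2L))
  expect_equal(d2$cost, 2L)

  t4 <- parse_newick("((A,B),(C,D));")
  expect_equal(wagner_down_pass(t4, c(A = 0, B = 1, C = 4, D = 4))$cost, 4L)

  star <- parse_newick("(A,B,C);")
  expect_error(wagner_down_pass(star, c(A = 0, B = 1, C = 2)),
               "not binary")
  expect_error(wagner_down_pass(t4, c(A = 0, B = 1, C = 4)), "missing")
})

test_that("the linear-cost DP matches closed forms and handles bounds", {
  star <- parse_newick("(A,B,C);")
  # star-tree optimum: sum of absolute deviations from the median
  expect_equal(sankoff_linear(star, c(A = 0, B = 1, C = 5))$cost, 5)
  for (s in 1:10) {
    x <- domrep:::with_seed(s, stats::setNames(sample(0:6, 5, TRUE),
                                               c("A", "B", "C", "D", "E")))
    star5 <- parse_newick("(A,B,C,D,E);")
    expect_equal(sankoff_linear(star5, x)$cost,
                 sum(abs(x - stats::median(x))))
  }

  t4 <- parse_newick("((A,B),(C,D));")
  const <- sankoff_linear(t4, c(A = 3, B = 3, C = 3, D = 3))
  expect_equal(const$cost, 0)
  expect_true(all(const$scores[, "3"] == 0))

  expect_error(sankoff_linear(t4, c(A = 0, B = 1, C = 4, D = 4),
                              max_state = 2), "below maximum leaf state")
})

test_that("DP, Farris pass and brute force agree on random small trees", {
  for (s in 1:40) {
    n <- 3 + (s %% 4)
    phy <- random_binary_tree(n, seed = 600 + s)
    x <- random_states(phy, 4, seed = 700 + s)
    bf <- brute_force_parsimony(phy, x)
    expect_equal(sankoff_linear(phy, x)$cost, bf)
    expect_equal(wagner_down_pass(phy, x)$cost, bf)
  }
})

test_that("the DP cost matches an independent Sankoff implementation", {
  skip_if_not_installed("phangorn")
  for (s in 1:15) {
    phy <- random_binary_tree(sample(5:12, 1), seed = 800 + s)
    x <- random_states(phy, 4, seed = 900 + s)
    dat <- phangorn::phyDat(matrix(as.character(x), ncol = 1,
                                   dimnames = list(names(x), NULL)),
                            type = "USER", levels = as.character(0:4))
    cost <- abs(outer(0:4, 0:4, "-"))
    dimnames(cost) <- list(0:4, 0:4)
    ext <- phangorn::parsimony(phy, dat, method = "sankoff", cost = cost)
    expect_equal(sankoff_linear(phy, x)$cost, unname(as.numeric(ext)))
  }
})

test_that("canonical assignments realize the DP minimum", {
  ch <- parse_newick("(A,B);")
  a <- assign_states(ch, sankoff_linear(ch, c(A = 0, B = 2)))
  expect_equal(unname(a$state["n2"]), 0L)   # root-smallest
  expect_equal(a$cost, 2L)
  b <- assign_states(ch, sankoff_linear(ch, c(A = 0, B = 2)),
                     policy = "root-largest")
  expect_equal(unname(b$state["n2"]), 2L)
  expect_equal(b$cost, 2L)

  t4 <- parse_newick("((A,B),(C,D));")
  k <- assign_states(t4, sankoff_linear(t4, c(A = 2, B = 2, C = 2, D = 2),
                                        max_state = 3))
  expect_true(all(k$state == 2L))

  for (s in 1:50) {
    phy <- random_binary_tree(sample(4:12, 1), seed = 1100 + s)
    x <- random_states(phy, 5, seed = 1200 + s)
    down <- sankoff_linear(phy, x)
    a <- assign_states(phy, down)
    expect_equal(a$cost, as.integer(down$cost))
    expect_equal(a$state[names(x)], x)      # leaves keep their states
  }
})

test_that("assignments are deterministic and ignore branch lengths", {
  phy <- random_binary_tree(10, seed = 42)
  x <- random_states(phy, 4, seed = 43)
  a1 <- assign_states(phy, sankoff_linear(phy, x))
  a2 <- assign_states(phy, sankoff_linear(phy, x))
  expect_identical(a1, a2)

  noblen <- phy; noblen$edge.length <- NULL
  stretched <- phy; stretched$edge.length <- phy$edge.length * 1000
  expect_identical(assign_states(noblen, sankoff_linear(noblen, x))$state,
                   a1$state)
  expect_identical(assign_states(stretched,
                                 sankoff_linear(stretched, x))$state,
                   a1$state)
})

test_that("parsimony cost bounds hold and the root stays in the leaf range", {
  for (s in 1:30) {
    phy <- random_binary_tree(sample(4:10, 1), seed = 1300 + s)
    x <- random_states(phy, 6, seed = 1400 + s)
    down <- sankoff_linear(phy, x)
    expect_gte(down$cost, max(x) - min(x))
    a <- assign_states(phy, down)
    root_state <- a$state[[ape::Ntip(phy) + 1L]]
    expect_true(root_state >= min(x) && root_state <= max(x))
  }
  # equality on a two-leaf tree
  ch <- parse_newick("(A,B);")
  expect_equal(sankoff_linear(ch, c(A = 1, B = 5))$cost, 4)
})

test_that("matrix-level reconstruction treats domains independently", {
  phy <- random_binary_tree(6, seed = 21)
  reps <- lapply(seq_len(6), function(i) domrep:::with_seed(30 + i, {
    domain_repertoire(phy$tip.label[i],
                      stats::setNames(sample(1:3, 3, TRUE),
                                      c("D1", "D2", "D3")))
  }))
  m <- build_matrix(reps)
  asr <- reconstruct_asr(phy, m)
  expect_named(asr, colnames(m))
  for (d in colnames(m)) {
    solo <- assign_states(phy, sankoff_linear(phy, extract_character(m, d)),
                          domain = d)
    expect_equal(asr[[d]]$state, solo$state)
  }
  tab <- asr_table(asr)
  expect_equal(nrow(tab), length(asr) * (ape::Ntip(phy) + phy$Nnode))
})
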