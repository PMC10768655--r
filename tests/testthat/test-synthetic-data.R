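test_that("Yule trees are rooted, binary, ultrametric and deterministic", {
  ch <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(ch), 2)
  depths <- ape::node.depth.edgelength(ch)
  expect_equal(depths[1], depths[2])

  y <- simulate_yule_tree(20, 1, seed = 9)
  expect_equal(y$Nnode, 19)              # 2n - 2 branches, n - 1 internals
  expect_equal(nrow(y$edge), 38)
  expect_equal(sort(y$tip.label), sort(paste0("T", 1:20)))
  d <- ape::node.depth.edgelength(y)
  expect_lt(max(abs(d[1:20] - max(d))), 1e-9)

  expect_identical(write_newick(simulate_yule_tree(10, 2, seed = 5)),
                   write_newick(simulate_yule_tree(10, 2, seed = 5)))
  expect_error(simulate_yule_tree(1, 1), "at least 2")
})

test_that("repertoire evolution respects the rates and absorbing zero", {
  y <- simulate_yule_tree(6, 1, seed = 2)
  frozen <- evolution_params(gain_rate = 0, dup_rate = 0, loss_rate = 0,
                             root_repertoire = c(A = 2L, B = 1L), seed = 3)
  sim <- simulate_repertoire_evolution(y, frozen)
  expect_equal(nrow(sim$truth_log), 0)
  for (r in sim$leaf_repertoires)
    expect_equal(r$counts, c(A = 2L, B = 1L))

  doomed <- evolution_params(gain_rate = 0, dup_rate = 0, loss_rate = 50,
                             root_repertoire = c(A = 3L, B = 2L), seed = 4)
  sim2 <- simulate_repertoire_evolution(y, doomed)
  for (r in sim2$leaf_repertoires) expect_length(r$counts, 0)
  expect_true(all(sim2$truth_log$event == "loss"))
  # per branch, losses never exceed copies present at the branch start
  expect_lte(max(table(sim2$truth_log$child)), 5)
})

test_that("replaying the truth log reproduces every leaf repertoire", {
  for (s in 1:30) {
    y <- simulate_yule_tree(8, 1, seed = 3000 + s)
    p <- evolution_params(gain_rate = 0.15, dup_rate = 0.2, loss_rate = 0.2,
                          root_repertoire = c(Ca_hom_mod = 2L, EF_hand = 1L),
                          seed = 3100 + s)
    sim <- simulate_repertoire_evolution(y, p)
    replayed <- replay_truth_log(y, p$root_repertoire, sim$truth_log)
    expect_equal(lapply(replayed, `[[`, "counts"),
                 lapply(sim$leaf_repertoires, `[[`, "counts"))
  }
})

test_that("simulators are pure functions of their seed", {
  y <- simulate_yule_tree(6, 1, seed = 2)
  p <- evolution_params(seed = 77)
  s1 <- simulate_repertoire_evolution(y, p)
  s2 <- simulate_repertoire_evolution(y, p)
  expect_identical(s1, s2)
  g1 <- plant_orfs(c("MKLV"), spacer_length = 20, seed = 8)
  g2 <- plant_orfs(c("MKLV"), spacer_length = 20, seed = 8)
  expect_identical(g1$seq, g2$seq)
  expect_identical(make_domtblout_fixture(domain_repertoire("t", c(A = 1)),
                                          decoys = 3, seed = 6),
                   make_domtblout_fixture(domain_repertoire("t", c(A = 1)),
                                          decoys = 3, seed = 6))
})

test_that("planted ORFs are recovered at their planted coordinates", {
  g <- plant_orfs("MK", spacer_length = 20, seed = 1)
  o <- find_orfs(g, min_aa = 2, mode = "maximal")
  expect_true("MK" %in% o$aa_seq)
  expect_equal(sum(o$aa_seq == "MK"), 1)

  prots <- domrep:::with_seed(12, vapply(1:10, function(i)
    paste0("M", paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]],
                             sample(8:20, 1), replace = TRUE),
                      collapse = "")), ""))
  g10 <- plant_orfs(prots, spacer_length = 30, seed = 13)
  planted <- attr(g10, "planted")
  o10 <- find_orfs(g10, min_aa = min(nchar(prots)), mode = "maximal")
  expect_gte(nrow(o10), 10)
  for (i in seq_len(nrow(planted))) {
    hit <- o10[o10$start == planted$start[i] & o10$end == planted$end[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$aa_seq, planted$protein[i])
    expect_equal(hit$strand, "+")
  }
  expect_error(plant_orfs("KLM"), "start with M")
  expect_error(plant_orfs("MK*"), "stop symbols")
})

test_that("domtblout fixtures filter back to the planted repertoire", {
  r <- domain_repertoire("t1", c(Ca_hom_mod = 1L))
  txt <- make_domtblout_fixture(r, decoys = 5, seed = 2)
  hits <- parse_domtblout(text = txt)
  expect_equal(nrow(hits), 6)
  expect_equal(build_repertoire(filter_hits(hits), "t1")$counts, r$counts)

  none <- make_domtblout_fixture(domain_repertoire("t2", integer(0)),
                                 decoys = 3, seed = 3)
  kept <- filter_hits(parse_domtblout(text = none))
  expect_equal(nrow(kept), 0)

  for (s in 1:25) {
    cnt <- domrep:::with_seed(s, stats::setNames(
      sample(1:4, 8, TRUE), sample(sprintf("FAM%02d", 1:40), 8)))
    r <- domain_repertoire(paste0("t", s), cnt)
    hits <- parse_domtblout(text = make_domtblout_fixture(
      r, decoys = sample(0:6, 1), seed = 4000 + s))
    expect_equal(build_repertoire(filter_hits(hits), r$taxon)$counts,
                 r$counts)
  }
})

test_that("single-event histories log exactly one unit event per domain", {
  for (s in 1:10) {
    y <- simulate_yule_tree(8, 1, seed = 5000 + s)
    root_rep <- c(A = 2L, B = 1L, C = 3L)
    sim <- simulate_single_event_history(y, root_rep, n_gains = 1,
                                         n_dups = 1, n_losses = 1,
                                         seed = 5100 + s)
    expect_equal(nrow(sim$truth_log), 3)
    expect_equal(anyDuplicated(sim$truth_log$domain), 0)
    # the log and the leaf repertoires are mutually consistent
    replayed <- replay_truth_log(y, root_rep, sim$truth_log)
    expect_equal(lapply(replayed, `[[`, "counts"),
                 lapply(sim$leaf_repertoires, `[[`, "counts"))
    # losses avoid root-incident branches (identifiability)
    kids <- c(y$tip.label, y$node.label)[y$edge[y$edge[, 1] ==
                                                  ape::Ntip(y) + 1, 2]]
    losses <- sim$truth_log[sim$truth_log$event == "loss", ]
    expect_false(any(losses$child %in% kids))
  }
  expect_error(simulate_single_event_history(
    simulate_yule_tree(4, 1, seed = 1), c(A = 1L), n_dups = 1, n_losses = 1),
    "too small")
})
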