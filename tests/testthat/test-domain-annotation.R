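fixture_lines <- c(
  "# hmmscan :: search sequence(s) against a profile database",
  "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
  "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
  "Ca_hom_mod           PF08805.12   248 orf1                 -            315   1.2e-50  170.1   0.3   1   1   3.1e-52   1.4e-50  169.9   0.2     2   246     10   250      8   252 0.97 Calcium homeostasis modulator",
  "EF-hand_1            PF00036.35    29 orf2                 -            150   0.00045   20.3   0.1   1   2   0.00021    0.0021   19.1   0.0     1    29     40    68     38    70 0.92 -")

test_that("domtblout parsing extracts all 22 columns plus description", {
  hits <- parse_domtblout(text = paste(fixture_lines, collapse = "\n"))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$target_name, c("Ca_hom_mod", "EF-hand_1"))
  expect_equal(hits$query_name, c("orf1", "orf2"))
  expect_equal(hits$seq_evalue, c(1.2e-50, 4.5e-4))
  expect_equal(hits$c_evalue, c(3.1e-52, 2.1e-4))
  expect_equal(hits$domain_total, c(1L, 2L))
  expect_equal(hits$ali_from, c(10L, 40L))
  expect_equal(hits$acc, c(0.97, 0.92))
  expect_equal(hits$description,
               c("Calcium homeostasis modulator", "-"))
})

test_that("malformed domtblout lines are rejected with their line number", {
  short <- c("# comment", "Ca_hom_mod PF08805.12 248 orf1 - 315")
  expect_error(parse_domtblout(text = paste(short, collapse = "\n")),
               "line 2.*22 columns")
  bad <- fixture_lines
  bad[4] <- sub("1.2e-50", "not_a_number", bad[4])
  expect_error(parse_domtblout(text = paste(bad, collapse = "\n")),
               "line 4.*seq_evalue")
})

test_that("domtblout write/parse round-trips all field values", {
  rep <- domain_repertoire("taxA", stats::setNames(
    rep(1L, 50), sprintf("DOM%03d", 1:50)))
  txt <- make_domtblout_fixture(rep, decoys = 50, seed = 11)
  hits <- parse_domtblout(text = txt)
  expect_equal(nrow(hits), 100)
  back <- parse_domtblout(text = write_domtblout(hits))
  expect_equal(back, hits)
})

test_that("empty hit tables serialize to comments only", {
  txt <- write_domtblout(parse_domtblout(text = "# nothing"))
  expect_true(all(grepl("^#", strsplit(txt, "\n")[[1]])))
  expect_equal(nrow(parse_domtblout(text = txt)), 0)
})

test_that("E-value filtering applies both inclusive criteria", {
  hits <- parse_domtblout(text = paste(fixture_lines, collapse = "\n"))
  hits$seq_evalue <- c(1e-5, 1e-5)
  hits$c_evalue <- c(1e-4, 0.01)
  kept <- filter_hits(hits)
  expect_equal(kept$target_name, "Ca_hom_mod")   # second fails c-Evalue

  hits$seq_evalue <- 1e-3; hits$c_evalue <- 1e-3  # inclusive boundary
  expect_equal(nrow(filter_hits(hits)), 2)

  # idempotent and monotone in the thresholds
  expect_equal(filter_hits(kept), kept)
  tight <- filter_hits(hits, 1e-4, 1e-4)
  loose <- filter_hits(hits, 1e-2, 1e-2)
  expect_true(all(tight$query_name %in% loose$query_name))
})

test_that("repertoire construction counts one copy per hit", {
  hits <- parse_domtblout(text = paste(fixture_lines, collapse = "\n"))
  hits <- hits[c(1, 1, 2), ]
  rep <- build_repertoire(hits, "Homo_sapiens")
  expect_equal(rep$counts, c(Ca_hom_mod = 2L, `EF-hand_1` = 1L),
               ignore_attr = FALSE)
  expect_equal(sum(rep$counts), nrow(hits))
  expect_equal(length(build_repertoire(hits[0, ], "empty")$counts), 0)
})

test_that("the non-redundant domain set is the sorted union", {
  r1 <- domain_repertoire("t1", c(A = 2))
  r2 <- domain_repertoire("t2", c(B = 1, A = 1))
  expect_equal(nonredundant_domains(list(r1, r2)), c("A", "B"))
  r3 <- domain_repertoire("t3", c(X = 1, Y = 1, Z = 1))
  r4 <- domain_repertoire("t4", c(P = 1, Q = 1, R = 1, S = 1))
  expect_length(nonredundant_domains(list(r3, r4)), 7)

  pool <- sprintf("FAM%02d", 1:50)
  reps <- lapply(1:5, function(i) domrep:::with_seed(i, {
    nm <- sample(pool, 12)
    domain_repertoire(paste0("t", i),
                      stats::setNames(sample(1:3, 12, TRUE), nm))
  }))
  planted <- sort(unique(unlist(lapply(reps, function(r) names(r$counts)))))
  expect_equal(nonredundant_domains(reps), planted)
})

test_that("envelope de-duplication keeps the best-scoring hit", {
  hits <- parse_domtblout(text = paste(fixture_lines, collapse = "\n"))
  dup <- hits[c(1, 1), ]
  dup$dom_score <- c(100, 200)
  kept <- dedup_overlaps(dup)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$dom_score, 200)
  # non-overlapping envelopes are both retained
  dup$env_from <- c(1L, 300L); dup$env_to <- c(100L, 400L)
  expect_equal(nrow(dedup_overlaps(dup)), 2)
})
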