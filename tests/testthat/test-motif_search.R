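test_that("search configuration is validated", {
  expect_error(search_config(0, 5), "l_min")
  expect_error(search_config(6, 5), "l_max")
  expect_equal(search_config(5, 10)$extend, "both")
  expect_equal(search_space_size(5, 10), 1397760)
  expect_equal(search_space_size(3, 3), 64)
})

test_that("seed enumeration keeps exactly the non-negative Z-scores", {
  sp <- small_planted_pool(seed = 301, n_reads = 800)
  cfg <- search_config(4, 6)
  seeds <- enumerate_seeds(sp$pool, config = cfg)
  expect_lte(nrow(seeds), 4^4)
  expect_true(all(seeds$Z >= 0))
  expect_true(all(seeds$length == 4L))
  # recompute one survivor's score independently
  s <- seeds$string[1]
  expect_equal(seeds$F[1], count_containing_reads(s, sp$pool))
  P <- length_averaged_prob(s, sp$pool, estimate_base_probs(sp$pool))
  expect_equal(seeds$Z[1], z_score(seeds$F[1], sp$pool$N, P))
})

test_that("every window of a strongly planted motif survives seeding", {
  sp <- small_planted_pool(seed = 302, n_reads = 2000, prevalence = 0.3)
  seeds <- enumerate_seeds(sp$pool, config = search_config(5, 10))
  motif <- "TATGGACTTC"
  windows <- substring(motif, 1:6, 5:10)
  expect_true(all(windows %in% seeds$string))
})

test_that("extension keeps a child iff some generating parent allows it", {
  sp <- small_planted_pool(seed = 303, n_reads = 1000)
  pool <- sp$pool
  probs <- estimate_base_probs(pool)
  lvl5 <- enumerate_seeds(pool, probs, search_config(5, 6))
  lvl6 <- extend_strings(lvl5, pool, probs, extend = "both")
  expect_true(all(lvl6$Z >= 0))
  expect_true(all(nchar(lvl6$string) == 6L))
  # recheck the retention rule against the parent table
  z5 <- setNames(lvl5$Z, lvl5$string)
  for (i in seq_len(min(nrow(lvl6), 50))) {
    ch <- lvl6$string[i]
    parents <- intersect(c(substr(ch, 1, 5), substr(ch, 2, 6)),
                         names(z5))
    expect_gt(length(parents), 0)
    expect_true(any(lvl6$Z[i] >= z5[parents]))
  }
  # a child exactly tying its parent is retained ("less than" is strict):
  # verify the boundary on a hand-built survivor table where the only
  # parent has Z equal to what the child will score
  tie_pool <- sequence_pool(c("AATTCGG", "CCGGTTA", "GGAACCT", "TTCCGAA"))
  tie_probs <- estimate_base_probs(tie_pool)
  tab5 <- string_score_table(c("AATTC"), tie_pool, tie_probs)
  tab6 <- string_score_table(c("AATTCG"), tie_pool, tie_probs)
  kept <- extend_strings(tab5[, c("string", "length", "F", "P", "Z")],
                         tie_pool, tie_probs)
  expect_equal("AATTCG" %in% kept$string, tab6$Z >= tab5$Z)
})

test_that("selection at l_min = l_max reduces to seed enumeration", {
  sp <- small_planted_pool(seed = 304, n_reads = 500)
  cfg <- search_config(5, 5)
  sel <- select_strings(sp$pool, config = cfg)
  seeds <- enumerate_seeds(sp$pool, config = cfg)
  expect_equal(sel$strings[, c("string", "F", "Z")],
               seeds[, c("string", "F", "Z")],
               ignore_attr = TRUE)
  expect_equal(sel$m, nrow(seeds))
})

test_that("selection is deterministic and survivors have Z >= 0", {
  sp <- small_planted_pool(seed = 305, n_reads = 1000)
  cfg <- search_config(5, 8)
  a <- select_strings(sp$pool, config = cfg)
  b <- select_strings(sp$pool, config = cfg)
  expect_identical(a$strings, b$strings)
  expect_true(all(a$strings$Z >= 0))
  expect_equal(a$m, sum(a$per_length))
  # every survivor longer than l_min has a parent among the level below
  for (l in 6:8) {
    lvl <- a$strings[a$strings$length == l, ]
    below <- a$strings$string[a$strings$length == l - 1]
    if (nrow(lvl) == 0) next
    has_parent <- vapply(lvl$string, function(ch) {
      any(c(substr(ch, 1, l - 1), substr(ch, 2, l)) %in% below)
    }, logical(1))
    expect_true(all(has_parent))
  }
})

test_that("a planted 10-mer dominates length-10 survivors", {
  sp <- small_planted_pool(seed = 306, n_reads = 2000, prevalence = 0.3)
  sel <- select_strings(sp$pool, config = search_config(5, 10))
  s10 <- sel$strings[sel$strings$length == 10, ]
  expect_true("TATGGACTTC" %in% s10$string)
  expect_equal(s10$string[which.max(s10$Z)], "TATGGACTTC")
})

test_that("pruned search does not miss exhaustive per-length winners", {
  sp <- small_planted_pool(seed = 307, n_reads = 1500)
  sel <- select_strings(sp$pool, config = search_config(5, 8))
  top <- exhaustive_top_strings(sp$pool, lengths = 5:8, n_top = 1)
  expect_true(all(top$string %in% sel$strings$string))
})

test_that("selection warns when l_max exceeds the shortest read", {
  pool <- sequence_pool(c("ACGTAC", "ACGTACGTACGT"), c(5L, 5L))
  expect_warning(
    try(select_strings(pool, config = search_config(5, 10)), silent = TRUE),
    "shortest read")
})
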