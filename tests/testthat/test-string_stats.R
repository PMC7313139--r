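test_that("base probabilities are multiplicity-weighted composition", {
  expect_equal(unname(estimate_base_probs(sequence_pool(c("AC", "GT")))),
               rep(0.25, 4))
  expect_equal(unname(estimate_base_probs(sequence_pool("AAAA"))),
               c(1, 0, 0, 0))
  p <- estimate_base_probs(sequence_pool(c("AAC", "G"), c(2L, 1L)))
  expect_equal(unname(p), c(4 / 7, 2 / 7, 1 / 7, 0))
  expect_equal(sum(p), 1)
})

test_that("border sets are the proper prefixes that are also suffixes", {
  expect_equal(border_set("ATATA"), c("A", "ATA"))
  expect_equal(border_set("GACTT"), character(0))
  expect_equal(border_set("AAAA"), c("A", "AA", "AAA"))
  expect_equal(border_set("A"), character(0))
  expect_error(border_set(""), "empty")
})

test_that("containment table matches hand-derivable cases", {
  # below the string length the probability is zero
  expect_equal(containment_prob_table("ATATA", uniform_probs, 4),
               rep(0, 5))
  # single letter: closed form 1 - (1-p)^L
  expect_equal(containment_prob_table("A", uniform_probs, 2)[3], 0.4375)
  # bordered string, enumeration by hand: p^2 + p^2 - p^3 at p = 1/2
  pa <- alphabet_probs(c(0.5, 0.5 / 3, 0.5 / 3, 0.5 / 3))
  expect_equal(containment_prob_table("AA", pa, 3)[4], 0.375)
  # border-free string, full enumeration of the 64 trinucleotides
  expect_equal(containment_prob_table("AT", uniform_probs, 3)[4], 0.125)
})

test_that("containment table is monotone and dominated by substrings", {
  set.seed(101)
  for (rep in 1:20) {
    s <- rand_string(sample(2:7, 1))
    p <- rand_probs()
    tab <- containment_prob_table(s, p, 25)
    expect_true(all(diff(tab) >= -1e-15))
    expect_true(all(tab >= 0 & tab <= 1))
    # containing-string's probability cannot exceed its substring's
    sub <- substr(s, 1, nchar(s) - 1)
    tab_sub <- containment_prob_table(sub, p, 25)
    expect_true(all(tab <= tab_sub + 1e-12))
  }
})

test_that("impossible strings (zero-probability base) get an all-zero table", {
  p <- alphabet_probs(c(0.5, 0.5, 0, 0))
  expect_equal(containment_prob_table("AG", p, 10), rep(0, 11))
})

test_that("recurrence agrees with both independent oracles", {
  set.seed(7)
  strings <- c("ATATA", "AAAA", "ATGATG",
               replicate(12, rand_string(sample(2:6, 1))))
  for (s in strings) {
    p <- rand_probs()
    tab <- containment_prob_table(s, p, 30)
    for (L in c(nchar(s), 7, 9)) {
      expect_lt(abs(tab[L + 1] -
                      exact_containment_oracle(s, p, L, "enumerate")),
                1e-10)
    }
    auto <- vapply(0:30, function(L)
      exact_containment_oracle(s, p, L, "automaton"), numeric(1))
    expect_lt(max(abs(tab - auto)), 1e-10)
  }
  expect_error(exact_containment_oracle("A", uniform_probs, 12,
                                        "enumerate"), "refused")
})

test_that("length-averaged probability is the count-weighted mean", {
  p <- uniform_probs
  pool <- sequence_pool(c("ACGTACGTACGTACGTACGTACGTACGTAC",  # L = 30
                          "ACGTACGTACGTACGTACGTACGTACGT"),   # L = 28
                        c(3L, 1L))
  tab <- containment_prob_table("GGAC", p, 30)
  expect_equal(length_averaged_prob("GGAC", pool, p),
               (3 * tab[31] + tab[29]) / 4)
  # constant lengths: averaging is the identity
  pool1 <- sequence_pool(c("ACGTACGT", "TTTTTTTT"))
  expect_equal(length_averaged_prob("ACG", pool1, p),
               containment_prob_table("ACG", p, 8)[9])
  # every read shorter than the string
  expect_equal(length_averaged_prob("AAAAAAAAAA", pool1, p), 0)
})

test_that("containment frequency counts reads, not occurrences", {
  pool <- sequence_pool("AAAA", 5L)
  expect_equal(count_containing_reads("AA", pool), 5L)
  expect_equal(count_containing_reads("GG", pool), 0L)
  pool2 <- sequence_pool(c("AGGAGGGGGACTTAGGACTGGGTTTAGGG", "CCCC"))
  expect_equal(count_containing_reads(c("GACTT", "CCCC", "GACTTT"), pool2),
               c(1L, 1L, 0L))
})

test_that("z_score follows the binomial standardization", {
  expect_equal(z_score(5, 100, 0.05), 0)
  expect_equal(z_score(10, 100, 0.05), 0.05 / sqrt(0.05 * 0.95 / 100))
  expect_equal(z_score(10, 100, 0.05), 2.2942, tolerance = 1e-4)
  expect_equal(z_score(0, 4, 0.5), -2)
  expect_error(z_score(1, 10, 0), "undefined")
  expect_error(z_score(1, 10, 1), "undefined")
  # sign property: Z > 0 iff observed fraction exceeds expectation
  set.seed(11)
  for (rep in 1:25) {
    N <- sample(10:1000, 1)
    F_s <- sample(0:N, 1)
    P_s <- runif(1, 0.01, 0.99)
    expect_equal(z_score(F_s, N, P_s) > 0, F_s / N > P_s)
  }
})

test_that("batch scoring excludes strings with degenerate probability", {
  pool <- sequence_pool(c("AAAAAA", "AACAAA"), c(9L, 1L))  # p_G = p_T = 0
  tab <- string_score_table(c("AAA", "AAG"), pool)
  expect_true(tab$scoreable[tab$string == "AAA"])
  expect_false(tab$scoreable[tab$string == "AAG"])
  expect_true(is.na(tab$Z[tab$string == "AAG"]))
})
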