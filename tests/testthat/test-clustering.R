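ranked_manual <- function(strings, z_star, z = z_star,
                          len = nchar(strings)) {
  data.frame(string = strings, length = len, Z = z, Z_star = z_star,
             rank = seq_along(strings))
}

test_that("Z normalization standardizes within each length class", {
  df <- data.frame(string = c("AAAAA", "CCCCC"), length = 5L, Z = c(2, 4))
  nz <- normalize_z(df)
  expect_equal(sort(nz$Z_star), c(-1, 1) / sqrt(2))
  # a singleton class sits at its class mean
  df1 <- data.frame(string = "AAAAA", length = 5L, Z = 3.7)
  expect_equal(normalize_z(df1)$Z_star, 0)
  # two classes standardized independently: per-class mean 0, sample SD 1
  set.seed(21)
  df2 <- data.frame(string = c(replicate(6, rand_string(5)),
                               replicate(4, rand_string(6))),
                    length = rep(c(5L, 6L), c(6, 4)),
                    Z = rnorm(10, mean = 50, sd = 9))
  nz2 <- normalize_z(df2)
  for (l in c(5L, 6L)) {
    zs <- nz2$Z_star[nz2$length == l]
    expect_equal(mean(zs), 0)
    expect_equal(sd(zs), 1)
  }
})

test_that("ranking uses the documented deterministic tie-breaks", {
  df <- data.frame(string = c("CCCCC", "AAAAA"), length = 5L,
                   Z = c(1, 2), Z_star = c(1.2, 0.3))
  expect_equal(rank_strings(df)$string, c("CCCCC", "AAAAA"))
  # Z* tie -> higher raw Z first
  df2 <- data.frame(string = c("AAAAA", "CCCCC"), length = 5L,
                    Z = c(1, 2), Z_star = c(0.5, 0.5))
  expect_equal(rank_strings(df2)$string, c("CCCCC", "AAAAA"))
  # full tie -> longer first, then lexicographically smaller
  df3 <- data.frame(string = c("TTTTT", "AAAAA", "GGGGGG"),
                    length = c(5L, 5L, 6L),
                    Z = 1, Z_star = 0)
  expect_equal(rank_strings(df3)$string, c("GGGGGG", "AAAAA", "TTTTT"))
  expect_equal(rank_strings(df3)$rank, 1:3)
})

test_that("greedy extraction assigns each sequence to its best string", {
  pool <- sequence_pool(c("AAACGTTT",    # contains rank 1 and rank 2
                          "CCCCGTTT",    # contains rank 2 only
                          "GGGGGGGG"))   # matches nothing
  ranked <- ranked_manual(c("AAACG", "CGTTT"), z_star = c(2, 1))
  cl <- greedy_cluster(pool, ranked)
  a <- cl$assignment
  expect_equal(a$cluster[a$sequence == "AAACGTTT"], 1L)
  expect_equal(a$cluster[a$sequence == "CCCCGTTT"], 2L)
  expect_true(is.na(a$cluster[a$sequence == "GGGGGGGG"]))
  expect_equal(cl$K, 2L)
  expect_equal(cl$n_unassigned, 1L)
})

test_that("empty extractions do not consume a cluster rank", {
  pool <- sequence_pool(c("AAACGTTT", "CCCAGTTT"))
  # rank 1 absorbs everything containing GTTT; the next two strings then
  # match nothing; the last would have matched but sequences are gone
  ranked <- ranked_manual(c("GTTT", "TTTTT", "ACGTA", "AAACG"),
                          z_star = c(4, 3, 2, 1))
  cl <- greedy_cluster(pool, ranked)
  expect_equal(cl$K, 1L)
  expect_equal(unique(cl$assignment$cluster), 1L)
})

test_that("clustering partitions the pool", {
  sp <- small_planted_pool(seed = 401, n_reads = 1500)
  res <- run_fsbc(sp$pool, min_count = 1, l_min = 5, l_max = 8)
  cl <- res$clusters
  n_unique <- length(sp$pool$sequence)
  expect_equal(sum(cl$cluster_sizes$n_unique) + cl$n_unassigned, n_unique)
  expect_equal(nrow(cl$assignment), n_unique)
  # ranks of non-empty clusters are consecutive 1..K
  got <- sort(unique(cl$assignment$cluster[!is.na(cl$assignment$cluster)]))
  expect_equal(got, seq_len(cl$K))
  # cluster 1 is extracted by the best-ranked string that matches anything
  first_rank <- min(which(res$ranked$string %in%
                            cl$assignment$matched_string))
  expect_equal(cl$assignment$matched_string[cl$assignment$cluster == 1][1],
               res$ranked$string[first_rank])
})

test_that("cluster TSV export carries ranks and NA for unassigned", {
  pool <- sequence_pool(c("AAACGTTT", "GGGGGGGG"))
  cl <- greedy_cluster(pool, ranked_manual("AACG", 1))
  path <- tempfile(fileext = ".tsv")
  write_clusters_tsv(cl, path)
  df <- read.delim(path)
  expect_named(df, c("sequence", "count", "cluster_rank",
                     "matched_string", "string_Zstar"))
  expect_equal(sum(is.na(df$cluster_rank)), 1L)
})
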