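test_that("release_diff is the set difference of annotated gene sets", {
  expect_identical(release_diff(c("A", "B"), c("A", "B")), character())
  expect_identical(release_diff(c("A"), c("B", "C")), c("B", "C"))
  set.seed(2)
  old <- sample(LETTERS, 12)
  new <- sample(LETTERS, 15)
  expect_identical(release_diff(old, new),
                   sort(new[!vapply(new, `%in%`, logical(1), old)]))
})

test_that("matched similarities embed whole summaries pairwise", {
  embed <- mock_embed_provider()
  same <- gene_text_pairs(c("g1", "g2"), c("aa bb", "cc dd"), c("aa bb", "cc dd"))
  expect_equal(matched_similarities(same, embed), c(1, 1))

  pred_vocab <- c("alpha", "beta", "gamma")
  cur_vocab <- c("delta", "epsilon", "zeta")
  # verified hash-disjoint vocabularies -> exactly orthogonal embeddings
  expect_length(intersect(vapply(pred_vocab, oracle_hash_bucket, numeric(1)),
                          vapply(cur_vocab, oracle_hash_bucket, numeric(1))), 0)
  disjoint <- gene_text_pairs(c("g1", "g2", "g3"),
                              c("alpha beta", "gamma", "beta"),
                              c("delta epsilon", "zeta", "delta"))
  expect_equal(matched_similarities(disjoint, embed), c(0, 0, 0))
  expect_length(matched_similarities(disjoint, embed), 3)
  expect_error(gene_text_pairs("g", "", "x"), "non-empty")
})

test_that("permuted background enumerates or samples ordered mismatches", {
  embed <- mock_embed_provider()
  two <- gene_text_pairs(c("g1", "g2"), c("aa", "bb"), c("aa", "bb"))
  expect_length(permuted_background(two, embed, mode = "all_mismatched"), 2)

  pairs <- make_validation_pairs(fixture_config(seed = 6), 10)
  bg <- permuted_background(pairs, embed, mode = "all_mismatched")
  expect_length(bg, 10 * 9)
  s1 <- permuted_background(pairs, embed, mode = "sampled", n_samples = 10,
                            seed = 99)
  s2 <- permuted_background(pairs, embed, mode = "sampled", n_samples = 10,
                            seed = 99)
  expect_identical(s1, s2)
  expect_length(s1, 10)
})

test_that("Mann-Whitney agrees with brute-force enumeration (small samples)", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  x <- c(5, 1); y <- c(5, 1)  # identical samples: U = mn/2 with midranks
  expect_equal(mann_whitney_u(x, y)$u_statistic, 2)

  set.seed(17)
  for (i in 1:20) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    v <- sample(1000, m + n)  # distinct values, no ties
    x <- v[1:m]; y <- v[(m + 1):(m + n)]
    got <- mann_whitney_u(x, y)
    oracle <- oracle_mwu_exact(x, y)
    expect_equal(got$u_statistic, oracle$u)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
    expect_identical(got$method, "exact")
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3, 4)
  got <- mann_whitney_u(x, y)
  expect_identical(got$method, "normal_approximation")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(got$p_value, ref$p.value)
})

test_that("planted pairs separate from the permuted background", {
  embed <- mock_embed_provider()
  hits <- 0L
  for (seed in 1:20) {
    pairs <- make_validation_pairs(fixture_config(seed = seed), 50)
    v <- run_validation(pairs, embed)
    if (v$p_value < 1e-3 &&
        stats::median(v$matched_scores) > stats::median(v$background_scores)) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("identical texts under permuted labels show no separation", {
  embed <- mock_embed_provider()
  txt <- rep("shared vocabulary throughout", 6)
  pairs <- gene_text_pairs(paste0("g", 1:6), txt, txt[c(2:6, 1)])
  v <- run_validation(pairs, embed)
  expect_equal(v$p_value, 1)
  expect_equal(v$u_statistic, length(v$matched_scores) *
                 length(v$background_scores) / 2)
})

test_that("histogram bins cover both samples and counts sum correctly", {
  pairs <- make_validation_pairs(fixture_config(seed = 8), 20)
  v <- run_validation(pairs, mock_embed_provider(), bins = 15)
  expect_equal(nrow(v$histogram), 15)
  expect_equal(sum(v$histogram$matched_count), length(v$matched_scores))
  expect_equal(sum(v$histogram$background_count), length(v$background_scores))
  expect_true(all(v$matched_scores >= -1 & v$matched_scores <= 1))
})

test_that("validation pairs TSV reader round-trips the generator output", {
  pairs <- make_validation_pairs(fixture_config(seed = 10), 8)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_validation_pairs(f)
  expect_equal(as.data.frame(back), as.data.frame(pairs))
})
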