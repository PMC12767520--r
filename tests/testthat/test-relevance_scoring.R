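test_that("chunking follows the sliding token window with overlap", {
  expect_equal(nrow(chunk_text("", 10, 2)), 0)
  short <- chunk_text("one two three", 10, 2)
  expect_equal(nrow(short), 1)
  expect_identical(short$text, "one two three")
  expect_equal(short$start_index, 0)

  # 25 tokens, window 10, overlap 2 -> starts at tokens 0, 8, 16, 24
  text <- paste(sprintf("t%02d", 0:24), collapse = " ")
  ch <- chunk_text(text, 10, 2)
  expect_equal(nrow(ch), 4)
  expect_identical(ch$start_index, c(0L, 8L, 16L, 24L) * 4L)
  expect_identical(ch$text[1], paste(sprintf("t%02d", 0:9), collapse = " "))
  expect_identical(ch$text[4], "t24")
  # consecutive chunks share the configured overlap
  expect_identical(substr(ch$text[2], 1, 7), "t08 t09")
  expect_error(chunk_text("x", 5, 5), "chunk_tokens > overlap_tokens")
})

test_that("mock embedder is a deterministic hashed bag-of-words", {
  embed <- mock_embed_provider()
  v <- embed(c("alpha beta", "alpha beta", "!!! ...", "alpha", "beta"))
  expect_identical(v[1, ], v[2, ])
  expect_identical(v[3, ], rep(0, 64))
  expect_equal(cosine_similarity(v[1, ], v[2, ]), 1.0)

  # direct hash-bucket oracle: alpha and beta land in distinct buckets
  expect_false(oracle_hash_bucket("alpha") == oracle_hash_bucket("beta"))
  expect_equal(cosine_similarity(v[4, ], v[5, ]), 0.0)
  expect_equal(which(v[4, ] > 0), oracle_hash_bucket("alpha"))
  expect_equal(sum(v[1, ]^2), 1.0)  # L2-normalized
})

test_that("cosine_similarity handles sign, scale and zero vectors", {
  v <- c(0.3, -1.2, 4)
  expect_equal(cosine_similarity(v, v), 1.0)
  expect_equal(cosine_similarity(v, -v), -1.0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.7071, tolerance = 1e-4)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(1:2, 1:3), "dimension")
})

test_that("abstract-pathway score is the mean of per-chunk cosines", {
  embed <- mock_embed_provider()
  expect_equal(score_abstract_pathway("same words here", "same words here", embed),
               1.0)
  expect_equal(score_abstract_pathway("alpha beta gamma", "delta epsilon", embed),
               0.0)
  expect_warning(s0 <- score_abstract_pathway("  ", "context", embed), "zero chunks")
  expect_equal(s0, 0)

  # multi-chunk: recompute as arithmetic mean of per-chunk cosines
  abstract <- paste(sample(c("aa", "bb", "cc", "dd"), 30, TRUE), collapse = " ")
  ctx <- "aa bb"
  got <- score_abstract_pathway(abstract, ctx, embed,
                                chunk_tokens = 8, overlap_tokens = 2)
  chunks <- chunk_text(abstract, 8, 2)
  per <- vapply(chunks$text, function(t) {
    cosine_similarity(embed(ctx)[1, ], embed(t)[1, ])
  }, numeric(1))
  expect_equal(got, mean(per))
  expect_true(got >= -1 && got <= 1)
})

test_that("mock judge is rescaled token-set Jaccard", {
  judge <- mock_judge_provider(5)
  expect_equal(judge("alpha beta", "alpha beta"), 5L)
  expect_equal(judge("alpha", "beta"), 0L)
  # 5-token fixture: overlap {b, c} of union {a, b, c, d, e} -> 2/5 * 5 = 2
  expect_equal(judge("a b c", "b c d e"), round(5 * 2 / 5))
})

test_that("rank_matches filters by both thresholds then sorts lexicographically", {
  m <- data.frame(pmid = c("10", "11"), pathway_id = c("P1", "P2"),
                  cosine_score = c(0.5, 0.5), judge_score = c(2, 4),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(rank_matches(m, min_cosine = 0.9, min_judge = 0)), 0)
  two <- rank_matches(m, min_cosine = 0, min_judge = 0)
  expect_identical(two$pmid, c("11", "10"))  # equal cosine, higher judge first

  set.seed(9)
  rnd <- data.frame(
    pmid = as.character(sample(100:120, 20)),
    pathway_id = sample(c("PA", "PB"), 20, TRUE),
    cosine_score = round(runif(20), 1), judge_score = sample(0:5, 20, TRUE),
    stringsAsFactors = FALSE)
  got <- rank_matches(rnd, 0, 0)
  oracle <- rnd[order(-rnd$cosine_score, -rnd$judge_score,
                      as.numeric(rnd$pmid), rnd$pathway_id), ]
  expect_identical(got$pmid, oracle$pmid)
  expect_identical(got$pathway_id, oracle$pathway_id)

  # threshold monotonicity: raising either threshold never adds matches
  base <- nrow(rank_matches(rnd, 0.3, 2))
  expect_lte(nrow(rank_matches(rnd, 0.5, 2)), base)
  expect_lte(nrow(rank_matches(rnd, 0.3, 4)), base)
})

test_that("relevant abstracts outrank irrelevant ones on planted corpora", {
  embed <- mock_embed_provider()
  for (seed in 1:25) {
    cfg <- fixture_config(seed = seed)
    kb <- make_knowledgebase(cfg)
    store <- make_abstract_corpus(cfg, kb, "QG", "PW0001")
    target <- kb$pathways$PW0001
    ctx <- pathway_context_text(target, target$gene_set[1:3])
    scores <- vapply(store$pmids, function(pm) {
      score_abstract_pathway(fetch_abstracts(store, pm)[[1]]$abstract, ctx, embed)
    }, numeric(1))
    rel <- scores[1:cfg$n_relevant_abstracts]
    irr <- scores[(cfg$n_relevant_abstracts + 1):length(scores)]
    expect_gt(min(rel), max(irr))
  }
})
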