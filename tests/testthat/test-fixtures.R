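write_kb_string <- function(kb) {
  f <- tempfile()
  write_knowledgebase(kb, f)
  paste(readLines(f), collapse = "\n")
}

test_that("knowledgebase generator respects config and seed", {
  expect_length(make_knowledgebase(fixture_config(n_pathways = 0))$pathways, 0)

  cfg <- fixture_config(seed = 1, n_pathways = 3, genes_per_pathway = 7)
  kb <- make_knowledgebase(cfg)
  expect_length(kb$pathways, 3)
  expect_true(all(lengths(lapply(kb$pathways, `[[`, "gene_set")) == 7))
  expect_length(kb$annotated_genes, 21)  # disjoint gene sets

  expect_identical(write_kb_string(kb), write_kb_string(make_knowledgebase(cfg)))
  kb2 <- make_knowledgebase(fixture_config(seed = 2, n_pathways = 3,
                                           genes_per_pathway = 7))
  expect_false(identical(kb$pathways$PW0001$summary_text,
                         kb2$pathways$PW0001$summary_text))
})

test_that("partner enrichment controls the planted overlap fraction", {
  kb <- make_knowledgebase(fixture_config(seed = 3))
  target_genes <- kb$pathways$PW0001$gene_set

  all_in <- make_interactions(fixture_config(seed = 3, partner_enrichment = 1),
                              kb, "Q", "PW0001")
  expect_true(all(partners_of(all_in, "Q")$partner %in% target_genes))

  none_in <- make_interactions(fixture_config(seed = 3, partner_enrichment = 0),
                               kb, "Q", "PW0001")
  expect_false(any(partners_of(none_in, "Q")$partner %in% target_genes))

  # empirical fraction over many seeds approximates the configured rate
  frac <- vapply(1:200, function(seed) {
    net <- make_interactions(fixture_config(seed = seed,
                                            partner_enrichment = 0.7),
                             kb, "Q", "PW0001")
    mean(partners_of(net, "Q")$partner %in% target_genes)
  }, numeric(1))
  expect_equal(mean(frac), 0.7, tolerance = 0.05)
})

test_that("abstract corpus separates relevant and irrelevant vocabulary", {
  cfg <- fixture_config(seed = 5, n_relevant_abstracts = 4,
                        n_irrelevant_abstracts = 3)
  kb <- make_knowledgebase(cfg)
  store <- make_abstract_corpus(cfg, kb, "QG1", "PW0002")
  expect_length(store$pmids, 7)
  recs <- fetch_abstracts(store, store$pmids)
  rel <- recs[1:4]; irr <- recs[5:7]
  expect_true(all(vapply(rel, function(r) grepl("QG1", r$abstract), logical(1))))

  embed <- mock_embed_provider()
  ctx <- pathway_context_text(kb$pathways$PW0002,
                              kb$pathways$PW0002$gene_set[1:2])
  sim <- function(r) cosine_similarity(embed(ctx)[1, ], embed(r$abstract)[1, ])
  expect_gt(min(vapply(rel, sim, numeric(1))),
            max(vapply(irr, sim, numeric(1))))
})

test_that("validation pair generator is deterministic and mode-sensitive", {
  cfg <- fixture_config(seed = 12)
  p1 <- make_validation_pairs(cfg, 6)
  expect_identical(p1, make_validation_pairs(cfg, 6))
  expect_equal(nrow(p1), 6)
  # planted mode: matched texts share per-gene vocabulary tokens
  toks <- function(x) unique(strsplit(x, " ")[[1]])
  expect_gt(length(intersect(toks(p1$predicted_text[1]), toks(p1$curated_text[1]))), 0)

  # null mode: matched and mismatched cosines agree in distribution
  embed <- mock_embed_provider()
  nul <- make_validation_pairs(fixture_config(seed = 12, signal = "null"), 200)
  matched <- matched_similarities(nul, embed)
  bg <- permuted_background(nul, embed, mode = "sampled", n_samples = 400,
                            seed = 3)
  expect_equal(mean(matched), mean(bg), tolerance = 0.05)
})

test_that("fixture bundle writes parseable files in all dialects", {
  cfg <- fixture_config(seed = 21)
  dir <- file.path(tempdir(), "bundle21")
  paths <- write_fixture_bundle(cfg, dir, query_gene = "QB",
                                n_validation_genes = 5)
  expect_true(all(file.exists(paths)))

  kb <- load_knowledgebase(paths[["kb"]])
  expect_length(kb$pathways, cfg$n_pathways)
  mitab <- parse_psimitab(paths[["mitab"]])
  tab3 <- parse_biogrid_tab3(paths[["tab3"]])
  fi <- parse_reactome_fi(paths[["fi"]])
  # one network, three serializations: identical canonical pairs
  key <- function(s) paste(s$edges$gene_a, s$edges$gene_b)
  expect_identical(key(mitab), key(tab3))
  expect_identical(key(mitab), key(fi))
  expect_length(fetch_abstracts(read_abstract_store(paths[["abstracts"]]),
                                "nonexistent"), 0)
  expect_equal(nrow(read_validation_pairs(paths[["pairs"]])), 5)
})
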