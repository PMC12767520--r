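test_that("shipped templates are byte-identical to the verbatim copies", {
  files <- c(ANNOTATED_PATHWAYS = "annotated_pathways.txt",
             PAIR_SUMMARY = "pair_summary.txt",
             CONDENSED_SUMMARY = "condensed_summary.txt",
             RELATIONSHIP_EXTRACTION = "relationship_extraction.txt")
  for (id in names(files)) {
    shipped <- prompt_template(id)$text
    ref_path <- test_path("fixtures", "prompts", files[[id]])
    ref <- readChar(ref_path, file.info(ref_path)$size, useBytes = TRUE)
    expect_identical(charToRaw(shipped), charToRaw(ref))
  }
})

test_that("rendering substitutes every placeholder byte-exactly", {
  tpl <- prompt_template("PAIR_SUMMARY")
  bindings <- list(total_words = 200, query_gene = "TANC1",
                   interacting_genes = c("PSD95", "HOMER1"),
                   pathway = "Synaptic scaffolding",
                   pathway_text = "scaffold assembly",
                   abstract_text = "PMID: 9: TANC1 binds PSD95")
  out <- render_prompt(tpl, bindings)
  expect_true(grepl("so that Reactome curators can create reactions", out,
                    fixed = TRUE))
  expect_true(grepl("query_gene: TANC1", out, fixed = TRUE))
  expect_true(grepl("interacting_genes: PSD95, HOMER1", out, fixed = TRUE))
  expect_false(grepl("\\{[a-z_]+\\}", out))
  expect_identical(out, render_prompt(tpl, bindings))

  expect_error(render_prompt(tpl, bindings[names(bindings) != "query_gene"]),
               "query_gene")
})

test_that("citation grammar extracts pmids and pathway names", {
  cit <- extract_citations(
    "A result [PMID: 123456] and another [PMID:77]; see [Signal Transduction].")
  expect_identical(cit$pmids, c("123456", "77"))
  expect_identical(cit$pathway_names, "Signal Transduction")
})

test_that("mock provider cites exactly the supplied context sources", {
  llm <- mock_llm_provider()
  expect_error(llm(""), "empty prompt")
  out <- llm("context\nPMID: 7: some grounded text")
  expect_true(grepl("[PMID: 7]", out, fixed = TRUE))
  expect_identical(out, llm("context\nPMID: 7: some grounded text"))
})

test_that("pair summaries are grounded against the abstract's pmid", {
  abs_rec <- list(pmid = "55", title = "t", abstract = "G9 binds G1")
  s <- summarize_pair("G9", c("G1", "G2"), "Alpha signaling",
                      "alpha cascade context", abs_rec, mock_llm_provider())
  expect_identical(s$cited_sources$pmids, "55")
  expect_length(s$grounding_report, 0)

  # fault-injection provider citing an unseen pmid is flagged
  liar <- function(prompt) "Result [PMID: 55] but also [PMID: 999]."
  s2 <- summarize_pair("G9", "G1", "Alpha", "ctx", abs_rec, liar)
  expect_identical(s2$grounding_report, "PMID: 999")

  # interacting genes are passed in sorted order (argument capture)
  seen <- NULL
  capture <- function(prompt) { seen <<- prompt; "ok" }
  summarize_pair("G9", c("ZZ", "AA", "MM"), "Alpha", "ctx", abs_rec, capture)
  expect_true(grepl("interacting_genes: AA, MM, ZZ", seen, fixed = TRUE))
})

test_that("condensation assembles PMID-prefixed paragraphs in rank order", {
  df <- data.frame(pmid = c("9", "5", "7"),
                   text = c("first summary", "second summary", "third summary"),
                   stringsAsFactors = FALSE)
  seen <- NULL
  capture <- function(prompt) { seen <<- prompt; "ok [PMID: 5]" }
  s <- condense_summaries(df, "G9", "G1", capture)
  ctx <- sub(".*\ncontext: ", "", seen)
  paras <- strsplit(ctx, "\n\n", fixed = TRUE)[[1]]
  expect_length(paras, 3)
  expect_identical(substr(paras, 1, 8),
                   c("PMID: 9:", "PMID: 5:", "PMID: 7:"))
  expect_length(s$grounding_report, 0)

  one <- condense_summaries(df[1, ], "G9", "G1", mock_llm_provider())
  expect_identical(one$cited_sources$pmids, "9")
  expect_length(one$grounding_report, 0)
})

test_that("annotated-gene summaries cover the gene's pathways and ground names", {
  kb <- tiny_kb()
  off <- summarize_annotated_gene(kb, "NOPE", mock_llm_provider())
  expect_identical(off$status, "not_annotated")
  expect_identical(off$text, "")

  seen <- NULL
  capture <- function(prompt) { seen <<- prompt; "x" }
  summarize_annotated_gene(kb, "G3", capture)   # G3 is in PWA and PWB
  expect_true(grepl("Pathway: Alpha signaling", seen, fixed = TRUE))
  expect_true(grepl("Pathway: Beta transport", seen, fixed = TRUE))

  s <- summarize_annotated_gene(kb, "G3", mock_llm_provider())
  expect_setequal(s$cited_sources$pathway_names,
                  c("Alpha signaling", "Beta transport"))
  expect_length(s$grounding_report, 0)

  liar <- function(prompt) "All about [Made Up Pathway]."
  expect_identical(summarize_annotated_gene(kb, "G3", liar)$grounding_report,
                   "Made Up Pathway")
})

test_that("cached_provider memoizes by prompt", {
  calls <- 0L
  slow <- function(prompt) { calls <<- calls + 1L; toupper(prompt) }
  prov <- cached_provider(slow)
  expect_identical(prov("abc"), "ABC")
  expect_identical(prov("abc"), "ABC")
  expect_equal(calls, 1L)
  expect_identical(prov("abd"), "ABD")
  expect_equal(calls, 2L)
})
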