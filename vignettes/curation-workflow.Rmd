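---
title: "Predicting and triaging pathway annotations for a query gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and triaging pathway annotations for a query gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcurator)
```

## The problem

Pathway knowledgebases are curated from primary literature: for each gene a
curator must decide which pathways it acts in, find the papers that support
that placement, and distill the mechanism into reviewable prose. The
bottleneck is triage — most of the curator's time goes into finding the
right pathway candidates and the right papers. `pathcurator` implements a
triage pipeline that proposes candidate pathways from interaction data,
ranks candidate abstracts by relevance to each candidate, and drafts
citation-grounded summaries for human review. It is an assistant, not an
annotator: every output is designed to be checked.

## The enrichment model

The core statistical claim is that a gene tends to act in pathways where
its interaction partners already act. Let `N` be the number of genes
annotated anywhere in the knowledgebase, `m` the number annotated in a
candidate pathway, and `k` the number of the query gene's interaction
partners that are annotated genes. If partners were placed at random, the
overlap `x` between partners and the pathway would follow
`Binomial(k, m/N)`; the pathway's p-value is the exact upper tail
`P(X >= x)`.

Three modeling choices matter:

* **Only annotated partners count as trials.** A partner absent from the
  knowledgebase carries no information about pathway membership, so it
  neither inflates nor deflates the test.
* **Only pathways with an entity-level view containing reactions are
  candidates.** Pathway hierarchies nest broad container pathways around the
  specific ones curators annotate into; without this filter the containers
  dominate every ranking.
* **Pathways with zero overlap are not tested**, and the
  Benjamini–Hochberg adjustment runs over the family actually tested,
  before top-`k` truncation. Untested pathways have no p-value; adjusting
  before truncation keeps the FDR interpretable as a property of the full
  candidate family.

Ranking is ascending by `(p_value, pathway_id)`; the id tie-break makes
output order reproducible. Defaults `top_pathways = 10` and
`max_fdr = 0.05` are ordinary desk-scale settings, adjustable per run.

Interaction input can be experimentally supported PPIs (PSI-MI TAB 2.7 or
BioGRID TAB3; only human–human rows, symbols from the files' own
alias/symbol columns, no external identifier mapping) or scored functional
interactions (FI TSV). PPIs may optionally be filtered to pairs whose FI
score reaches `min_fi_score` — FI evidence as a confidence gate on
experimentally curated edges. When both PPI sources are selected they are
unioned, with PMIDs merged per canonical pair.

## Two-way relevance scoring

Abstract relevance to a candidate pathway is judged against the
*pathway-context text*: the pathway summary concatenated (newline-joined,
sorted by gene symbol) with the reaction-role descriptions of the query
gene's partners in that pathway. Scoring is two-way:

1. **Embedding cosine.** The abstract is split into token windows
   (`chunk_tokens = 256`, `overlap_tokens = 10`; whitespace tokenizer when
   no model tokenizer is configured); the score is the mean cosine between
   each chunk's embedding and the single embedding of the context text.
   Contexts are short, so the pathway side is not chunked.
2. **LLM judge.** A provider scores the (abstract, context) pair on a
   declared integer scale, 0–5 by default.

A match passes only if *both* scores meet their thresholds
(`min_cosine = 0.2`, `min_judge = 2` by default); passing matches are
ranked by cosine, then judge score, then PMID and pathway id. The
AND-threshold plus lexicographic rank is a deliberate reading of "use both
scores": each score can veto, and neither is collapsed into a weighted sum
whose weights we could not justify.

Zero-norm embeddings (texts with no alphanumeric tokens) score 0, never
`NaN`; an abstract yielding zero chunks scores 0 with a warning.

## Providers and grounding

Every external capability is a function contract: `search(query, n)`,
`embed(texts)`, `judge(abstract, context, gene)`, `complete(prompt)`. The
shipped mocks are deterministic — substring-count search, hashed
bag-of-words embedding (64 buckets, L2-normalized), token-Jaccard judge, and
an LLM mock that echoes back citations for exactly the source markers in
its prompt. Remote providers can be slotted in (and wrapped in
`cached_provider()` for reproducibility), but no test or example requires
one.

The four instruction templates ship verbatim in `inst/prompts/` and render
by byte-exact placeholder substitution; rendering fails loudly on a missing
binding or a residual placeholder. Generated text is grounded lexically: a
fixed bracket grammar extracts `[PMID: n]` and `[Pathway Name]` citation
tokens, and any token not present in the supplied context lands in the
summary's grounding report. This catches fabricated citations; it does not
attempt semantic hallucination detection, which is out of scope.

Full-text relationship extraction follows the same pattern: documents are
plain text (PDF conversion is an adapter concern), the 12 chunks most
similar to the gene's interactions/reactions/pathways facet queries are
batched into one extraction prompt, and provider output is parsed against
the arrow grammar `GENE - type -> object`, with non-conforming lines
preserved in a raw remainder rather than dropped or raised.

## The validation statistic

To validate generated summaries at corpus scale, each gene's predicted
summary is compared with a curated reference summary: matched cosine
similarities (whole-text embeddings — validation compares documents
pairwise, so no chunking) against the permuted background of all `n(n-1)`
ordered mismatched pairs, with a two-sided Mann–Whitney U test. Two-sided
because the claim under test is a distribution shift, and the exact path
(no ties, `|x||y| <= 1e6`) falls back to a tie- and continuity-corrected
normal approximation otherwise; a fully degenerate comparison (every score
identical) returns p = 1 by convention. Above 400 genes the background is
sampled without replacement under a fixed seed instead of enumerated.

The matched and background samples share embeddings, so they are weakly
dependent; empirically this leaves the null p-value distribution uniform
(the suite checks a Kolmogorov–Smirnov test over 200 null replicates and a
rejection rate within [0.02, 0.09] over 500), but it is a known deviation
from the independence assumption of the test.

## What the synthetic fixtures emulate — and what they do not

The fixture generator creates all study inputs with a controllable
relevance signal. Relevance is carried by *vocabulary*: each pathway owns a
disjoint token pool used for its summary, its per-gene role texts, and its
relevant abstracts; irrelevant abstracts and off-topic document paragraphs
draw from a reserved pool. Under the bag-of-words mock embedder,
vocabulary overlap is exactly cosine similarity, so planted structure is
recoverable by construction. Default conditions: 5 pathways x 20 genes,
10 partners with `partner_enrichment = 0.8`, 6 relevant + 6 irrelevant
abstracts per query, 30-word pathway vocabularies; validation pairs use
25 private-vocabulary tokens plus 5 shared ones per text ("planted") or a
single 120-word shared pool ("null"). These are desk-scale sizes chosen
once to keep every property test's effect size realistic rather than
saturated: with enrichment 0.8, roughly 3% of seeds draw few enough target
partners that the planted pathway, while still top-ranked, does not clear
`max_fdr = 0.05` — which is why recovery properties are asserted on the
candidate *ranking*, and threshold behavior is tested separately as
monotonicity.

Passing on these fixtures shows the machinery is correct and deterministic.
It does **not** show that real abstracts separate as cleanly: real language
shares vocabulary across topics, real embedding models are not bags of
words, and real pathway gene sets overlap. Results with remote providers on
real corpora will be noisier in ways these tests cannot certify.

## Numerical and degenerate-input choices

* Binomial tails use the exact distribution function (no approximation);
  `x = 0` returns 1 by definition.
* Gene symbols are case-sensitive exact strings; synonym resolution is
  deliberately not attempted (a known failure mode of LLM-based triage is
  conflating a gene with its synonym, and silent synonym mapping would make
  such failures invisible).
* Edge canonicalization: self-edges dropped, pairs stored lexicographically,
  duplicates merged with PMIDs unioned and the maximum score retained.
* Empty intermediate results are statuses (`NO_PARTNERS`, `NO_PATHWAYS`,
  `NO_ABSTRACTS`, `NO_PASSING_MATCHES`), never errors: the absence of
  results is itself a curation-relevant finding (genes whose products act
  outside protein-protein reactions commonly have no annotated partners).
* All report serialization is canonical (fixed field order, sorted sets), so
  identical runs are byte-identical — reproducibility is asserted, not
  assumed.

## Known limitations

* The mock search provider ranks by raw substring counts; it stands in for
  a search engine's relevance ranking only at the contract level.
* The judge and embedding mocks share the bag-of-words view of text, so
  their scores are correlated on fixtures in a way a real embedder and a
  real LLM judge would not be.
* Grounding is citation-token membership, not factual verification.
* The enrichment model treats partners as exchangeable trials; it ignores
  interaction confidence except as a pre-filter, and pathway gene-set
  overlap is not modeled (a partner in two pathways contributes to both
  tests).

## A minimal run

```{r example, eval = FALSE}
cfg    <- fixture_config(seed = 7)
kb     <- make_knowledgebase(cfg)
net    <- make_interactions(cfg, kb, "QGENE1", "PW0001")
store  <- make_abstract_corpus(cfg, kb, "QGENE1", "PW0001")
report <- run_pipeline(pipeline_config(), "QGENE1", kb, net, store)
report$predicted_pathways
write_report_markdown(report, "QGENE1_report.md")
```
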