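#' Configuration for synthetic fixtures
#'
#' The generators emulate the workflow's real inputs — a pathway
#' knowledgebase, an interaction network around a query gene, an abstract
#' corpus, and validation text pairs — with a controllable relevance signal.
#' Relevance is carried by vocabulary: each pathway owns a disjoint core
#' vocabulary used for its summary, its gene-role texts and its "relevant"
#' abstracts, while irrelevant abstracts draw from a reserved off-topic pool.
#' Under the bag-of-words mock embedder this yields a clean cosine signal;
#' real embedding models will behave differently on real language.
#'
#' @param seed Integer RNG seed; the same config and seed reproduce fixtures
#'   byte-identically.
#' @param n_pathways Number of pathways (default 5).
#' @param genes_per_pathway Genes annotated per pathway (default 20, disjoint
#'   across pathways).
#' @param n_background_genes Reserved for network padding: extra unannotated
#'   genes available as interactor candidates (default 40).
#' @param vocab_size_per_pathway Words in each pathway's vocabulary
#'   (default 30).
#' @param n_relevant_abstracts,n_irrelevant_abstracts Corpus composition per
#'   query (defaults 6 and 6).
#' @param n_partners Interaction partners drawn for the query gene
#'   (default 10).
#' @param partner_enrichment Probability that a partner is drawn from the
#'   target pathway's gene set (default 0.8).
#' @param signal `"planted"` (matched validation pairs share per-gene
#'   vocabulary) or `"null"` (all texts from one shared pool).
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_pathways = 5L, genes_per_pathway = 20L,
                           n_background_genes = 40L,
                           vocab_size_per_pathway = 30L,
                           n_relevant_abstracts = 6L,
                           n_irrelevant_abstracts = 6L,
                           n_partners = 10L, partner_enrichment = 0.8,
                           signal = c("planted", "null")) {
  signal <- match.arg(signal)
  stopifnot(n_pathways >= 0, genes_per_pathway >= 0, n_background_genes >= 0,
            vocab_size_per_pathway >= 1, n_relevant_abstracts >= 0,
            n_irrelevant_abstracts >= 0, n_partners >= 0,
            partner_enrichment >= 0, partner_enrichment <= 1)
  structure(list(seed = as.integer(seed), n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 n_background_genes = as.integer(n_background_genes),
                 vocab_size_per_pathway = as.integer(vocab_size_per_pathway),
                 n_relevant_abstracts = as.integer(n_relevant_abstracts),
                 n_irrelevant_abstracts = as.integer(n_irrelevant_abstracts),
                 n_partners = as.integer(n_partners),
                 partner_enrichment = partner_enrichment, signal = signal),
            class = "fixture_config")
}

# run code under a deterministic local RNG stream derived from (seed, tag);
# restores the caller's RNG state on exit
.with_fixture_rng <- function(seed, tag, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  offset <- c(knowledgebase = 1L, interactions = 2L, corpus = 3L,
              pairs = 4L, doc = 5L)[[tag]]
  set.seed((as.integer(seed) * 7L + offset) %% .Machine$integer.max)
  force(code)
}

.pathway_vocab <- function(i, size) sprintf("pw%02dterm%02d", i, seq_len(size))
.offtopic_vocab <- function(size) sprintf("offtopic%02d", seq_len(size))

.sample_sentence <- function(vocab, n_words) {
  paste(sample(vocab, n_words, replace = TRUE), collapse = " ")
}

#' Generate a synthetic knowledgebase
#'
#' `n_pathways` pathways with disjoint gene sets (`P01G01`, ...) and disjoint
#' core vocabularies; each pathway gets a ~40-word summary and a short role
#' text per gene, all drawn from its own vocabulary. Both eligibility flags
#' are set.
#'
#' @param cfg A [fixture_config()].
#' @return A [knowledgebase()].
#' @export
make_knowledgebase <- function(cfg) {
  stopifnot(inherits(cfg, "fixture_config"))
  .with_fixture_rng(cfg$seed, "knowledgebase", {
    pathways <- lapply(seq_len(cfg$n_pathways), function(i) {
      vocab <- .pathway_vocab(i, cfg$vocab_size_per_pathway)
      genes <- sprintf("P%02dG%02d", i, seq_len(cfg$genes_per_pathway))
      roles <- vapply(genes, function(g) .sample_sentence(vocab, 8L),
                      character(1))
      pathway_record(
        pathway_id = sprintf("PW%04d", i),
        name = sprintf("Synthetic pathway %02d", i),
        gene_set = genes,
        summary_text = .sample_sentence(vocab, 40L),
        gene_roles = roles)
    })
    knowledgebase(pathways, release_label = sprintf("synthetic-%d", cfg$seed))
  })
}

#' Generate a synthetic interaction network for a query gene
#'
#' Draws `n_partners` distinct partners for the query gene: each partner
#' comes from the target pathway's gene set with probability
#' `partner_enrichment`, otherwise uniformly from the other annotated genes.
#' Edges carry functional-interaction scores sampled uniformly in
#' `[0.5, 1]` and one synthetic supporting PMID each.
#'
#' @param cfg A [fixture_config()].
#' @param kb The [make_knowledgebase()] output.
#' @param query_gene Query gene symbol (typically an unannotated symbol).
#' @param target_pathway Pathway id of the planted target.
#' @return An [interaction_set()].
#' @export
make_interactions <- function(cfg, kb, query_gene, target_pathway) {
  stopifnot(inherits(cfg, "fixture_config"), inherits(kb, "knowledgebase"))
  target <- kb$pathways[[target_pathway]]
  if (is.null(target)) stop("unknown target pathway: ", target_pathway, call. = FALSE)
  others <- setdiff(kb$annotated_genes, target$gene_set)
  .with_fixture_rng(cfg$seed, "interactions", {
    partners <- character()
    n_target_pool <- length(target$gene_set)
    while (length(partners) < cfg$n_partners &&
           length(partners) < n_target_pool + length(others)) {
      from_target <- stats::runif(1) < cfg$partner_enrichment
      pool <- if (from_target) target$gene_set else others
      pool <- setdiff(pool, partners)
      if (length(pool) == 0L) pool <- setdiff(c(target$gene_set, others), partners)
      partners <- c(partners, sample(pool, 1L))
    }
    n <- length(partners)
    interaction_set(rep(query_gene, n), partners,
                    source = "REACTOME_FI",
                    score = stats::runif(n, 0.5, 1),
                    pmids = lapply(seq_len(n), function(i) as.character(900000L + i)))
  })
}

#' Generate a synthetic abstract corpus
#'
#' Relevant abstracts are composed from the target pathway's vocabulary plus
#' the query gene symbol (and a couple of partner symbols); irrelevant
#' abstracts come from a reserved off-topic vocabulary. PMIDs are sequential
#' from a seed-derived base.
#'
#' @param cfg A [fixture_config()].
#' @param kb The knowledgebase.
#' @param query_gene Query gene symbol.
#' @param target_pathway Pathway id of the planted target.
#' @return An [abstract_store()]; relevant records carry attribute-free
#'   sequential PMIDs starting at the base, relevant first.
#' @export
make_abstract_corpus <- function(cfg, kb, query_gene, target_pathway) {
  stopifnot(inherits(cfg, "fixture_config"), inherits(kb, "knowledgebase"))
  target <- kb$pathways[[target_pathway]]
  if (is.null(target)) stop("unknown target pathway: ", target_pathway, call. = FALSE)
  idx <- match(target_pathway, names(kb$pathways))
  vocab <- .pathway_vocab(idx, cfg$vocab_size_per_pathway)
  off <- .offtopic_vocab(max(30L, cfg$vocab_size_per_pathway))
  base_pmid <- 100000L + (cfg$seed %% 1000L) * 100L
  .with_fixture_rng(cfg$seed, "corpus", {
    recs <- list()
    for (i in seq_len(cfg$n_relevant_abstracts)) {
      mention <- sample(target$gene_set, 2L)
      body <- paste(query_gene, .sample_sentence(vocab, 30L),
                    mention[1], .sample_sentence(vocab, 20L), mention[2])
      recs[[length(recs) + 1L]] <- list(
        pmid = as.character(base_pmid + length(recs)),
        title = paste(query_gene, "interactions in", target$name),
        abstract = body, year = 2020L + (i %% 5L))
    }
    for (i in seq_len(cfg$n_irrelevant_abstracts)) {
      recs[[length(recs) + 1L]] <- list(
        pmid = as.character(base_pmid + length(recs)),
        title = .sample_sentence(off, 6L),
        abstract = .sample_sentence(off, 50L), year = 2019L)
    }
    abstract_store(recs)
  })
}

#' Generate synthetic validation text pairs
#'
#' In `"planted"` mode each gene owns a private vocabulary shared by its
#' predicted and curated texts, so matched cosines exceed mismatched ones.
#' In `"null"` mode every text is drawn independently from one shared pool,
#' so matched and mismatched cosines are identically distributed.
#'
#' @param cfg A [fixture_config()]; `cfg$signal` selects the mode.
#' @param n_genes Number of gene pairs.
#' @return A [gene_text_pairs()] data.frame.
#' @export
make_validation_pairs <- function(cfg, n_genes) {
  stopifnot(inherits(cfg, "fixture_config"), n_genes >= 2)
  .with_fixture_rng(cfg$seed, "pairs", {
    genes <- sprintf("VG%03d", seq_len(n_genes))
    if (cfg$signal == "planted") {
      pred <- character(n_genes); cur <- character(n_genes)
      shared <- sprintf("common%02d", seq_len(20L))
      for (i in seq_len(n_genes)) {
        own <- sprintf("g%03dw%02d", i, seq_len(15L))
        pred[i] <- paste(.sample_sentence(own, 25L),
                         .sample_sentence(shared, 5L))
        cur[i] <- paste(.sample_sentence(own, 25L),
                        .sample_sentence(shared, 5L))
      }
    } else {
      pool <- sprintf("shared%03d", seq_len(120L))
      pred <- vapply(seq_len(n_genes), function(i) .sample_sentence(pool, 30L),
                     character(1))
      cur <- vapply(seq_len(n_genes), function(i) .sample_sentence(pool, 30L),
                    character(1))
    }
    gene_text_pairs(genes, pred, cur)
  })
}

#' Generate a synthetic full-text document
#'
#' A multi-paragraph plain-text document in which some paragraphs mention
#' the query gene together with target-pathway vocabulary and partner genes,
#' and the rest are off-topic.
#'
#' @param cfg A [fixture_config()].
#' @param kb The knowledgebase.
#' @param query_gene Query gene symbol.
#' @param target_pathway Pathway id of the planted target.
#' @param n_relevant,n_offtopic Paragraph counts (defaults 4 and 8).
#' @return A single string (paragraphs separated by blank lines).
#' @export
make_fulltext_document <- function(cfg, kb, query_gene, target_pathway,
                                   n_relevant = 4L, n_offtopic = 8L) {
  stopifnot(inherits(cfg, "fixture_config"), inherits(kb, "knowledgebase"))
  target <- kb$pathways[[target_pathway]]
  idx <- match(target_pathway, names(kb$pathways))
  vocab <- .pathway_vocab(idx, cfg$vocab_size_per_pathway)
  off <- .offtopic_vocab(max(30L, cfg$vocab_size_per_pathway))
  .with_fixture_rng(cfg$seed, "doc", {
    rel <- vapply(seq_len(n_relevant), function(i) {
      paste(query_gene, "interactions with", sample(target$gene_set, 1L),
            "in reactions and pathways:", .sample_sentence(vocab, 30L))
    }, character(1))
    irr <- vapply(seq_len(n_offtopic), function(i) {
      .sample_sentence(off, 35L)
    }, character(1))
    paras <- c(rel, irr)
    paste(paras[sample.int(length(paras))], collapse = "\n\n")
  })
}

#' Write a full fixture bundle to disk
#'
#' Materializes a synthetic scenario in the workflow's external file formats:
#' knowledgebase JSON, interaction files in all three dialects (PSI-MI TAB
#' 2.7, BioGRID TAB3, FI TSV), the abstract corpus as JSON-lines, and
#' validation pairs as TSV.
#'
#' @param cfg A [fixture_config()].
#' @param dir Output directory (created if needed).
#' @param query_gene Query gene symbol (default `"QGENE1"`).
#' @param target_pathway Target pathway id (default the first pathway).
#' @param n_validation_genes Validation pair count (default 20).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(cfg, dir, query_gene = "QGENE1",
                                 target_pathway = NULL,
                                 n_validation_genes = 20L) {
  stopifnot(inherits(cfg, "fixture_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kb <- make_knowledgebase(cfg)
  if (is.null(target_pathway)) target_pathway <- names(kb$pathways)[1]
  net <- make_interactions(cfg, kb, query_gene, target_pathway)
  store <- make_abstract_corpus(cfg, kb, query_gene, target_pathway)
  pairs <- make_validation_pairs(cfg, n_validation_genes)

  paths <- c(kb = file.path(dir, "knowledgebase.json"),
             mitab = file.path(dir, "interactions.mitab27.txt"),
             tab3 = file.path(dir, "interactions.biogrid.tab3.txt"),
             fi = file.path(dir, "interactions.fi.tsv"),
             abstracts = file.path(dir, "abstracts.jsonl"),
             pairs = file.path(dir, "validation_pairs.tsv"))
  write_knowledgebase(kb, paths[["kb"]])
  write_psimitab(net, paths[["mitab"]])
  write_biogrid_tab3(net, paths[["tab3"]])
  write_reactome_fi(net, paths[["fi"]])
  write_abstract_store(store, paths[["abstracts"]])
  utils::write.table(pairs, paths[["pairs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write an interaction set as PSI-MI TAB 2.7
#'
#' Minimal 15-column MITAB emitter used for fixture generation; gene symbols
#' go to the alias columns with `(gene name)` type, PMIDs to the
#' publication-identifier column, and both interactors are marked human.
#'
#' @param s An [interaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psimitab <- function(s, path) {
  stopifnot(inherits(s, "interaction_set"))
  e <- s$edges
  lines <- vapply(seq_len(nrow(e)), function(i) {
    pm <- if (length(e$pmids[[i]]) > 0L) {
      paste(paste0("pubmed:", e$pmids[[i]]), collapse = "|")
    } else "-"
    paste(c(paste0("uniprotkb:U", i, "A"), paste0("uniprotkb:U", i, "B"),
            "-", "-",
            paste0("uniprotkb:", e$gene_a[i], "(gene name)"),
            paste0("uniprotkb:", e$gene_b[i], "(gene name)"),
            'psi-mi:"MI:0018"(two hybrid)', "-", pm,
            "taxid:9606(human)", "taxid:9606(human)",
            'psi-mi:"MI:0915"(physical association)',
            'psi-mi:"MI:0469"(IntAct)', paste0("intact:EBI-", i), "-"),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an interaction set as BioGRID TAB3
#'
#' @param s An [interaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_biogrid_tab3 <- function(s, path) {
  stopifnot(inherits(s, "interaction_set"))
  e <- s$edges
  header <- paste(c("#BioGRID Interaction ID",
                    "Official Symbol Interactor A",
                    "Official Symbol Interactor B",
                    "Publication Source",
                    "Organism ID Interactor A", "Organism ID Interactor B"),
                  collapse = "\t")
  lines <- vapply(seq_len(nrow(e)), function(i) {
    pm <- if (length(e$pmids[[i]]) > 0L) {
      paste(paste0("PUBMED:", e$pmids[[i]]), collapse = "|")
    } else "-"
    paste(c(i, e$gene_a[i], e$gene_b[i], pm, 9606, 9606), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' Write an interaction set as a functional-interaction TSV
#'
#' Edges without a score are written with score 1.
#'
#' @param s An [interaction_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reactome_fi <- function(s, path) {
  stopifnot(inherits(s, "interaction_set"))
  e <- s$edges
  score <- ifelse(is.na(e$score), 1, e$score)
  lines <- c("gene_a\tgene_b\tscore",
             sprintf("%s\t%s\t%s", e$gene_a, e$gene_b,
                     formatC(score, format = "fg", digits = 15)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
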