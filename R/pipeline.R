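#' Pipeline configuration
#'
#' Validated bundle of every tunable threshold in the workflow, serialized
#' into each report for provenance. Mirrors a curation app's configuration
#' panel: interaction sources and the FI filter, how many top abstracts to
#' analyze, pathway-count and FDR cutoffs, and the two relevance thresholds.
#'
#' @param ppi_source `"intact"`, `"biogrid"`, `"both"` or `"fi"` (use the
#'   functional-interaction network directly).
#' @param use_fi_filter Filter PPI edges by FI score (default `FALSE`).
#' @param min_fi_score FI-score threshold for the filter (default 0.9).
#' @param top_abstracts Number of candidate abstracts analyzed (default 20).
#' @param top_pathways Maximum predicted pathways kept (default 10).
#' @param max_fdr FDR cutoff for predicted pathways (default 0.05).
#' @param min_cosine Embedding-similarity threshold for a match
#'   (default 0.2).
#' @param min_judge Judge-score threshold on the 0-5 scale (default 2).
#' @param chunk_tokens,overlap_tokens Abstract chunking parameters
#'   (defaults 256 and 10).
#' @param total_words_pair,total_words_condensed,total_words_annotated
#'   Target summary lengths (defaults 200, 300, 300).
#' @param seed Seed recorded for provenance and used by any stochastic
#'   provider (the mock providers are deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ppi_source = c("fi", "intact", "biogrid", "both"),
                            use_fi_filter = FALSE, min_fi_score = 0.9,
                            top_abstracts = 20L, top_pathways = 10L,
                            max_fdr = 0.05, min_cosine = 0.2, min_judge = 2,
                            chunk_tokens = 256L, overlap_tokens = 10L,
                            total_words_pair = 200L,
                            total_words_condensed = 300L,
                            total_words_annotated = 300L, seed = 1L) {
  ppi_source <- match.arg(ppi_source)
  stopifnot(min_fi_score >= 0, min_fi_score <= 1, top_abstracts >= 1,
            top_pathways >= 1, max_fdr > 0, max_fdr <= 1,
            min_cosine >= -1, min_cosine <= 1, min_judge >= 0,
            chunk_tokens > overlap_tokens, overlap_tokens >= 0)
  structure(list(ppi_source = ppi_source, use_fi_filter = isTRUE(use_fi_filter),
                 min_fi_score = min_fi_score,
                 top_abstracts = as.integer(top_abstracts),
                 top_pathways = as.integer(top_pathways), max_fdr = max_fdr,
                 min_cosine = min_cosine, min_judge = min_judge,
                 chunk_tokens = as.integer(chunk_tokens),
                 overlap_tokens = as.integer(overlap_tokens),
                 total_words_pair = as.integer(total_words_pair),
                 total_words_condensed = as.integer(total_words_condensed),
                 total_words_annotated = as.integer(total_words_annotated),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full curation pipeline for a query gene
#'
#' End-to-end orchestration: (1) if the gene is already annotated, summarize
#' its existing pathway annotations; (2) predict interacting pathways by
#' binomial enrichment of its interaction partners; (3) retrieve candidate
#' abstracts via the facet queries; (4) score every (abstract, pathway) pair
#' with the two-way cosine + judge scheme and rank passing matches;
#' (5) generate grounded pair summaries and a condensed gene-level summary;
#' (6) collect the interaction-evidence PMIDs per predicted pathway. Every
#' stage appends a structured log line. Empty intermediate results produce
#' distinct statuses (`NO_PARTNERS`, `NO_PATHWAYS`, `NO_ABSTRACTS`,
#' `NO_PASSING_MATCHES`), never an error.
#'
#' @param config A [pipeline_config()].
#' @param query_gene Query gene symbol.
#' @param kb A [knowledgebase()].
#' @param interactions An [interaction_set()] (already source-selected; use
#'   [filter_ppis_by_fi()] upstream or set `use_fi_filter` with `fis`).
#' @param store An [abstract_store()].
#' @param search A search provider (default: [mock_search_provider()] over
#'   `store`).
#' @param embed An embedding provider (default [mock_embed_provider()]).
#' @param judge A judge provider (default [mock_judge_provider()]).
#' @param llm An LLM provider (default [mock_llm_provider()]).
#' @param fis Optional FI [interaction_set()] used when
#'   `config$use_fi_filter` is set.
#' @return An object of class `annotation_report`.
#' @export
run_pipeline <- function(config, query_gene, kb, interactions, store,
                         search = mock_search_provider(store),
                         embed = mock_embed_provider(),
                         judge = mock_judge_provider(),
                         llm = mock_llm_provider(), fis = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(kb, "knowledgebase"),
            inherits(interactions, "interaction_set"),
            inherits(store, "abstract_store"))
  log <- character()
  note <- function(stage, ...) {
    log[[length(log) + 1L]] <<- paste0("[", stage, "] ", paste0(...))
  }
  report <- list(query_gene = query_gene, config = unclass(config),
                 status = "OK")

  if (config$use_fi_filter) {
    if (is.null(fis)) stop("use_fi_filter set but no 'fis' supplied", call. = FALSE)
    interactions <- filter_ppis_by_fi(interactions, fis, config$min_fi_score)
    note("fi_filter", "min_fi_score=", config$min_fi_score,
         " edges_kept=", nrow(interactions$edges))
  }

  # (a) summary of existing annotation, when the gene is already curated
  annotated <- summarize_annotated_gene(kb, query_gene, llm,
                                        config$total_words_annotated)
  note("annotated_gene", "status=", annotated$status)
  report$annotated_summary <- annotated

  # (b) pathway prediction
  enriched <- predict_interacting_pathways(kb, interactions, query_gene,
                                           config$top_pathways, config$max_fdr)
  note("predict_pathways", "status=", attr(enriched, "status"),
       " candidates=", nrow(enriched))
  report$predicted_pathways <- enriched
  if (attr(enriched, "status") == "no_partners") {
    report$status <- "NO_PARTNERS"
  } else if (nrow(enriched) == 0L) {
    report$status <- "NO_PATHWAYS"
  }

  # (e) interaction evidence PMIDs per predicted pathway
  partner_tab <- partners_of(interactions, query_gene)
  report$interaction_evidence <- lapply(seq_len(nrow(enriched)), function(i) {
    genes <- enriched$overlap_genes[[i]]
    pm <- sort(unique(unlist(
      partner_tab$pmids[partner_tab$partner %in% genes], use.names = FALSE)))
    list(pathway_id = enriched$pathway_id[i],
         pmids = if (is.null(pm)) character() else pm)
  })

  if (report$status != "OK") {
    report$log <- log
    return(structure(report, class = "annotation_report"))
  }

  # (c) literature retrieval + two-way scoring
  pmids <- search_gene_literature(search, query_gene,
                                  max_results = config$top_abstracts)
  abstracts <- fetch_abstracts(store, pmids, config$top_abstracts)
  note("literature", "queried=", length(pmids), " fetched=", length(abstracts),
       " missing=", length(attr(abstracts, "missing")))
  if (length(abstracts) == 0L) {
    report$status <- "NO_ABSTRACTS"
    report$log <- log
    return(structure(report, class = "annotation_report"))
  }

  contexts <- vapply(seq_len(nrow(enriched)), function(i) {
    pathway_context_text(kb$pathways[[enriched$pathway_id[i]]],
                         enriched$overlap_genes[[i]])
  }, character(1))

  grid <- expand.grid(a = seq_along(abstracts), p = seq_len(nrow(enriched)))
  matches <- data.frame(
    pmid = vapply(grid$a, function(i) abstracts[[i]]$pmid, character(1)),
    pathway_id = enriched$pathway_id[grid$p],
    stringsAsFactors = FALSE)
  matches$cosine_score <- vapply(seq_len(nrow(grid)), function(r) {
    score_abstract_pathway(abstracts[[grid$a[r]]]$abstract, contexts[grid$p[r]],
                           embed, config$chunk_tokens, config$overlap_tokens)
  }, numeric(1))
  matches$judge_score <- vapply(seq_len(nrow(grid)), function(r) {
    judge(abstracts[[grid$a[r]]]$abstract, contexts[grid$p[r]], query_gene)
  }, numeric(1))
  ranked <- rank_matches(matches, config$min_cosine, config$min_judge)
  note("relevance", "scored=", nrow(matches), " passed=", nrow(ranked))
  report$scored_matches <- ranked
  if (nrow(ranked) == 0L) {
    report$status <- "NO_PASSING_MATCHES"
    report$log <- log
    return(structure(report, class = "annotation_report"))
  }

  # (d) grounded summaries
  by_pmid <- new.env(parent = emptyenv())
  for (i in seq_along(abstracts)) {
    assign(abstracts[[i]]$pmid, abstracts[[i]], envir = by_pmid)
  }
  pair_rows <- lapply(seq_len(nrow(ranked)), function(i) {
    pid <- ranked$pathway_id[i]
    j <- match(pid, enriched$pathway_id)
    s <- summarize_pair(query_gene, enriched$overlap_genes[[j]],
                        enriched$name[j], contexts[j],
                        get(ranked$pmid[i], envir = by_pmid), llm,
                        config$total_words_pair)
    list(pmid = ranked$pmid[i], pathway_id = pid, summary = s)
  })
  pair_df <- data.frame(
    pmid = vapply(pair_rows, `[[`, character(1), "pmid"),
    text = vapply(pair_rows, function(r) r$summary$text, character(1)),
    stringsAsFactors = FALSE)
  all_partner_genes <- sort(unique(unlist(enriched$overlap_genes,
                                          use.names = FALSE)))
  condensed <- condense_summaries(pair_df, query_gene, all_partner_genes, llm,
                                  config$total_words_condensed)
  note("summaries", "pairs=", nrow(pair_df),
       " condensed_ungrounded=", length(condensed$grounding_report))
  report$pair_summaries <- pair_rows
  report$condensed_summary <- condensed
  report$log <- log
  structure(report, class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat("<annotation_report>", x$query_gene, "| status:", x$status, "|",
      nrow(x$predicted_pathways), "predicted pathway(s)\n")
  invisible(x)
}

.report_as_list <- function(report) {
  ep <- report$predicted_pathways
  list(
    query_gene = report$query_gene,
    status = report$status,
    config = report$config,
    annotated_summary = list(status = report$annotated_summary$status,
                             text = report$annotated_summary$text),
    predicted_pathways = lapply(seq_len(nrow(ep)), function(i) {
      list(pathway_id = ep$pathway_id[i], name = ep$name[i],
           overlap_genes = as.list(ep$overlap_genes[[i]]),
           x = ep$x[i], k = ep$k[i], m = ep$m[i], N = ep$N[i],
           p_value = ep$p_value[i], fdr = ep$fdr[i])
    }),
    scored_matches = if (is.null(report$scored_matches)) list() else
      lapply(seq_len(nrow(report$scored_matches)), function(i) {
        r <- report$scored_matches[i, ]
        list(pmid = r$pmid, pathway_id = r$pathway_id,
             cosine_score = round(r$cosine_score, 4),
             judge_score = r$judge_score, rank = r$rank)
      }),
    pair_summaries = if (is.null(report$pair_summaries)) list() else
      lapply(report$pair_summaries, function(p) {
        list(pmid = p$pmid, pathway_id = p$pathway_id, text = p$summary$text,
             ungrounded_citations = as.list(p$summary$grounding_report))
      }),
    condensed_summary = if (is.null(report$condensed_summary)) NULL else
      list(text = report$condensed_summary$text,
           ungrounded_citations =
             as.list(report$condensed_summary$grounding_report)),
    interaction_evidence = lapply(report$interaction_evidence, function(e) {
      list(pathway_id = e$pathway_id, pmids = as.list(e$pmids))
    }),
    log = as.list(report$log))
}

#' Write an annotation report as JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report An `annotation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "annotation_report"))
  json <- jsonlite::toJSON(.report_as_list(report), auto_unbox = TRUE,
                           pretty = TRUE, null = "null", digits = NA)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Write an annotation report as markdown
#'
#' Human-readable report mirroring a curation app's Summary/Details views.
#'
#' @param report An `annotation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_markdown <- function(report, path) {
  stopifnot(inherits(report, "annotation_report"))
  ep <- report$predicted_pathways
  lines <- c(paste0("# Curation report: ", report$query_gene),
             "", paste0("Status: `", report$status, "`"), "")
  if (report$annotated_summary$status == "ok") {
    lines <- c(lines, "## Existing annotation", "",
               report$annotated_summary$text, "")
  }
  lines <- c(lines, "## Predicted pathways", "")
  if (nrow(ep) == 0L) {
    lines <- c(lines, "_none_", "")
  } else {
    lines <- c(lines,
               "| pathway | x/k | m | p-value | FDR | overlap genes |",
               "|---|---|---|---|---|---|",
               vapply(seq_len(nrow(ep)), function(i) {
                 sprintf("| %s (%s) | %d/%d | %d | %.3g | %.3g | %s |",
                         ep$name[i], ep$pathway_id[i], ep$x[i], ep$k[i],
                         ep$m[i], ep$p_value[i], ep$fdr[i],
                         paste(ep$overlap_genes[[i]], collapse = ", "))
               }, character(1)), "")
  }
  if (!is.null(report$condensed_summary)) {
    lines <- c(lines, "## Summary", "", report$condensed_summary$text, "")
  }
  if (!is.null(report$pair_summaries) && length(report$pair_summaries) > 0L) {
    lines <- c(lines, "## Details", "")
    sm <- report$scored_matches
    for (p in report$pair_summaries) {
      row <- which(sm$pmid == p$pmid & sm$pathway_id == p$pathway_id)[1]
      lines <- c(lines,
                 sprintf("### PMID %s - %s", p$pmid, p$pathway_id),
                 "",
                 sprintf("cosine: %.4f | judge: %s | FDR: %.3g",
                         sm$cosine_score[row], sm$judge_score[row],
                         ep$fdr[match(p$pathway_id, ep$pathway_id)]),
                 "", p$summary$text, "")
    }
  }
  if (length(report$interaction_evidence) > 0L) {
    lines <- c(lines, "## Interaction evidence (PMIDs per pathway)", "",
               vapply(report$interaction_evidence, function(e) {
                 paste0("- ", e$pathway_id, ": ",
                        if (length(e$pmids) > 0L)
                          paste(e$pmids, collapse = ", ") else "none")
               }, character(1)), "")
  }
  lines <- c(lines, "## Log", "", paste0("    ", report$log))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
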