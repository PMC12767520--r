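#' Load a prompt template
#'
#' The four instruction templates that drive summary generation and
#' relationship extraction ship with the package verbatim; placeholders are
#' written `{name}`.
#'
#' @param template_id One of `"ANNOTATED_PATHWAYS"`, `"PAIR_SUMMARY"`,
#'   `"CONDENSED_SUMMARY"`, `"RELATIONSHIP_EXTRACTION"`.
#' @return An object of class `prompt_template` with elements `template_id`,
#'   `text` and `required_placeholders`.
#' @export
prompt_template <- function(template_id = c("ANNOTATED_PATHWAYS", "PAIR_SUMMARY",
                                            "CONDENSED_SUMMARY",
                                            "RELATIONSHIP_EXTRACTION")) {
  template_id <- match.arg(template_id)
  file <- switch(template_id,
                 ANNOTATED_PATHWAYS = "annotated_pathways.txt",
                 PAIR_SUMMARY = "pair_summary.txt",
                 CONDENSED_SUMMARY = "condensed_summary.txt",
                 RELATIONSHIP_EXTRACTION = "relationship_extraction.txt")
  path <- system.file("prompts", file, package = "pathcurator", mustWork = TRUE)
  text <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(text) <- "UTF-8"
  placeholders <- unique(regmatches(text, gregexpr("\\{[a-z_]+\\}", text))[[1]])
  structure(list(template_id = template_id, text = text,
                 required_placeholders = gsub("[{}]", "", placeholders)),
            class = "prompt_template")
}

#' Render a prompt template
#'
#' Byte-exact substitution of `{placeholder}` markers. Every required
#' placeholder must be bound; a missing binding is an error naming the
#' placeholder, and the rendered text is checked to contain no residual
#' placeholder markers.
#'
#' @param template A [prompt_template()].
#' @param bindings Named list/character vector of placeholder values.
#' @return The rendered prompt string.
#' @export
render_prompt <- function(template, bindings) {
  stopifnot(inherits(template, "prompt_template"))
  bindings <- lapply(bindings, function(x) paste(as.character(x), collapse = ", "))
  missing <- setdiff(template$required_placeholders, names(bindings))
  if (length(missing) > 0L) {
    stop("missing prompt binding(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- template$text
  for (nm in template$required_placeholders) {
    out <- gsub(paste0("{", nm, "}"), bindings[[nm]], out, fixed = TRUE)
  }
  leftover <- regmatches(out, gregexpr("\\{[a-z_]+\\}", out))[[1]]
  if (length(leftover) > 0L) {
    stop("unresolved placeholder(s) after rendering: ",
         paste(leftover, collapse = ", "), call. = FALSE)
  }
  out
}

#' Extract citation tokens from generated text
#'
#' Fixed bracket grammar: `[PMID: 123456]` cites an abstract;
#' any other bracketed token `[Some Pathway Name]` cites a pathway.
#'
#' @param text Generated text.
#' @return List with character vectors `pmids` and `pathway_names`.
#' @export
extract_citations <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  all_tokens <- regmatches(text, gregexpr("\\[[^]]+\\]", text))[[1]]
  inner <- substr(all_tokens, 2L, nchar(all_tokens) - 1L)
  is_pmid <- grepl("^PMID:\\s*[0-9]+$", inner)
  list(pmids = unique(sub("^PMID:\\s*", "", inner[is_pmid])),
       pathway_names = unique(trimws(inner[!is_pmid])))
}

#' Deterministic mock LLM provider
#'
#' Completes a prompt without any model by echoing a digest of the context it
#' was given: every `PMID: n` source marker found in the prompt is cited back
#' as `[PMID: n]`, and every `Pathway: <name>` marker as `[<name>]`. Because
#' the mock can only cite sources present in its prompt, grounding reports
#' are empty by construction — which is exactly what makes it useful for
#' offline grounding tests (fault-injection providers violate this on
#' purpose).
#'
#' @return A provider: `function(prompt)` returning deterministic text.
#' @export
mock_llm_provider <- function() {
  function(prompt) {
    stopifnot(is.character(prompt), length(prompt) == 1L)
    if (!nzchar(prompt)) stop("empty prompt", call. = FALSE)
    # source markers are "PMID: <n>: <text>"; the trailing colon keeps the
    # bracketed citation-format example in the instructions from matching
    pmids <- unique(regmatches(prompt,
                               gregexpr("PMID: [0-9]+(?=: )", prompt,
                                        perl = TRUE))[[1]])
    pmids <- sub("^PMID: ", "", pmids)
    pw <- unique(regmatches(prompt,
                            gregexpr("(?m)^Pathway: [^\n]+", prompt,
                                     perl = TRUE))[[1]])
    pw <- sub("^Pathway: ", "", pw)
    parts <- "Deterministic mock summary of the supplied context."
    if (length(pmids) > 0L) {
      parts <- c(parts, paste0("Evidence drawn from ",
                               paste(sprintf("[PMID: %s]", pmids), collapse = ", "),
                               "."))
    }
    if (length(pw) > 0L) {
      parts <- c(parts, paste0("Pathways covered: ",
                               paste(sprintf("[%s]", pw), collapse = ", "), "."))
    }
    paste(parts, collapse = " ")
  }
}

#' Cache an LLM provider by prompt
#'
#' Wraps any provider so repeated identical prompts hit an in-memory cache,
#' making remote use reproducible and cheap. The mock providers are already
#' deterministic; caching matters for remote ones.
#'
#' @param provider A provider function.
#' @return A caching provider with the same contract.
#' @export
cached_provider <- function(provider) {
  cache <- new.env(parent = emptyenv())
  function(prompt) {
    key <- paste0("p", .token_hash(prompt), "_", nchar(prompt))
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, provider(prompt), envir = cache)
    }
    get(key, envir = cache)
  }
}

.summary_output <- function(text, cited, known_pmids = NULL, known_pathways = NULL,
                            status = "ok") {
  ungrounded <- character()
  if (!is.null(known_pmids)) {
    bad <- setdiff(cited$pmids, as.character(known_pmids))
    if (length(bad) > 0L) ungrounded <- c(ungrounded, paste0("PMID: ", bad))
  }
  if (!is.null(known_pathways)) {
    ungrounded <- c(ungrounded, setdiff(cited$pathway_names, known_pathways))
  }
  structure(list(text = text, cited_sources = cited,
                 grounding_report = ungrounded, status = status),
            class = "summary_output")
}

#' @export
print.summary_output <- function(x, ...) {
  cat("<summary_output> status:", x$status, "|",
      length(x$grounding_report), "ungrounded citation(s)\n")
  cat(x$text, "\n")
  invisible(x)
}

#' Summarize one abstract-pathway match
#'
#' Renders the pair-summary template with the query gene, its interacting
#' genes annotated in the pathway (sorted), the pathway-context text and the
#' abstract (prefixed with its `PMID:` source marker so providers can cite
#' it), then runs the provider and checks grounding: any cited PMID other
#' than the abstract's own is flagged.
#'
#' @param query_gene Query gene symbol.
#' @param interacting_genes Partner genes annotated in the pathway.
#' @param pathway_name Display name of the pathway.
#' @param pathway_context The [pathway_context_text()] string.
#' @param abstract An abstract record (`pmid`, `title`, `abstract`).
#' @param provider An LLM provider function.
#' @param total_words Target summary length in words (default 200).
#' @return A `summary_output` with `text`, `cited_sources` and
#'   `grounding_report`.
#' @export
summarize_pair <- function(query_gene, interacting_genes, pathway_name,
                           pathway_context, abstract, provider,
                           total_words = 200L) {
  tpl <- prompt_template("PAIR_SUMMARY")
  prompt <- render_prompt(tpl, list(
    total_words = total_words,
    query_gene = query_gene,
    interacting_genes = paste(sort(unique(interacting_genes)), collapse = ", "),
    pathway = pathway_name,
    pathway_text = pathway_context,
    abstract_text = paste0("PMID: ", abstract$pmid, ": ", abstract$abstract)))
  text <- provider(prompt)
  .summary_output(text, extract_citations(text), known_pmids = abstract$pmid)
}

#' Condense pair summaries into one gene-level summary
#'
#' Assembles the context as `PMID: text` paragraphs in rank order, renders
#' the condensed-summary template, runs the provider, and flags any cited
#' PMID outside the supplied set.
#'
#' @param pair_summaries Data.frame with columns `pmid` and `text`, in rank
#'   order.
#' @param query_gene Query gene symbol.
#' @param interacting_genes Partner genes across the summarized pathways.
#' @param provider An LLM provider function.
#' @param total_words Target length (default 300).
#' @return A `summary_output`.
#' @export
condense_summaries <- function(pair_summaries, query_gene, interacting_genes,
                               provider, total_words = 300L) {
  stopifnot(is.data.frame(pair_summaries), nrow(pair_summaries) >= 1L,
            all(c("pmid", "text") %in% names(pair_summaries)))
  context <- paste(paste0("PMID: ", pair_summaries$pmid, ": ",
                          pair_summaries$text),
                   collapse = "\n\n")
  tpl <- prompt_template("CONDENSED_SUMMARY")
  prompt <- render_prompt(tpl, list(
    total_words = total_words,
    query_gene = query_gene,
    interacting_genes = paste(sort(unique(interacting_genes)), collapse = ", "),
    context = context))
  text <- provider(prompt)
  .summary_output(text, extract_citations(text),
                  known_pmids = pair_summaries$pmid)
}

#' Summarize a gene's existing pathway annotations
#'
#' For a gene already annotated in the knowledgebase, assembles a context of
#' per-pathway `Pathway:`/`Summary:`/`Role:` blocks and renders the
#' annotated-pathways template. Citations are expected in `[Pathway name]`
#' form and are checked against the supplied names. A gene absent from the
#' knowledgebase returns a `not_annotated` status without calling the
#' provider.
#'
#' @param kb A [knowledgebase()].
#' @param gene Gene symbol.
#' @param provider An LLM provider function.
#' @param total_words Target length (default 300).
#' @return A `summary_output`; `status` is `"not_annotated"` when the gene
#'   has no annotations.
#' @export
summarize_annotated_gene <- function(kb, gene, provider, total_words = 300L) {
  stopifnot(inherits(kb, "knowledgebase"))
  if (!gene %in% kb$annotated_genes) {
    return(.summary_output("", list(pmids = character(),
                                    pathway_names = character()),
                           status = "not_annotated"))
  }
  in_pw <- Filter(function(p) gene %in% p$gene_set, kb$pathways)
  blocks <- vapply(in_pw, function(p) {
    role <- if (gene %in% names(p$gene_roles)) p$gene_roles[[gene]] else ""
    paste0("Pathway: ", p$name, "\nSummary: ", p$summary_text,
           if (nzchar(role)) paste0("\nRole: ", role) else "")
  }, character(1))
  tpl <- prompt_template("ANNOTATED_PATHWAYS")
  prompt <- render_prompt(tpl, list(
    total_words = total_words, gene = gene,
    annotated_pathways_text = paste0("\n", paste(blocks, collapse = "\n\n"))))
  text <- provider(prompt)
  .summary_output(text, extract_citations(text),
                  known_pathways = vapply(in_pw, `[[`, character(1), "name"))
}
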