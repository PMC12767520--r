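#' Load and chunk a plain-text document
#'
#' Full-text input is pre-extracted plain text (one file per document); a
#' PDF-to-text step is an adapter concern outside this package, which keeps
#' the extraction path testable with text fixtures.
#'
#' @param path Path to a UTF-8 text file.
#' @param chunk_tokens,overlap_tokens Chunking parameters (see
#'   [chunk_text()]).
#' @return Chunk data.frame with columns `text`, `start_index` and
#'   `source_id` (the file name).
#' @export
load_fulltext_document <- function(path, chunk_tokens = 256L,
                                   overlap_tokens = 10L) {
  if (!file.exists(path)) stop("document not found: ", path, call. = FALSE)
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  chunks <- chunk_text(text, chunk_tokens, overlap_tokens)
  chunks$source_id <- rep(basename(path), nrow(chunks))
  chunks
}

#' Retrieve document chunks relevant to a gene's function
#'
#' Ranks document chunks by their maximum cosine similarity to the three
#' facet queries of [build_queries()] (the gene's interactions, reactions and
#' pathways) and returns the top `k`. Exhaustive scoring is used rather than
#' an approximate-nearest-neighbor index: identical semantics at desk scale.
#' Ties are broken by ascending `start_index`.
#'
#' @param doc_chunks Chunk data.frame (`text`, `start_index`).
#' @param query_gene Query gene symbol.
#' @param embed An embedding provider.
#' @param k Number of chunks to keep (default 12).
#' @return The top-`k` rows of `doc_chunks` with a `similarity` column, in
#'   rank order.
#' @export
retrieve_relevant_chunks <- function(doc_chunks, query_gene, embed, k = 12L) {
  stopifnot(is.data.frame(doc_chunks), k >= 1)
  if (nrow(doc_chunks) == 0L) {
    out <- doc_chunks
    out$similarity <- numeric()
    return(out)
  }
  queries <- build_queries(query_gene)
  vecs <- embed(c(queries, doc_chunks$text))
  qv <- vecs[seq_along(queries), , drop = FALSE]
  sim <- vapply(seq_len(nrow(doc_chunks)), function(i) {
    cv <- vecs[length(queries) + i, ]
    max(vapply(seq_along(queries), function(j) {
      cosine_similarity(qv[j, ], cv)
    }, numeric(1)))
  }, numeric(1))
  out <- doc_chunks
  out$similarity <- sim
  ord <- order(-sim, doc_chunks$start_index)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Parse arrow-format relationship lines
#'
#' Accepts exactly the grammar
#' `<query_gene> - <relationship_type> -> <object>`, optionally followed by
#' ` | context: term1; term2`. Lines that do not conform — including lines
#' whose subject is not the query gene — are preserved verbatim in the raw
#' remainder, never dropped and never an error.
#'
#' @param lines Character vector of provider output lines.
#' @param query_gene The expected subject gene.
#' @return List with `relationships` (data.frame: `subject_gene`,
#'   `relationship_type`, `object`, `context_terms` list-column) and
#'   `raw_remainder` (character vector of non-conforming lines).
#' @export
parse_relationships <- function(lines, query_gene) {
  stopifnot(is.character(lines), is.character(query_gene))
  pattern <- "^\\s*(\\S+)\\s+-\\s+(.+?)\\s+->\\s+(.+?)\\s*$"
  subj <- character(); type <- character(); obj <- character()
  ctx <- list(); remainder <- character()
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    body <- line
    context_terms <- character()
    if (grepl(" | context: ", line, fixed = TRUE)) {
      split_at <- regexpr(" | context: ", line, fixed = TRUE)
      body <- substr(line, 1L, split_at - 1L)
      context_terms <- trimws(strsplit(
        substr(line, split_at + attr(split_at, "match.length"), nchar(line)),
        ";", fixed = TRUE)[[1]])
      context_terms <- context_terms[nzchar(context_terms)]
    }
    m <- regmatches(body, regexec(pattern, body))[[1]]
    if (length(m) == 4L && m[2] == query_gene) {
      subj <- c(subj, m[2]); type <- c(type, m[3]); obj <- c(obj, m[4])
      ctx[[length(ctx) + 1L]] <- context_terms
    } else {
      remainder <- c(remainder, line)
    }
  }
  rel <- data.frame(subject_gene = subj, relationship_type = type,
                    object = obj, stringsAsFactors = FALSE)
  rel$context_terms <- ctx
  list(relationships = rel, raw_remainder = remainder)
}

#' Serialize relationships back to arrow-format lines
#'
#' Inverse of [parse_relationships()] up to whitespace normalization.
#'
#' @param relationships The `relationships` data.frame from
#'   [parse_relationships()].
#' @return Character vector of lines.
#' @export
serialize_relationships <- function(relationships) {
  stopifnot(is.data.frame(relationships))
  vapply(seq_len(nrow(relationships)), function(i) {
    line <- paste0(relationships$subject_gene[i], " - ",
                   relationships$relationship_type[i], " -> ",
                   relationships$object[i])
    terms <- relationships$context_terms[[i]]
    if (length(terms) > 0L) {
      line <- paste0(line, " | context: ", paste(terms, collapse = "; "))
    }
    line
  }, character(1))
}

#' Deterministic mock extraction provider
#'
#' Stand-in for LLM relationship extraction: for each document chunk in the
#' prompt that mentions the query gene, emits one `co-occurs_with` arrow line
#' per other all-caps-like gene token in that chunk, in first-seen order.
#'
#' @return A provider: `function(prompt)` returning arrow-format lines.
#' @export
mock_extraction_provider <- function() {
  function(prompt) {
    stopifnot(is.character(prompt), length(prompt) == 1L, nzchar(prompt))
    gene <- sub(".*\nquery_gene: ([^\n]+)\n.*", "\\1", prompt)
    doc <- sub(".*\ndocument: ", "", prompt)
    out <- character()
    for (para in strsplit(doc, "\n", fixed = TRUE)[[1]]) {
      if (!grepl(gene, para, fixed = TRUE)) next
      tokens <- regmatches(para, gregexpr("\\b[A-Z][A-Z0-9-]{1,9}\\b", para))[[1]]
      others <- setdiff(unique(tokens), gene)
      out <- c(out, paste0(gene, " - co-occurs_with -> ", others))
    }
    paste(unique(out), collapse = "\n")
  }
}

#' Extract functional relationships from retrieved chunks
#'
#' Renders the relationship-extraction template over the retrieved chunks
#' (batched into one prompt, one chunk per line), runs the provider, and
#' parses the arrow-format output. Non-conforming output lines are kept in
#' `raw_remainder`.
#'
#' @param chunks Chunk data.frame (at least one row).
#' @param query_gene Query gene symbol.
#' @param provider An LLM provider function.
#' @return As [parse_relationships()], plus element `prompt`.
#' @export
extract_relationships <- function(chunks, query_gene, provider) {
  stopifnot(is.data.frame(chunks), nrow(chunks) >= 1L)
  tpl <- prompt_template("RELATIONSHIP_EXTRACTION")
  prompt <- render_prompt(tpl, list(
    query_gene = query_gene,
    document = paste(chunks$text, collapse = "\n")))
  raw <- provider(prompt)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  out <- parse_relationships(lines, query_gene)
  out$prompt <- prompt
  out
}
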