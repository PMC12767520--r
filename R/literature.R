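#' Build an abstract store from records
#'
#' A PMID-indexed local store of abstracts, the file-backed counterpart of the
#' PubMed-baseline database a production deployment would use. Lookup by PMID
#' is constant-time via an environment index.
#'
#' @param records List of records, each with fields `pmid`, `title`,
#'   `abstract` and optionally `year`.
#' @return An object of class `abstract_store`.
#' @export
abstract_store <- function(records = list()) {
  idx <- new.env(parent = emptyenv(), size = max(29L, length(records)))
  pmids <- character(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (is.null(r$pmid) || is.null(r$title) || is.null(r$abstract)) {
      stop("abstract record ", i, " lacks pmid/title/abstract", call. = FALSE)
    }
    pmid <- as.character(r$pmid)
    if (!nzchar(r$abstract)) {
      stop("abstract record ", pmid, " has empty abstract text", call. = FALSE)
    }
    if (exists(pmid, envir = idx, inherits = FALSE)) {
      stop("duplicate pmid in abstract store: ", pmid, call. = FALSE)
    }
    rec <- list(pmid = pmid, title = as.character(r$title),
                abstract = as.character(r$abstract),
                year = if (is.null(r$year)) NA_integer_ else as.integer(r$year))
    assign(pmid, rec, envir = idx)
    pmids[i] <- pmid
  }
  structure(list(index = idx, pmids = pmids), class = "abstract_store")
}

#' @export
print.abstract_store <- function(x, ...) {
  cat("<abstract_store>", length(x$pmids), "abstracts\n")
  invisible(x)
}

#' Read an abstract store from JSON-lines
#'
#' One record per line: `{"pmid": "...", "title": "...", "abstract": "...",
#' "year": 2020}`.
#'
#' @param path Path to the JSON-lines file.
#' @return An [abstract_store()].
#' @export
read_abstract_store <- function(path) {
  if (!file.exists(path)) stop("abstract store not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  abstract_store(lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE))
}

#' Write an abstract store to JSON-lines
#'
#' @param store An [abstract_store()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstract_store <- function(store, path) {
  stopifnot(inherits(store, "abstract_store"))
  lines <- vapply(store$pmids, function(pmid) {
    r <- get(pmid, envir = store$index)
    jsonlite::toJSON(list(pmid = jsonlite::unbox(r$pmid),
                          title = jsonlite::unbox(r$title),
                          abstract = jsonlite::unbox(r$abstract),
                          year = jsonlite::unbox(r$year)), null = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read abstracts from PubMed XML
#'
#' Optional adapter mapping `MedlineCitation` elements of a PubMed XML export
#' to store records. Requires the `xml2` package.
#'
#' @param path Path to the XML file.
#' @return An [abstract_store()].
#' @export
read_pubmed_xml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("read_pubmed_xml requires the 'xml2' package", call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, ".//MedlineCitation")
  recs <- lapply(cites, function(cite) {
    pmid <- xml2::xml_text(xml2::xml_find_first(cite, "./PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(cite, ".//ArticleTitle"))
    abs_nodes <- xml2::xml_find_all(cite, ".//Abstract/AbstractText")
    abstract <- paste(xml2::xml_text(abs_nodes), collapse = " ")
    year <- xml2::xml_text(xml2::xml_find_first(cite, ".//PubDate/Year"))
    list(pmid = pmid, title = title, abstract = abstract,
         year = if (is.na(year) || !nzchar(year)) NULL else as.integer(year))
  })
  recs <- Filter(function(r) nzchar(r$abstract), recs)
  abstract_store(recs)
}

#' Literature queries for a gene
#'
#' The fixed facet queries used against PubMed-style search: the gene's
#' interactions, reactions and pathways, in that order.
#'
#' @param gene Non-empty gene symbol.
#' @return Character vector of three query strings.
#' @export
build_queries <- function(gene) {
  if (!is.character(gene) || length(gene) != 1L || !nzchar(gene)) {
    stop("'gene' must be a non-empty gene symbol", call. = FALSE)
  }
  paste(gene, c("interactions", "reactions", "pathways"))
}

#' Fetch abstracts by PMID
#'
#' Returns records for the first `top_n` requested PMIDs present in the
#' store, preserving the input order. Missing PMIDs are reported via the
#' `missing` attribute, never fatal.
#'
#' @param store An [abstract_store()].
#' @param pmids Character vector of PMIDs, in ranked order.
#' @param top_n Number of found records to return (default all).
#' @return List of abstract records with attribute `missing`.
#' @export
fetch_abstracts <- function(store, pmids, top_n = length(pmids)) {
  stopifnot(inherits(store, "abstract_store"), top_n >= 1)
  pmids <- as.character(pmids)
  found <- list(); missing <- character()
  for (pmid in pmids) {
    if (length(found) >= top_n) break
    if (exists(pmid, envir = store$index, inherits = FALSE)) {
      found[[length(found) + 1L]] <- get(pmid, envir = store$index)
    } else {
      missing <- c(missing, pmid)
    }
  }
  structure(found, missing = missing)
}

#' Offline literature search over a local store
#'
#' Deterministic stand-in for a remote PubMed search: the query is lowercased
#' and split into terms; each abstract is scored by the total number of
#' occurrences of the terms in its title plus abstract text (fixed substring
#' match). Records with at least one occurrence are ranked by descending
#' match count, ties broken by ascending numeric PMID.
#'
#' @param store An [abstract_store()].
#' @return A search provider: `function(query, max_results)` returning an
#'   ordered character vector of PMIDs.
#' @export
mock_search_provider <- function(store) {
  stopifnot(inherits(store, "abstract_store"))
  function(query, max_results = 20L) {
    stopifnot(is.character(query), length(query) == 1L, max_results >= 1)
    terms <- strsplit(tolower(trimws(query)), "\\s+")[[1]]
    terms <- terms[nzchar(terms)]
    if (length(terms) == 0L) return(character())
    counts <- vapply(store$pmids, function(pmid) {
      r <- get(pmid, envir = store$index)
      hay <- tolower(paste(r$title, r$abstract))
      sum(vapply(terms, function(t) {
        m <- gregexpr(t, hay, fixed = TRUE)[[1]]
        sum(m > 0)
      }, numeric(1)))
    }, numeric(1))
    hit <- counts > 0
    pm <- store$pmids[hit]
    cn <- counts[hit]
    ord <- order(-cn, as.numeric(pm))
    utils::head(pm[ord], max_results)
  }
}

#' Run the facet queries and merge candidate PMIDs
#'
#' Runs all three facet queries of [build_queries()] through a search
#' provider and unions the PMID lists, preserving first-seen order.
#'
#' @param search A search provider function.
#' @param gene Query gene symbol.
#' @param max_results Per-query result cap.
#' @return Character vector of PMIDs.
#' @export
search_gene_literature <- function(search, gene, max_results = 20L) {
  queries <- build_queries(gene)
  unique(unlist(lapply(queries, search, max_results = max_results),
                use.names = FALSE))
}
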