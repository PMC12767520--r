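#' Construct a pathway record
#'
#' A pathway record holds everything the curation workflow needs to know about
#' a single pathway: its annotated gene set, the free-text summary used for
#' semantic scoring, per-gene reaction-role texts, and the two hierarchy flags
#' that determine whether the pathway is a candidate for enrichment (only
#' pathways with entity-level views that contain reactions are eligible).
#'
#' @param pathway_id Opaque stable identifier, unique within a knowledgebase.
#' @param name Display name.
#' @param gene_set Character vector of gene symbols annotated in the pathway.
#'   Symbols are case-sensitive exact strings; no synonym resolution is
#'   attempted.
#' @param summary_text Free-text pathway description.
#' @param gene_roles Named character vector or list mapping a gene symbol to a
#'   short text describing its role in reactions of this pathway. Every name
#'   must be a member of `gene_set`.
#' @param has_entity_level_view,contains_reactions Eligibility flags.
#' @return An object of class `pathway_record`.
#' @export
pathway_record <- function(pathway_id, name, gene_set, summary_text = "",
                           gene_roles = character(), has_entity_level_view = TRUE,
                           contains_reactions = TRUE) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L, nzchar(pathway_id))
  gene_set <- unique(as.character(gene_set))
  gene_roles <- vapply(as.list(gene_roles), as.character, character(1))
  bad <- setdiff(names(gene_roles), gene_set)
  if (length(bad) > 0L) {
    stop("pathway '", pathway_id, "': gene_roles keys not in gene_set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(pathway_id = pathway_id, name = as.character(name)[1],
         gene_set = gene_set, summary_text = as.character(summary_text)[1],
         gene_roles = gene_roles,
         has_entity_level_view = isTRUE(has_entity_level_view),
         contains_reactions = isTRUE(contains_reactions)),
    class = "pathway_record")
}

#' Assemble a knowledgebase from pathway records
#'
#' A knowledgebase is a flat snapshot of a pathway database: a collection of
#' [pathway_record()]s plus the derived universe of annotated genes (the union
#' of all pathway gene sets), which is the `N` of the binomial enrichment
#' model.
#'
#' @param pathways List of `pathway_record` objects with unique ids.
#' @param release_label Free-text label identifying the snapshot release.
#' @return An object of class `knowledgebase` with elements `pathways` (named
#'   by pathway id), `annotated_genes` (sorted character vector) and
#'   `release_label`.
#' @export
knowledgebase <- function(pathways = list(), release_label = "unreleased") {
  stopifnot(is.list(pathways))
  for (p in pathways) {
    if (!inherits(p, "pathway_record")) {
      stop("all elements of 'pathways' must be pathway_record objects", call. = FALSE)
    }
  }
  ids <- vapply(pathways, `[[`, character(1), "pathway_id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(pathways) <- ids
  genes <- sort(unique(unlist(lapply(pathways, `[[`, "gene_set"), use.names = FALSE)))
  if (is.null(genes)) genes <- character()
  structure(
    list(release_label = as.character(release_label)[1],
         pathways = pathways, annotated_genes = genes),
    class = "knowledgebase")
}

#' @export
print.knowledgebase <- function(x, ...) {
  cat("<knowledgebase> release:", x$release_label, "|",
      length(x$pathways), "pathways |", length(x$annotated_genes),
      "annotated genes\n")
  invisible(x)
}

#' Read a knowledgebase snapshot from JSON
#'
#' The snapshot format is a single UTF-8 JSON document:
#' `{"release_label": str, "pathways": [{"pathway_id", "name", "gene_set":
#' [..], "summary_text", "gene_roles": {gene: text}, "has_entity_level_view",
#' "contains_reactions"}]}`. Malformed records are rejected with an error that
#' names the offending record; nothing is silently dropped.
#'
#' @param path Path to the JSON snapshot.
#' @return A [knowledgebase()].
#' @export
load_knowledgebase <- function(path) {
  if (!file.exists(path)) stop("knowledgebase file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(doc) || is.null(doc$pathways)) {
    stop("not a knowledgebase snapshot (missing 'pathways'): ", path, call. = FALSE)
  }
  pathways <- lapply(seq_along(doc$pathways), function(i) {
    rec <- doc$pathways[[i]]
    needed <- c("pathway_id", "name", "gene_set", "summary_text",
                "gene_roles", "has_entity_level_view", "contains_reactions")
    missing <- setdiff(needed, names(rec))
    if (length(missing) > 0L) {
      stop("pathway record ", i, " (id: ",
           if (is.null(rec$pathway_id)) "<missing>" else rec$pathway_id,
           ") lacks fields: ", paste(missing, collapse = ", "), call. = FALSE)
    }
    roles <- vapply(rec$gene_roles, as.character, character(1))
    pathway_record(rec$pathway_id, rec$name,
                   unlist(rec$gene_set, use.names = FALSE),
                   rec$summary_text, roles,
                   rec$has_entity_level_view, rec$contains_reactions)
  })
  knowledgebase(pathways,
                release_label = if (is.null(doc$release_label)) "unreleased"
                                else doc$release_label)
}

#' Write a knowledgebase snapshot to JSON
#'
#' Canonical writer: fields are emitted in a fixed order with sorted gene sets
#' so that write -> load -> write round-trips byte-identically.
#'
#' @param kb A [knowledgebase()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knowledgebase <- function(kb, path) {
  stopifnot(inherits(kb, "knowledgebase"))
  recs <- lapply(unname(kb$pathways), function(p) {
    roles <- p$gene_roles[order(names(p$gene_roles))]
    list(pathway_id = jsonlite::unbox(p$pathway_id),
         name = jsonlite::unbox(p$name),
         gene_set = as.list(sort(p$gene_set)),
         summary_text = jsonlite::unbox(p$summary_text),
         gene_roles = as.list(roles),
         has_entity_level_view = jsonlite::unbox(p$has_entity_level_view),
         contains_reactions = jsonlite::unbox(p$contains_reactions))
  })
  doc <- list(release_label = jsonlite::unbox(kb$release_label), pathways = recs)
  json <- jsonlite::toJSON(doc, pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Pathways eligible for enrichment
#'
#' Pathway hierarchies nest broad container pathways around the detailed ones
#' curators actually annotate into; restricting candidates to pathways that
#' have an entity-level view and contain reactions controls for that
#' hierarchy.
#'
#' @param kb A [knowledgebase()].
#' @return List of `pathway_record`s with both eligibility flags set, in
#'   stored order.
#' @export
eligible_pathways <- function(kb) {
  stopifnot(inherits(kb, "knowledgebase"))
  Filter(function(p) p$has_entity_level_view && p$contains_reactions, kb$pathways)
}

#' Pathway-context text for relevance scoring
#'
#' The reference text an abstract is scored against: the pathway summary
#' followed by the reaction-role descriptions of those interaction partners
#' that are annotated in the pathway. Partners without a role entry contribute
#' nothing. Roles are appended in sorted gene-symbol order and joined with a
#' newline so the text is a pure, deterministic function of its inputs.
#'
#' @param p A [pathway_record()].
#' @param partners Character vector of partner gene symbols (non-empty).
#' @return A single string.
#' @export
pathway_context_text <- function(p, partners) {
  stopifnot(inherits(p, "pathway_record"))
  partners <- as.character(partners)
  if (length(partners) == 0L) stop("'partners' must be non-empty", call. = FALSE)
  with_roles <- sort(intersect(unique(partners), names(p$gene_roles)))
  paste(c(p$summary_text, unname(p$gene_roles[with_roles])), collapse = "\n")
}
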