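#' Upper-tail binomial probability
#'
#' Probability `P(X >= x)` for `X ~ Binomial(k, q)`: the enrichment p-value
#' when `x` of a gene's `k` annotated interaction partners fall in a pathway
#' whose gene set covers a fraction `q` of the annotated universe.
#'
#' @param x Observed success count, `0 <= x <= k`.
#' @param k Number of trials (annotated partners).
#' @param q Success probability in `[0, 1]`.
#' @return The exact upper-tail probability (full pmf mass from `x` to `k`).
#' @export
binomial_tail <- function(x, k, q) {
  if (!is.numeric(x) || !is.numeric(k) || !is.numeric(q) ||
      length(x) != 1L || length(k) != 1L || length(q) != 1L ||
      is.na(x) || is.na(k) || is.na(q) ||
      x < 0 || k < 0 || x > k || q < 0 || q > 1 ||
      x != round(x) || k != round(k)) {
    stop("binomial_tail requires 0 <= x <= k (integers) and q in [0, 1]",
         call. = FALSE)
  }
  if (x == 0) return(1)
  stats::pbinom(x - 1, size = k, prob = q, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values, order-aligned with the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Predict interacting pathways for a query gene
#'
#' For each eligible pathway (entity-level view with reactions), tests whether
#' the query gene's interaction partners are over-represented in the pathway's
#' gene set using the binomial model: with `N` annotated genes in the
#' knowledgebase, a pathway of (annotated) size `m`, and `k` partners that are
#' annotated genes, the overlap `x = |partners ∩ gene_set|` is compared to
#' `Binomial(k, m/N)`. Only partners that are annotated genes count as trials;
#' pathways with zero overlap are not tested. P-values are BH-adjusted over
#' the tested family, then candidates are sorted ascending by
#' `(p_value, pathway_id)`, truncated to `top_pathways`, and filtered to
#' `fdr <= max_fdr`.
#'
#' @param kb A [knowledgebase()].
#' @param interactions An [interaction_set()].
#' @param query_gene Query gene symbol.
#' @param top_pathways Maximum number of candidates to keep (default 10).
#' @param max_fdr FDR cutoff in `(0, 1]` (default 0.05).
#' @return A data.frame of class `enriched_pathways` with columns
#'   `pathway_id`, `name`, `x`, `k`, `m`, `N`, `p_value`, `fdr` and
#'   list-column `overlap_genes`, plus attribute `status`: `"ok"`,
#'   `"no_partners"` (no annotated partners — common for genes whose products
#'   act outside protein reactions) or `"no_overlap"`.
#' @export
predict_interacting_pathways <- function(kb, interactions, query_gene,
                                         top_pathways = 10, max_fdr = 0.05) {
  stopifnot(inherits(kb, "knowledgebase"), inherits(interactions, "interaction_set"),
            is.character(query_gene), length(query_gene) == 1L, nzchar(query_gene),
            top_pathways >= 1, max_fdr > 0, max_fdr <= 1)

  empty <- function(status) {
    out <- data.frame(pathway_id = character(), name = character(),
                      x = integer(), k = integer(), m = integer(),
                      N = integer(), p_value = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
    out$overlap_genes <- list()
    structure(out, status = status, query_gene = query_gene,
              class = c("enriched_pathways", "data.frame"))
  }

  partners <- unique(partners_of(interactions, query_gene)$partner)
  annotated_partners <- sort(intersect(partners, kb$annotated_genes))
  if (length(annotated_partners) == 0L) return(empty("no_partners"))

  elig <- eligible_pathways(kb)
  N <- length(kb$annotated_genes)
  k <- length(annotated_partners)

  rows <- lapply(elig, function(p) {
    genes <- intersect(p$gene_set, kb$annotated_genes)
    overlap <- sort(intersect(annotated_partners, genes))
    x <- length(overlap)
    if (x == 0L) return(NULL)
    m <- length(genes)
    list(pathway_id = p$pathway_id, name = p$name, x = x, k = k, m = m,
         N = N, p_value = binomial_tail(x, k, m / N), overlap = overlap)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(empty("no_overlap"))

  out <- data.frame(
    pathway_id = vapply(rows, `[[`, character(1), "pathway_id"),
    name = vapply(rows, `[[`, character(1), "name"),
    x = vapply(rows, `[[`, integer(1), "x"),
    k = vapply(rows, `[[`, integer(1), "k"),
    m = vapply(rows, `[[`, integer(1), "m"),
    N = vapply(rows, `[[`, integer(1), "N"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$overlap_genes <- lapply(rows, `[[`, "overlap")

  ord <- order(out$p_value, out$pathway_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, top_pathways)
  out <- out[out$fdr <= max_fdr, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, status = "ok", query_gene = query_gene,
            class = c("enriched_pathways", "data.frame"))
}

#' Write enriched pathways as TSV
#'
#' @param ep An `enriched_pathways` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enriched_tsv <- function(ep, path) {
  flat <- as.data.frame(ep[setdiff(names(ep), "overlap_genes")])
  flat$overlap_genes <- vapply(ep$overlap_genes, paste, character(1), collapse = ",")
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
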