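#' Build an interaction set from edge components
#'
#' An interaction set is a canonical, deduplicated collection of undirected
#' gene-gene edges. Each edge carries its source database, an optional
#' confidence score in `[0, 1]` (functional-interaction edges carry the
#' random-forest score; experimentally curated PPI edges usually carry none),
#' and the set of supporting PubMed identifiers. Self-edges are dropped; each
#' pair is stored with `gene_a < gene_b` lexicographically so that `(A, B)`
#' and `(B, A)` are the same edge; duplicate pairs are merged by unioning
#' PMIDs and keeping the maximum score.
#'
#' @param gene_a,gene_b Character vectors of gene symbols (recycled pairwise).
#' @param source Source label per edge: `"INTACT"`, `"BIOGRID"` or
#'   `"REACTOME_FI"`.
#' @param score Numeric score per edge in `[0, 1]`, or `NA` when absent.
#' @param pmids List of character vectors of supporting PMIDs (may be empty).
#' @param counts Optional named list of parser counters
#'   (`rows_read`, `edges_kept`, `rows_skipped`).
#' @return An object of class `interaction_set` with elements `edges` (a
#'   data.frame with columns `gene_a`, `gene_b`, `source`, `score` and a
#'   list-column `pmids`) and `counts`.
#' @export
interaction_set <- function(gene_a = character(), gene_b = character(),
                            source = character(), score = numeric(),
                            pmids = list(), counts = NULL) {
  n <- length(gene_a)
  stopifnot(length(gene_b) == n)
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  source <- rep_len(as.character(source), n)
  score <- rep_len(as.numeric(score), if (n) n else 0L)
  if (length(pmids) == 0L) pmids <- rep(list(character()), n)
  stopifnot(length(pmids) == n)
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) {
    stop("interaction score outside [0, 1]: ",
         paste(utils::head(score[bad], 3), collapse = ", "), call. = FALSE)
  }

  keep <- gene_a != gene_b & nzchar(gene_a) & nzchar(gene_b)
  gene_a <- gene_a[keep]; gene_b <- gene_b[keep]
  source <- source[keep]; score <- score[keep]; pmids <- pmids[keep]

  swap <- gene_a > gene_b
  tmp <- gene_a[swap]; gene_a[swap] <- gene_b[swap]; gene_b[swap] <- tmp

  key <- paste(gene_a, gene_b, sep = "\r")
  ord <- order(key, method = "radix")
  key <- key[ord]; gene_a <- gene_a[ord]; gene_b <- gene_b[ord]
  source <- source[ord]; score <- score[ord]; pmids <- pmids[ord]
  grp <- match(key, unique(key))
  first <- !duplicated(grp)

  merged_pmids <- lapply(split(pmids, grp), function(x) {
    v <- unique(unlist(x, use.names = FALSE))
    if (is.null(v)) character() else sort(v)
  })
  merged_score <- vapply(split(score, grp), function(s) {
    s <- s[!is.na(s)]
    if (length(s) == 0L) NA_real_ else max(s)
  }, numeric(1))

  edges <- data.frame(gene_a = gene_a[first], gene_b = gene_b[first],
                      source = source[first], score = unname(merged_score),
                      stringsAsFactors = FALSE)
  edges$pmids <- unname(merged_pmids)
  if (is.null(counts)) {
    counts <- list(rows_read = n, edges_kept = nrow(edges),
                   rows_skipped = n - sum(keep))
  }
  structure(list(edges = edges, counts = counts), class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("<interaction_set>", nrow(x$edges), "edges |",
      "rows read:", x$counts$rows_read,
      "| skipped:", x$counts$rows_skipped, "\n")
  invisible(x)
}

# First alias annotated "(gene name)" in a PSI-MI alias field like
# "uniprotkb:TP53(gene name)|uniprotkb:p53(gene name synonym)".
.mitab_gene_symbol <- function(field) {
  if (is.na(field) || field == "-") return(NA_character_)
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  hits <- grep("\\(gene name\\)$", parts, value = TRUE)
  if (length(hits) == 0L) return(NA_character_)
  sym <- sub("^[^:]*:", "", sub("\\(gene name\\)$", "", hits[1]))
  if (sym %in% c("", "-")) NA_character_ else sym
}

.mitab_is_human <- function(field) {
  # "-" (unspecified) is rejected: the import keeps human-human rows only
  grepl("taxid:9606\\b", field)
}

.extract_pmids <- function(field, prefix = "pubmed:") {
  if (is.na(field) || field == "-") return(character())
  parts <- strsplit(field, "|", fixed = TRUE)[[1]]
  hits <- parts[startsWith(tolower(parts), prefix)]
  ids <- sub("^[^:]*:", "", hits)
  unique(ids[grepl("^[0-9]+$", ids)])
}

#' Parse a PSI-MI TAB 2.7 interaction file
#'
#' Reads tab-delimited PSI-MI TAB 2.7 (15 or more columns). Gene symbols are
#' taken from the alias columns (entries of type `(gene name)`), supporting
#' PMIDs from the publication-identifier column, and only rows where both
#' interactors are human (`taxid:9606`) are kept. Rows for which both gene
#' symbols cannot be resolved are skipped and counted, never fatal. MITAB
#' confidence columns are ignored: PPI edges carry no intrinsic score here
#' (they are filtered with functional-interaction scores, if at all).
#'
#' @param path Path to the MITAB file. A leading `#` header line is allowed.
#' @return An [interaction_set()] with `source = "INTACT"` and parse counts.
#' @export
parse_psimitab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && startsWith(lines[1], "#")) lines <- lines[-1]
  rows_read <- length(lines)
  ga <- gb <- character(rows_read)
  pm <- vector("list", rows_read)
  ok <- logical(rows_read)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 15L) {
      stop("not a PSI-MI TAB 2.7 file: row ", i, " has ", length(f),
           " columns (need >= 15)", call. = FALSE)
    }
    if (!.mitab_is_human(f[10]) || !.mitab_is_human(f[11])) next
    a <- .mitab_gene_symbol(f[5]); b <- .mitab_gene_symbol(f[6])
    if (is.na(a)) a <- .mitab_gene_symbol(f[3])
    if (is.na(b)) b <- .mitab_gene_symbol(f[4])
    if (is.na(a) || is.na(b)) next
    ga[i] <- a; gb[i] <- b
    pm[[i]] <- .extract_pmids(f[9])
    ok[i] <- TRUE
  }
  s <- interaction_set(ga[ok], gb[ok], source = "INTACT",
                       score = rep(NA_real_, sum(ok)), pmids = pm[ok])
  s$counts <- list(rows_read = rows_read, edges_kept = nrow(s$edges),
                   rows_skipped = rows_read - sum(ok))
  s
}

#' Parse a BioGRID TAB3 interaction file
#'
#' Reads the named-header BioGRID TAB3 dialect. Gene symbols come from the
#' "Official Symbol Interactor A/B" columns, PMIDs from the
#' "Publication Source" column (entries like `PUBMED:12345`), and rows are
#' kept only when both "Organism ID Interactor" columns are human (9606).
#'
#' @param path Path to the TAB3 file (header row required, optionally
#'   starting with `#`).
#' @return An [interaction_set()] with `source = "BIOGRID"` and parse counts.
#' @export
parse_biogrid_tab3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  names(tab)[1] <- sub("^#", "", names(tab)[1])
  need <- c("Official Symbol Interactor A", "Official Symbol Interactor B",
            "Publication Source",
            "Organism ID Interactor A", "Organism ID Interactor B")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("not a BioGRID TAB3 file; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows_read <- nrow(tab)
  human <- tab[["Organism ID Interactor A"]] == 9606 &
           tab[["Organism ID Interactor B"]] == 9606
  a <- tab[["Official Symbol Interactor A"]]
  b <- tab[["Official Symbol Interactor B"]]
  resolvable <- !is.na(a) & !is.na(b) & a != "-" & b != "-" & nzchar(a) & nzchar(b)
  ok <- human & resolvable
  pm <- lapply(tab[["Publication Source"]][ok], function(x) {
    .extract_pmids(as.character(x), prefix = "pubmed:")
  })
  s <- interaction_set(a[ok], b[ok], source = "BIOGRID",
                       score = rep(NA_real_, sum(ok)), pmids = pm)
  s$counts <- list(rows_read = rows_read, edges_kept = nrow(s$edges),
                   rows_skipped = rows_read - sum(ok))
  s
}

#' Parse a functional-interaction TSV file
#'
#' Functional interactions (FIs) are gene pairs predicted by a random-forest
#' model over pairwise relationship features; each edge carries the model
#' score in `[0, 1]`. Expected columns: `gene_a`, `gene_b`, `score`.
#'
#' @param path Path to the TSV file.
#' @return An [interaction_set()] with `source = "REACTOME_FI"`.
#' @export
parse_reactome_fi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("not a functional-interaction TSV; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  score <- as.numeric(tab$score)
  if (anyNA(score) || any(score < 0 | score > 1)) {
    stop("FI scores must be numeric in [0, 1]", call. = FALSE)
  }
  s <- interaction_set(tab$gene_a, tab$gene_b, source = "REACTOME_FI",
                       score = score,
                       pmids = rep(list(character()), nrow(tab)))
  s$counts <- list(rows_read = nrow(tab), edges_kept = nrow(s$edges),
                   rows_skipped = nrow(tab) - nrow(s$edges))
  s
}

#' Filter PPI edges by functional-interaction score
#'
#' Keeps exactly the PPI edges whose canonical gene pair also appears in the
#' FI set with score at least `min_fi_score`; PMIDs come from the PPI edge.
#' Raising the threshold never adds edges.
#'
#' @param ppis [interaction_set()] of experimentally supported interactions.
#' @param fis [interaction_set()] of scored functional interactions.
#' @param min_fi_score Threshold in `[0, 1]`.
#' @return Filtered [interaction_set()].
#' @export
filter_ppis_by_fi <- function(ppis, fis, min_fi_score = 0.9) {
  stopifnot(inherits(ppis, "interaction_set"), inherits(fis, "interaction_set"),
            is.numeric(min_fi_score), min_fi_score >= 0, min_fi_score <= 1)
  fi_keep <- fis$edges[!is.na(fis$edges$score) & fis$edges$score >= min_fi_score, ]
  fi_key <- paste(fi_keep$gene_a, fi_keep$gene_b, sep = "\r")
  ppi_key <- paste(ppis$edges$gene_a, ppis$edges$gene_b, sep = "\r")
  keep <- ppi_key %in% fi_key
  out <- ppis
  out$edges <- ppis$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out$counts <- list(rows_read = nrow(ppis$edges), edges_kept = sum(keep),
                     rows_skipped = sum(!keep))
  out
}

#' Interaction partners of a gene
#'
#' @param s An [interaction_set()].
#' @param gene Gene symbol.
#' @return A data.frame with columns `partner`, `source`, `score` and
#'   list-column `pmids`, one row per edge incident to `gene`, sorted by
#'   partner symbol; zero rows when the gene is absent.
#' @export
partners_of <- function(s, gene) {
  stopifnot(inherits(s, "interaction_set"), is.character(gene), length(gene) == 1L)
  e <- s$edges
  hit_a <- e$gene_a == gene
  hit_b <- e$gene_b == gene
  partner <- c(e$gene_b[hit_a], e$gene_a[hit_b])
  idx <- c(which(hit_a), which(hit_b))
  out <- data.frame(partner = partner, source = e$source[idx],
                    score = e$score[idx], stringsAsFactors = FALSE)
  out$pmids <- e$pmids[idx]
  out <- out[order(out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of two interaction sets
#'
#' Merges edges from multiple sources (for example IntAct plus BioGRID) into
#' one canonical set; duplicate pairs are merged with PMIDs unioned.
#'
#' @param a,b [interaction_set()] objects.
#' @return Merged [interaction_set()].
#' @export
union_interactions <- function(a, b) {
  stopifnot(inherits(a, "interaction_set"), inherits(b, "interaction_set"))
  out <- interaction_set(c(a$edges$gene_a, b$edges$gene_a),
                         c(a$edges$gene_b, b$edges$gene_b),
                         source = c(a$edges$source, b$edges$source),
                         score = c(a$edges$score, b$edges$score),
                         pmids = c(a$edges$pmids, b$edges$pmids))
  out$counts <- list(rows_read = a$counts$rows_read + b$counts$rows_read,
                     edges_kept = nrow(out$edges),
                     rows_skipped = a$counts$rows_skipped + b$counts$rows_skipped)
  out
}
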