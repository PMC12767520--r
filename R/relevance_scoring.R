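#' Split text into overlapping token windows
#'
#' Token-window chunking in the style of sentence-transformer text splitters:
#' windows of `chunk_tokens` tokens advance by `chunk_tokens - overlap_tokens`
#' so that consecutive chunks share `overlap_tokens` tokens; the character
#' offset of each chunk's first token is recorded. A whitespace tokenizer is
#' used (the fallback when no model tokenizer is configured), so "tokens" are
#' whitespace-delimited words.
#'
#' @param text A single string.
#' @param chunk_tokens Window size in tokens (default 256, the sequence
#'   capacity of small sentence-embedding models).
#' @param overlap_tokens Overlap between consecutive windows (default 10).
#' @return A data.frame with columns `text` and `start_index` (0-based
#'   character offset); zero rows for empty text.
#' @export
chunk_text <- function(text, chunk_tokens = 256L, overlap_tokens = 10L) {
  stopifnot(is.character(text), length(text) == 1L,
            chunk_tokens > overlap_tokens, overlap_tokens >= 0)
  empty <- data.frame(text = character(), start_index = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  m <- gregexpr("\\S+", text)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  n <- length(starts)
  step <- chunk_tokens - overlap_tokens
  win_starts <- seq.int(1L, n, by = step)
  chunks <- vapply(win_starts, function(s) {
    e <- min(s + chunk_tokens - 1L, n)
    substr(text, starts[s], starts[e] + lens[e] - 1L)
  }, character(1))
  data.frame(text = chunks, start_index = starts[win_starts] - 1L,
             stringsAsFactors = FALSE)
}

# Deterministic string hash (poly-31 over UTF-8 bytes, mod 2^24),
# stable across platforms and sessions.
.token_hash <- function(token) {
  bytes <- as.integer(charToRaw(token))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 16777216
  h
}

#' Deterministic mock embedding provider (hashed bag-of-words)
#'
#' Embeds texts without any model: lowercase, split on non-alphanumeric
#' characters, hash each token into one of `dim` buckets, count, and
#' L2-normalize. Texts with no alphanumeric tokens map to the zero vector.
#' Two texts have cosine similarity 1 iff their token multisets hash to
#' proportional count vectors, and similarity 0 when their token sets hash to
#' disjoint buckets — which is what makes vocabulary-disjoint synthetic
#' fixtures carry a clean relevance signal.
#'
#' @param dim Number of hash buckets (default 64).
#' @return An embedding provider: `function(texts)` returning a
#'   `length(texts) x dim` numeric matrix.
#' @export
mock_embed_provider <- function(dim = 64L) {
  stopifnot(dim >= 1)
  force(dim)
  function(texts) {
    stopifnot(is.character(texts))
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      tokens <- strsplit(tolower(texts[i]), "[^a-z0-9]+")[[1]]
      tokens <- tokens[nzchar(tokens)]
      if (length(tokens) == 0L) next
      buckets <- vapply(tokens, .token_hash, numeric(1)) %% dim + 1
      counts <- tabulate(buckets, nbins = dim)
      nrm <- sqrt(sum(counts^2))
      out[i, ] <- counts / nrm
    }
    out
  }
}

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return `dot(a, b) / (|a| |b|)`; defined as 0 when either norm is 0.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors differ in dimension", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Average-cosine relevance of an abstract to a pathway context
#'
#' The abstract is chunked and each chunk embedded; the pathway-context text
#' (summary plus partner roles) is embedded as a single vector, and the score
#' is the arithmetic mean of the per-chunk cosines. An abstract yielding zero
#' chunks scores 0 with a warning.
#'
#' @param abstract_text Abstract text.
#' @param context_text Non-empty pathway-context text.
#' @param embed An embedding provider (see [mock_embed_provider()]).
#' @param chunk_tokens,overlap_tokens Chunking parameters.
#' @return Mean cosine similarity in `[-1, 1]`.
#' @export
score_abstract_pathway <- function(abstract_text, context_text, embed,
                                   chunk_tokens = 256L, overlap_tokens = 10L) {
  stopifnot(is.character(context_text), length(context_text) == 1L,
            nzchar(context_text))
  chunks <- chunk_text(abstract_text, chunk_tokens, overlap_tokens)
  if (nrow(chunks) == 0L) {
    warning("abstract produced zero chunks; relevance score set to 0")
    return(0)
  }
  vecs <- embed(c(context_text, chunks$text))
  ctx <- vecs[1, ]
  mean(vapply(seq_len(nrow(chunks)), function(i) {
    cosine_similarity(ctx, vecs[i + 1L, ])
  }, numeric(1)))
}

#' Deterministic mock LLM-judge provider
#'
#' Stand-in for a language-model relevance judge: scores an (abstract,
#' pathway-context) pair as the Jaccard similarity of their lowercase token
#' sets, rescaled to an integer `0..scale_max` by rounding. Fully
#' deterministic; identical texts score `scale_max`, token-disjoint texts 0.
#'
#' @param scale_max Top of the declared integer score scale (default 5).
#' @return A judge provider:
#'   `function(abstract_text, pathway_context, query_gene)` returning an
#'   integer score, with attributes `scale_max` on the provider.
#' @export
mock_judge_provider <- function(scale_max = 5L) {
  stopifnot(scale_max >= 1)
  force(scale_max)
  judge <- function(abstract_text, pathway_context, query_gene = NULL) {
    toks <- function(x) {
      t <- strsplit(tolower(x), "[^a-z0-9]+")[[1]]
      unique(t[nzchar(t)])
    }
    a <- toks(abstract_text); b <- toks(pathway_context)
    u <- union(a, b)
    if (length(u) == 0L) return(0L)
    as.integer(round(scale_max * length(intersect(a, b)) / length(u)))
  }
  attr(judge, "scale_max") <- scale_max
  judge
}

#' Filter and rank scored abstract-pathway matches
#'
#' The two-way match rule: a match passes iff its embedding cosine score and
#' its judge score both meet their thresholds; passing matches are ranked
#' descending by cosine score, then descending judge score, then ascending
#' PMID, then pathway id.
#'
#' @param matches Data.frame with columns `pmid`, `pathway_id`,
#'   `cosine_score`, `judge_score`.
#' @param min_cosine Cosine threshold (default 0.2).
#' @param min_judge Judge threshold (default 2).
#' @return The passing rows in rank order, with a `rank` column.
#' @export
rank_matches <- function(matches, min_cosine = 0.2, min_judge = 2) {
  stopifnot(is.data.frame(matches),
            all(c("pmid", "pathway_id", "cosine_score", "judge_score") %in%
                  names(matches)))
  keep <- matches$cosine_score >= min_cosine & matches$judge_score >= min_judge
  out <- matches[keep, , drop = FALSE]
  ord <- order(-out$cosine_score, -out$judge_score,
               as.numeric(out$pmid), out$pathway_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 0L) out$rank <- seq_len(nrow(out)) else out$rank <- integer()
  out
}
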