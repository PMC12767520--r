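#' Genes newly annotated between two releases
#'
#' The validation cohort: genes annotated in a later knowledgebase release
#' but not in the earlier baseline release.
#'
#' @param annotated_old,annotated_new Character vectors of gene symbols.
#' @return Sorted character vector `annotated_new \ annotated_old`.
#' @export
release_diff <- function(annotated_old, annotated_new) {
  sort(setdiff(as.character(annotated_new), as.character(annotated_old)))
}

#' Validation text pairs
#'
#' @param gene Gene symbols.
#' @param predicted_text Workflow-generated summary per gene (non-empty).
#' @param curated_text Curated-annotation summary per gene (non-empty).
#' @return Data.frame of class `gene_text_pairs`.
#' @export
gene_text_pairs <- function(gene, predicted_text, curated_text) {
  stopifnot(length(gene) == length(predicted_text),
            length(gene) == length(curated_text))
  if (any(!nzchar(predicted_text)) || any(!nzchar(curated_text))) {
    stop("predicted and curated texts must be non-empty", call. = FALSE)
  }
  structure(data.frame(gene = as.character(gene),
                       predicted_text = as.character(predicted_text),
                       curated_text = as.character(curated_text),
                       stringsAsFactors = FALSE),
            class = c("gene_text_pairs", "data.frame"))
}

#' Read validation pairs from TSV
#'
#' Expected columns: `gene`, `predicted_text`, `curated_text`.
#'
#' @param path Path to the TSV file.
#' @return A [gene_text_pairs()] data.frame.
#' @export
read_validation_pairs <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("gene", "predicted_text", "curated_text")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("validation pairs TSV missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gene_text_pairs(tab$gene, tab$predicted_text, tab$curated_text)
}

.embed_pair_matrix <- function(pairs, embed) {
  n <- nrow(pairs)
  vecs <- embed(c(pairs$predicted_text, pairs$curated_text))
  list(pred = vecs[seq_len(n), , drop = FALSE],
       cur = vecs[n + seq_len(n), , drop = FALSE], n = n)
}

#' Matched semantic similarities
#'
#' Cosine similarity between each gene's predicted and curated summary.
#' Whole summaries are embedded as single vectors (no chunking): validation
#' compares texts pairwise, unlike the chunked abstract-scoring path.
#'
#' @param pairs A [gene_text_pairs()] data.frame (>= 2 rows).
#' @param embed An embedding provider.
#' @return Numeric vector of per-gene cosines.
#' @export
matched_similarities <- function(pairs, embed) {
  stopifnot(inherits(pairs, "data.frame"), nrow(pairs) >= 2L)
  em <- .embed_pair_matrix(pairs, embed)
  vapply(seq_len(em$n), function(i) {
    cosine_similarity(em$pred[i, ], em$cur[i, ])
  }, numeric(1))
}

#' Permuted-background similarities
#'
#' The null distribution: cosine similarities of mismatched pairs
#' (gene `i`'s predicted summary against gene `j`'s curated summary,
#' `i != j`). Mode `"all_mismatched"` enumerates all `n(n-1)` ordered
#' mismatches; `"sampled"` draws `n_samples` of them without replacement
#' under `seed`.
#'
#' @param pairs A [gene_text_pairs()] data.frame (>= 2 rows).
#' @param embed An embedding provider.
#' @param mode `"all_mismatched"` or `"sampled"`.
#' @param n_samples,seed Sampling controls for `mode = "sampled"`.
#' @return Numeric vector of background cosines.
#' @export
permuted_background <- function(pairs, embed,
                                mode = c("all_mismatched", "sampled"),
                                n_samples = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(pairs, "data.frame"), nrow(pairs) >= 2L)
  em <- .embed_pair_matrix(pairs, embed)
  n <- em$n
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  ij <- ij[ij$i != ij$j, , drop = FALSE]
  if (mode == "sampled") {
    if (n_samples > nrow(ij)) n_samples <- nrow(ij)
    rows <- withr_seed_sample(seed, nrow(ij), n_samples)
    ij <- ij[rows, , drop = FALSE]
  }
  vapply(seq_len(nrow(ij)), function(r) {
    cosine_similarity(em$pred[ij$i[r], ], em$cur[ij$j[r], ])
  }, numeric(1))
}

# sample() under a local RNG state, leaving the caller's stream untouched
withr_seed_sample <- function(seed, n, size) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(n, size)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two score samples. `U` is computed with midranks
#' for ties; the two-sided p-value comes from exact enumeration when there
#' are no ties and `|x| * |y| <= max_exact`, otherwise from the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric score vectors (non-empty).
#' @param max_exact Product-size bound for the exact path (default `1e6`).
#' @return List with `u_statistic` (U for `x`), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y, max_exact = 1e6) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) >= 1L, length(y) >= 1L,
            !anyNA(x), !anyNA(y))
  ranks <- rank(c(x, y))
  u <- sum(ranks[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  has_ties <- any(duplicated(c(x, y)))
  exact <- !has_ties && length(x) * length(y) <= max_exact
  if (length(unique(c(x, y))) == 1L) {
    # fully degenerate: every observation tied; no evidence of shift
    return(list(u_statistic = unname(u), p_value = 1, method = "degenerate"))
  }
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE))
  list(u_statistic = unname(u), p_value = ht$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Run the semantic-similarity validation
#'
#' Composes the validation statistic end to end: matched cosines per gene, a
#' permuted background of mismatched cosines, a two-sided Mann-Whitney U test
#' between the two samples, and shared-bin histogram counts for plotting the
#' two distributions. The default background enumerates all ordered
#' mismatches for up to 400 genes and switches to sampling (fixed seed)
#' above that.
#'
#' @param pairs A [gene_text_pairs()] data.frame (>= 2 rows).
#' @param embed An embedding provider.
#' @param mode Background mode; `"auto"` (default) picks `all_mismatched`
#'   for `n <= 400`, else `sampled`.
#' @param n_samples,seed Sampling controls when sampling is used.
#' @param bins Number of histogram bins (default 20).
#' @return An object of class `validation_result`: `matched_scores`,
#'   `background_scores`, `u_statistic`, `p_value`, `n_genes`, `method` and
#'   `histogram` (data.frame `bin_low`, `bin_high`, `matched_count`,
#'   `background_count`).
#' @export
run_validation <- function(pairs, embed, mode = c("auto", "all_mismatched",
                                                  "sampled"),
                           n_samples = 1000L, seed = 1L, bins = 20L) {
  mode <- match.arg(mode)
  stopifnot(nrow(pairs) >= 2L, bins >= 1L)
  if (mode == "auto") {
    mode <- if (nrow(pairs) <= 400L) "all_mismatched" else "sampled"
  }
  matched <- matched_similarities(pairs, embed)
  background <- permuted_background(pairs, embed, mode = mode,
                                    n_samples = n_samples, seed = seed)
  test <- mann_whitney_u(matched, background)

  lo <- min(matched, background); hi <- max(matched, background)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = bins + 1L)
  hm <- graphics::hist(matched, breaks = breaks, plot = FALSE)$counts
  hb <- graphics::hist(background, breaks = breaks, plot = FALSE)$counts
  histogram <- data.frame(bin_low = breaks[-length(breaks)],
                          bin_high = breaks[-1L],
                          matched_count = hm, background_count = hb)

  structure(list(matched_scores = matched, background_scores = background,
                 u_statistic = test$u_statistic, p_value = test$p_value,
                 n_genes = nrow(pairs), method = test$method,
                 histogram = histogram),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat("<validation_result>", x$n_genes, "genes |",
      "matched median:", signif(stats::median(x$matched_scores), 4), "|",
      "background median:", signif(stats::median(x$background_scores), 4), "\n",
      "Mann-Whitney U:", x$u_statistic, "| two-sided p:",
      format(x$p_value, digits = 4), "(", x$method, ")\n")
  invisible(x)
}
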