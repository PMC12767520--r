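# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: log-space pmf summation, hand-rolled step-up,
# exhaustive rank enumeration, and naive O(pathways x genes) enrichment.

oracle_binomial_tail <- function(x, k, q) {
  if (x == 0) return(1)
  if (q == 0) return(0)
  if (q == 1) return(1)
  i <- x:k
  sum(exp(lchoose(k, i) + i * log(q) + (k - i) * log1p(-q)))
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- sorted * m / seq_len(m)
  # enforce monotonicity from the largest down (step-up)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# exact two-sided Mann-Whitney p by enumerating all assignments of the
# combined sample into the x-positions (ties not supported)
oracle_mwu_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  comb <- c(x, y)
  stopifnot(!any(duplicated(comb)))
  u_obs <- sum(rank(comb)[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(ii) {
    sum(rank(comb)[ii]) - m * (m + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# brute-force enrichment over every eligible pathway, no shortcuts
oracle_predict <- function(kb, partner_genes, top_pathways = 10, max_fdr = 0.05) {
  ann <- partner_genes[partner_genes %in% kb$annotated_genes]
  if (length(ann) == 0L) return(NULL)
  N <- length(kb$annotated_genes)
  k <- length(ann)
  rows <- list()
  for (p in kb$pathways) {
    if (!(p$has_entity_level_view && p$contains_reactions)) next
    genes <- intersect(p$gene_set, kb$annotated_genes)
    x <- length(intersect(ann, genes))
    if (x == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      pathway_id = p$pathway_id, x = x, k = k, m = length(genes), N = N,
      p_value = oracle_binomial_tail(x, k, length(genes) / N),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out$fdr <- oracle_bh(out$p_value)
  out <- out[order(out$p_value, out$pathway_id), ]
  out <- head(out, top_pathways)
  out <- out[out$fdr <= max_fdr, ]
  rownames(out) <- NULL
  out
}

# recompute the hashed bag-of-words embedding from first principles
oracle_hash_bucket <- function(token, dim = 64) {
  bytes <- as.integer(charToRaw(token))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 16777216
  h %% dim + 1
}

tiny_kb <- function() {
  knowledgebase(list(
    pathway_record("PWA", "Alpha signaling", c("G1", "G2", "G3"),
                   summary_text = "alpha cascade",
                   gene_roles = c(G1 = "G1 activates the alpha cascade",
                                  G2 = "G2 inhibits G1")),
    pathway_record("PWB", "Beta transport", c("G3", "G4"),
                   summary_text = "beta transport",
                   gene_roles = c(G4 = "G4 exports beta")),
    pathway_record("PWC", "Container only", c("G5"),
                   summary_text = "container",
                   has_entity_level_view = FALSE)),
    release_label = "test-1")
}

star_edges <- function(center, partners) {
  interaction_set(rep(center, length(partners)), partners,
                  source = "REACTOME_FI", score = rep(0.9, length(partners)),
                  pmids = lapply(seq_along(partners), function(i) as.character(i)))
}
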