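mitab_row <- function(a, b, pmids = "pubmed:12345", taxa = "taxid:9606(human)",
                      taxb = "taxid:9606(human)") {
  paste(c("uniprotkb:P1", "uniprotkb:P2", "-", "-",
          paste0("uniprotkb:", a, "(gene name)"),
          paste0("uniprotkb:", b, "(gene name)"),
          'psi-mi:"MI:0018"(two hybrid)', "-", pmids, taxa, taxb,
          'psi-mi:"MI:0915"(physical association)',
          'psi-mi:"MI:0469"(IntAct)', "intact:EBI-1", "-"),
        collapse = "\t")
}

test_that("PSI-MI TAB parser builds edges from alias gene names and pubmed ids", {
  f <- tempfile()
  writeLines(mitab_row("TP53", "MDM2"), f)
  s <- parse_psimitab(f)
  expect_equal(nrow(s$edges), 1)
  expect_identical(s$edges$gene_a, "MDM2")  # canonical lexicographic pair
  expect_identical(s$edges$gene_b, "TP53")
  expect_identical(s$edges$pmids[[1]], "12345")
  expect_identical(s$counts, list(rows_read = 1L, edges_kept = 1L,
                                  rows_skipped = 0L))

  # self-edges dropped; non-human rows skipped; unresolvable rows counted
  writeLines(c(mitab_row("TP53", "TP53"),
               mitab_row("TP53", "MDM2", taxb = "taxid:10090(mouse)"),
               mitab_row("-", "MDM2")), f)
  s2 <- parse_psimitab(f)
  expect_equal(nrow(s2$edges), 0)
  expect_equal(s2$counts$rows_skipped, 2)  # mouse + unresolvable; self-edge read then dropped

  # duplicate pair (reversed) merges pmids
  writeLines(c(mitab_row("TP53", "MDM2", "pubmed:1"),
               mitab_row("MDM2", "TP53", "pubmed:2")), f)
  s3 <- parse_psimitab(f)
  expect_equal(nrow(s3$edges), 1)
  expect_identical(s3$edges$pmids[[1]], c("1", "2"))

  writeLines("just,a,csv", f)
  expect_error(parse_psimitab(f), "PSI-MI")
})

test_that("BioGRID TAB3 parser honors header columns and species filter", {
  f <- tempfile()
  header <- paste(c("#BioGRID Interaction ID", "Official Symbol Interactor A",
                    "Official Symbol Interactor B", "Publication Source",
                    "Organism ID Interactor A", "Organism ID Interactor B"),
                  collapse = "\t")
  writeLines(c(header, "1\tBRCA1\tBARD1\tPUBMED:7545954\t9606\t9606"), f)
  s <- parse_biogrid_tab3(f)
  expect_equal(nrow(s$edges), 1)
  expect_identical(s$edges$gene_a, "BARD1")
  expect_identical(s$edges$pmids[[1]], "7545954")

  writeLines(header, f)
  expect_equal(nrow(parse_biogrid_tab3(f)$edges), 0)

  writeLines(c(header,
               "1\tBRCA1\tBARD1\tPUBMED:1\t9606\t9606",
               "2\tBARD1\tBRCA1\tPUBMED:2\t9606\t9606",
               "3\tBRCA1\tTrp53\tPUBMED:3\t9606\t10090"), f)
  s3 <- parse_biogrid_tab3(f)
  expect_equal(nrow(s3$edges), 1)
  expect_identical(s3$edges$pmids[[1]], c("1", "2"))
  expect_equal(s3$counts$rows_skipped, 1)
})

test_that("FI TSV parser populates scores and validates their range", {
  f <- tempfile()
  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t0.97", "C\tD\t0.5"), f)
  s <- parse_reactome_fi(f)
  expect_equal(nrow(s$edges), 2)
  expect_equal(s$edges$score[s$edges$gene_a == "A"], 0.97)
  expect_true(all(s$edges$source == "REACTOME_FI"))

  writeLines(c("gene_a\tgene_b\tscore", "A\tB\t1.2"), f)
  expect_error(parse_reactome_fi(f), "\\[0, 1\\]")
})

test_that("reversed-duplicate file parses identically to the deduplicated one", {
  f1 <- tempfile(); f2 <- tempfile()
  rows <- c("A\tB\t0.9", "A\tC\t0.7")
  writeLines(c("gene_a\tgene_b\tscore", rows), f1)
  writeLines(c("gene_a\tgene_b\tscore", rows, "B\tA\t0.9", "C\tA\t0.7"), f2)
  expect_identical(parse_reactome_fi(f1)$edges, parse_reactome_fi(f2)$edges)
})

test_that("FI filter keeps exactly the pairs passing the score threshold", {
  ppis <- interaction_set(c("A", "A", "B"), c("B", "C", "C"), "INTACT",
                          rep(NA_real_, 3),
                          list("10", "20", "30"))
  fis <- interaction_set(c("A", "A"), c("B", "C"), "REACTOME_FI",
                         c(0.95, 0.6), list(character(), character()))

  none <- filter_ppis_by_fi(ppis, interaction_set(), 0)
  expect_equal(nrow(none$edges), 0)

  all_kept <- filter_ppis_by_fi(ppis, fis, 0)
  expect_identical(sort(paste(all_kept$edges$gene_a, all_kept$edges$gene_b)),
                   c("A B", "A C"))

  strict <- filter_ppis_by_fi(ppis, fis, 0.9)
  expect_identical(paste(strict$edges$gene_a, strict$edges$gene_b), "A B")
  expect_identical(strict$edges$pmids[[1]], "10")  # pmids from the PPI edge

  # monotone: raising the threshold never adds edges
  sizes <- vapply(seq(0, 1, by = 0.1), function(t) {
    nrow(filter_ppis_by_fi(ppis, fis, t)$edges)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("partners_of is symmetric and returns incident edges", {
  expect_equal(nrow(partners_of(star_edges("Q", c("A", "B")), "ZZZ")), 0)
  star <- star_edges("Q", c("A", "B", "C", "D", "E"))
  p <- partners_of(star, "Q")
  expect_identical(p$partner, c("A", "B", "C", "D", "E"))

  set.seed(42)
  genes <- LETTERS[1:8]
  rnd <- interaction_set(sample(genes, 20, TRUE), sample(genes, 20, TRUE),
                         "BIOGRID", rep(NA_real_, 20),
                         as.list(as.character(1:20)))
  for (g in genes) {
    for (h in partners_of(rnd, g)$partner) {
      expect_true(g %in% partners_of(rnd, h)$partner)
    }
  }
})

test_that("union_interactions merges duplicate pairs across sources", {
  a <- interaction_set("X", "Y", "INTACT", NA_real_, list("1"))
  b <- interaction_set("Y", "X", "BIOGRID", NA_real_, list("2"))
  u <- union_interactions(a, b)
  expect_equal(nrow(u$edges), 1)
  expect_identical(u$edges$pmids[[1]], c("1", "2"))
})
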