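# Gene-locus clustering, span overlap, exact intron concordance and the
# concordance summary.

test_that("locus clustering is single-linkage on exonic overlap", {
  tx <- dplyr::bind_rows(
    transcript_tbl("A", "c1", c(0, 200), c(100, 300), "+"),
    transcript_tbl("B", "c1", c(250, 500), c(350, 600), "+"),
    transcript_tbl("C", "c1", 550, 650, "+"),
    transcript_tbl("D", "c1", 5000, 5100, "+"))
  loci <- cluster_loci(tx)
  by_tx <- setNames(loci$locus_id, loci$transcript_id)
  # A-B overlap, B-C overlap, A disjoint from C: one locus {A,B,C}
  expect_equal(unname(by_tx["A"]), unname(by_tx["C"]))
  expect_false(by_tx["A"] == by_tx["D"])
  # intron-only overlap does not cluster
  tx2 <- dplyr::bind_rows(
    transcript_tbl("E", "c1", c(0, 900), c(100, 1000), "+"),
    transcript_tbl("F", "c1", 400, 500, "+"))  # inside E's intron
  loci2 <- cluster_loci(tx2)
  expect_equal(dplyr::n_distinct(loci2$locus_id), 2L)
  # opposite strands never cluster directly
  tx3 <- dplyr::bind_rows(
    transcript_tbl("P", "c1", 0, 100, "+"),
    transcript_tbl("M", "c1", 50, 150, "-"))
  loci3 <- cluster_loci(tx3)
  b3 <- setNames(loci3$locus_id, loci3$transcript_id)
  expect_false(b3["P"] == b3["M"])
  # a '.'-strand transcript overlaps both and bridges them (single linkage)
  tx4 <- dplyr::bind_rows(tx3, transcript_tbl("U", "c1", 80, 120, "."))
  expect_equal(dplyr::n_distinct(cluster_loci(tx4)$locus_id), 1L)
})

test_that("locus clustering equals brute-force union-find on random sets", {
  set.seed(71)
  for (trial in 1:15) {
    tx <- rand_transcripts(sample(5:20, 1))
    mine <- cluster_loci(tx)
    mine_groups <- lapply(split(mine$transcript_id, mine$locus_id), sort)
    oracle_groups <- lapply(cluster_oracle(tx), sort)
    expect_setequal(
      unname(vapply(mine_groups, paste, character(1), collapse = ",")),
      unname(vapply(oracle_groups, paste, character(1), collapse = ",")))
  }
})

test_that("gene_id mode groups by assigned identifiers", {
  tx <- dplyr::bind_rows(
    transcript_tbl("A", "c1", 0, 100, "+", gene_id = "g1"),
    transcript_tbl("B", "c1", 5000, 5100, "+", gene_id = "g1"),
    transcript_tbl("C", "c1", 200, 300, "+", gene_id = "g2"))
  loci <- cluster_loci(tx, mode = "gene_id")
  by_tx <- setNames(loci$locus_id, loci$transcript_id)
  expect_equal(unname(by_tx["A"]), unname(by_tx["B"]))
  expect_false(by_tx["A"] == by_tx["C"])
})

make_annotation_fixture <- function() {
  bind_annotations(
    annotation_set("Ensembl",
                   tibble::tibble(chrom = "c1", start = c(0L, 500L),
                                  end = c(100L, 600L),
                                  gene_id = c("e1", "e2"), strand = "+"),
                   tibble::tibble(chrom = "c1", start = 100L, end = 200L,
                                  strand = "+")),
    annotation_set("RefSeq",
                   tibble::tibble(chrom = "c1", start = 99L, end = 150L,
                                  gene_id = "r1", strand = "-"),
                   tibble::tibble(chrom = "c1", start = 100L, end = 200L,
                                  strand = "-")),
    annotation_set("OtherRefSeq",
                   tibble::tibble(chrom = "c2", start = 0L, end = 50L,
                                  gene_id = "o1", strand = "+"),
                   tibble::tibble(chrom = "c1", start = 101L, end = 200L,
                                  strand = "+")))
}

test_that("gene-span overlap is strand-agnostic with a 1bp rule", {
  ann <- make_annotation_fixture()
  tx <- dplyr::bind_rows(
    transcript_tbl("t1", "c1", 99, 120, "+"),   # E (1bp) + R
    transcript_tbl("t2", "c1", 300, 400, "+"),  # none
    transcript_tbl("t3", "c2", 40, 90, "-"))    # O despite strand
  cats <- overlap_gene_annotations(tx, ann)
  by_tx <- setNames(cats$region, cats$transcript_id)
  expect_equal(unname(by_tx["t1"]), "ER")
  expect_equal(unname(by_tx["t2"]), "none")
  expect_equal(unname(by_tx["t3"]), "O")
})

test_that("span overlap agrees with an O(n^2) oracle on random intervals", {
  set.seed(72)
  for (trial in 1:5) {
    n <- 100
    spans <- tibble::tibble(
      chrom = sample(c("c1", "c2"), n, TRUE),
      start = sample(0:2000, n, TRUE))
    spans$end <- spans$start + sample(10:200, n, TRUE)
    spans$gene_id <- paste0("g", seq_len(n))
    spans$strand <- "."
    spans$source <- sample(c("Ensembl", "RefSeq", "OtherRefSeq"), n, TRUE)
    ann <- list(sources = c("Ensembl", "RefSeq", "OtherRefSeq"),
                gene_spans = spans,
                introns = tibble::tibble(chrom = character(),
                                         start = integer(), end = integer(),
                                         strand = character(),
                                         source = character()))
    tx <- rand_transcripts(40)
    cats <- overlap_gene_annotations(tx, ann)
    q <- transcript_spans(tx)
    expected <- overlap_oracle(q, spans)
    got <- lapply(cats$sources[match(q$transcript_id, cats$transcript_id)],
                  sort)
    expect_equal(got, expected)
  }
})

test_that("intron concordance is exact and strand-aware", {
  ann <- make_annotation_fixture()
  introns <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    chrom = "c1",
    start = c(100L, 101L, 100L, 102L),
    end = c(200L, 200L, 200L, 200L),
    strand = c("+", "+", "-", "+"))
  out <- intron_concordance(introns, ann)
  expect_equal(out$region, c("E", "O", "R", "none"))
  # '.'-strand introns match either strand
  dot <- intron_concordance(
    dplyr::mutate(introns[1, ], strand = "."), ann)
  expect_equal(dot$region, "ER")
})

test_that("the concordance summary conserves totals and breaks down the
          unannotated class", {
  ann <- make_annotation_fixture()
  tx <- dplyr::bind_rows(
    transcript_tbl("t1", "c1", c(0, 200), c(100, 300), "+"),
    transcript_tbl("t2", "c1", 320, 400, "+"),
    transcript_tbl("t3", "chrUn_9", 0, 80, "."))
  loci <- cluster_loci(tx)
  cats <- overlap_gene_annotations(
    tx, ann)
  isets <- intron_concordance(introns_of(tx), ann)
  s <- summarize_annotation(tx, loci, cats, isets)
  expect_equal(sum(s$transcript_venn$n), 3L)
  expect_equal(sum(s$intron_venn$n), nrow(introns_of(tx)))
  expect_equal(s$unannotated$n_none, 2L)
  expect_equal(s$unannotated$n_none_unplaced, 1L)
  expect_equal(s$unannotated$n_none_single_exon, 2L)
  # all transcripts single exon -> zero >=2-exon loci
  tx1 <- transcript_tbl("s", "c1", 0, 50, "+")
  s1 <- summarize_annotation(tx1, cluster_loci(tx1),
                             overlap_gene_annotations(tx1, ann),
                             intron_concordance(introns_of(tx1), ann))
  expect_equal(s1$loci_counts$n_loci, c(0L, 0L))
  # permutation invariance
  perm <- sample(nrow(tx))
  s2 <- summarize_annotation(tx[perm, ], loci, cats[sample(nrow(cats)), ],
                             isets)
  expect_equal(s2$transcript_venn, s$transcript_venn)
})
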