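# Spliced transcript sequences, coordinate maps, variant application,
# longest-ORF scanning, effect classification and reference-error calls.

test_that("spliced sequences concatenate exons and honor strand", {
  genome <- c(c1 = "ACGTTTGCA")
  tx_p <- transcript_tbl("p", "c1", c(0, 6), c(3, 9), "+")
  ts_p <- build_transcript_sequence(tx_p, genome)
  expect_equal(ts_p$seq, "ACGGCA")
  tx_m <- transcript_tbl("m", "c1", c(0, 6), c(3, 9), "-")
  ts_m <- build_transcript_sequence(tx_m, genome)
  expect_equal(ts_m$seq, "TGCCGT")
  # strand '.' stays in forward genomic orientation
  tx_d <- transcript_tbl("d", "c1", c(0, 6), c(3, 9), ".")
  expect_equal(build_transcript_sequence(tx_d, genome)$seq, "ACGGCA")
  expect_error(build_transcript_sequence(
    transcript_tbl("x", "c1", 0, 50, "+"), genome), "beyond|bounds")
})

test_that("the genomic/transcript coordinate map is a bijection", {
  set.seed(91)
  genome <- c(c1 = oracle_rand_dna(4000), c2 = oracle_rand_dna(4000))
  for (trial in 1:20) {
    tx <- rand_transcripts(1, chrom_len = 3000)
    ts <- build_transcript_sequence(tx, genome)
    L <- nchar(ts$seq)
    offs <- map_genomic_to_transcript(ts, ts$gmap)
    expect_setequal(offs, 0:(L - 1))
    # brute-force check for minus-strand orientation
    if (ts$strand == "-") {
      expect_equal(offs, (L - 1):0)
    } else {
      expect_equal(offs, 0:(L - 1))
    }
    # intronic / outside positions are absent
    sp <- transcript_spans(tx)
    outside <- sp$end + 10L
    expect_true(is.na(map_genomic_to_transcript(ts, outside)))
  }
  # first base of the first exon on '+' maps to offset 0
  tx1 <- transcript_tbl("t", "c1", c(100, 300), c(200, 400), "+")
  ts1 <- build_transcript_sequence(tx1, genome)
  expect_equal(map_genomic_to_transcript(ts1, 100L), 0L)
  expect_true(is.na(map_genomic_to_transcript(ts1, 250L)))
})

test_that("variant application edits the spliced sequence correctly", {
  genome <- c(c1 = "ACGTTTGCAACGT")
  tx <- transcript_tbl("t", "c1", c(0, 6), c(3, 10), "+")
  ts <- build_transcript_sequence(tx, genome)  # ACG GCAA
  # SNP keeps length
  snp <- apply_variant_to_transcript(ts, 2L, "C", "T")
  expect_equal(snp$status, "ok")
  expect_equal(snp$seq, "ATGGCAA")
  # 1bp deletion shortens by exactly 1
  del <- apply_variant_to_transcript(ts, 7L, "GC", "G")
  expect_equal(nchar(del$seq), nchar(ts$seq) - 1L)
  # insertion then its inverse deletion restores the original
  ins <- apply_variant_to_transcript(ts, 2L, "C", "CT")
  expect_equal(nchar(ins$seq), nchar(ts$seq) + 1L)
  # intronic variant is skipped
  expect_equal(apply_variant_to_transcript(ts, 5L, "T", "A")$status,
               "not_exonic")
  # variant straddling an exon boundary is skipped
  expect_equal(apply_variant_to_transcript(ts, 3L, "GTT", "G")$status,
               "boundary_overlap")
  # minus strand applies the reverse-complemented change
  tx_m <- transcript_tbl("m", "c1", c(0, 6), c(3, 10), "-")
  ts_m <- build_transcript_sequence(tx_m, genome)
  snp_m <- apply_variant_to_transcript(ts_m, 2L, "C", "T")
  expect_equal(snp_m$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGGCAA"))))
})

test_that("longest ORF matches brute-force enumeration in six frames", {
  expect_equal(longest_orf("ATGAAATAG", scan_both_strands = FALSE)$length, 9L)
  expect_null(longest_orf("CCCCCCCC"))
  set.seed(92)
  for (trial in 1:60) {
    s <- oracle_rand_dna(sample(30:1200, 1))
    expect_equal(longest_orf_length(s, scan_both_strands = TRUE),
                 orf_oracle(s, both = TRUE))
    expect_equal(longest_orf_length(s, scan_both_strands = FALSE),
                 orf_oracle(s, both = FALSE))
  }
})

test_that("longest ORF is invariant under benign suffix extension", {
  set.seed(93)
  base <- paste0("CC", "ATG", paste(rep("GGA", 30), collapse = ""), "TAA")
  l0 <- longest_orf_length(base, scan_both_strands = FALSE)
  expect_equal(l0, 3L + 90L + 3L)
  # suffix without ATG and without disturbing the frame
  suffix <- paste(rep("CCC", 10), collapse = "")
  expect_equal(longest_orf_length(paste0(base, suffix),
                                  scan_both_strands = FALSE), l0)
})

test_that("ORF effects classify extending, shortening and neutral variants", {
  # reference has a frameshift (extra C in a run) that truncates the ORF;
  # the deletion restores the designed long ORF
  utr5 <- "GGAGGAGG"
  cds_tail <- paste(rep("GAA", 20), collapse = "")
  clean <- paste0(utr5, "ATG", "GAT", "CCCC", "AA", cds_tail, "TAA", "GGAGG")
  refseq <- sub("CCCC", "CCCCC", clean)  # corrupted reference
  genome <- c(c1 = refseq)
  tx <- transcript_tbl("t", "c1", 0, nchar(refseq), "+")
  run_at <- as.integer(regexpr("CCCCC", refseq))
  del <- make_variants("c1", run_at - 1L,
                       paste0(substr(refseq, run_at - 1L, run_at - 1L), "C"),
                       substr(refseq, run_at - 1L, run_at - 1L))
  alle <- expand_alleles(del)
  alle <- normalize_alleles(alle, genome)
  eff <- classify_orf_effect(tx, genome, alle)
  expect_equal(eff$effect, "extending")
  expect_gt(eff$orf_alt, eff$orf_ref)
  # a deletion creating a premature in-frame stop shortens the ORF
  long_orf <- paste0("CC", "ATG", paste(rep("GAA", 30), collapse = ""),
                     "TAAGG")
  g2 <- c(c1 = long_orf)
  tx2 <- transcript_tbl("t2", "c1", 0, nchar(long_orf), "+")
  # delete one base early in the CDS: frameshift into random stops
  del2 <- make_variants("c1", 6L, substr(long_orf, 6, 7), substr(long_orf, 6, 6))
  eff2 <- classify_orf_effect(tx2, g2, normalize_alleles(
    expand_alleles(del2), g2), scan_both_strands = FALSE)
  expect_equal(eff2$effect, "shortening")
  # a SNP downstream of the stop with no new signal is neutral
  snp3 <- make_variants("c1", nchar(long_orf) - 1L,
                        substr(long_orf, nchar(long_orf) - 1L,
                               nchar(long_orf) - 1L), "C")
  eff3 <- classify_orf_effect(tx2, g2, normalize_alleles(
    expand_alleles(snp3), g2), scan_both_strands = FALSE)
  expect_equal(eff3$effect, "neutral")
})

empty_variants_for_test <- function() {
  make_variants(character(), integer(), character(), character())
}

test_that("reference-error calls take their class from genomic support", {
  genome <- c(c1 = paste0("GG", "ATG", "GAT", "CCCCC", "AA",
                          paste(rep("GAA", 25), collapse = ""), "TAA", "GG"))
  tx <- transcript_tbl("t", "c1", 0, nchar(genome[["c1"]]), "+")
  anchor <- 9L  # last base before the C run (0-based run start 9)
  del <- make_variants("c1", anchor, substr(genome[["c1"]], anchor, anchor + 1L),
                       substr(genome[["c1"]], anchor, anchor))
  alle <- normalize_alleles(expand_alleles(del), genome)
  effects <- classify_orf_effect(tx, genome, alle)
  expect_equal(effects$effect, "extending")
  gen_rec <- function(gt) {
    g <- del
    g$genotype <- gt
    g
  }
  hom <- call_reference_errors(effects, gen_rec("1/1"), genome)
  expect_equal(hom$support_class, "homozygous")
  expect_true(hom$candidate_reference_error)
  expect_true(hom$homopolymer_slip)
  het <- call_reference_errors(effects, gen_rec("0/1"), genome)
  expect_equal(het$support_class, "heterozygous")
  expect_false(het$candidate_reference_error)
  none <- call_reference_errors(effects, empty_variants_for_test(), genome)
  expect_equal(none$support_class, "unsupported")
})

test_that("mechanism flags: homopolymer adjacency and intron mimicry", {
  genome <- c(c1 = "AACCGGTTAACCGGTT")
  # deletion of one C flanked by C
  delC <- normalize_alleles(make_variants("c1", 2, "AC", "A"), genome)
  m1 <- classify_error_mechanism(delC, genome)
  expect_true(m1$homopolymer_slip)
  # deletion of one C between A and G (no run)
  g2 <- c(c1 = "AAACGGG")
  delSolo <- normalize_alleles(make_variants("c1", 3, "AC", "A"), g2)
  m2 <- classify_error_mechanism(delSolo, g2)
  expect_false(m2$homopolymer_slip)
  # insertion duplicating an adjacent base (left-aligns to the A anchor)
  insC <- normalize_alleles(make_variants("c1", 3, "C", "CC"), genome)
  expect_true(classify_error_mechanism(insC, genome)$homopolymer_slip)
  # SNPs never carry mechanism flags
  snp <- make_variants("c1", 5, "G", "T")
  m3 <- classify_error_mechanism(snp, genome)
  expect_false(m3$homopolymer_slip)
  expect_false(m3$intron_mimic)
  # 85bp deletion with an annotated 85bp intron starting 4bp away
  set.seed(94)
  g3 <- c(c1 = oracle_rand_dna(400))
  del85 <- tibble::tibble(
    chrom = "c1", pos = 100L,
    ref = substr(g3[["c1"]], 100, 185), alt = substr(g3[["c1"]], 100, 100))
  introns_hit <- tibble::tibble(chrom = "c1", start = 104L, end = 189L,
                                strand = "+")
  expect_true(classify_error_mechanism(del85, g3, introns_hit)$intron_mimic)
  # 11bp away: outside tolerance
  introns_far <- dplyr::mutate(introns_hit, start = 111L, end = 196L)
  expect_false(classify_error_mechanism(del85, g3, introns_far)$intron_mimic)
  # right length matters too
  introns_len <- dplyr::mutate(introns_hit, end = 190L)
  expect_false(classify_error_mechanism(del85, g3, introns_len)$intron_mimic)
})
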