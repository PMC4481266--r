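# Fragment linking: segment alignment, candidate rules, split-alignment
# refinement against annotated introns, junction merging, merge closure.

test_that("segment alignment finds unique hits and suppresses multimappers", {
  set.seed(21)
  seqs <- c(tA = oracle_rand_dna(200), tB = oracle_rand_dna(200))
  seg <- substr(seqs[["tA"]], 11, 35)
  h <- align_segment(seg, seqs)
  expect_equal(nrow(h), 1L)
  expect_equal(h$transcript_id, "tA")
  expect_equal(h$offset, 10L)
  expect_equal(h$mismatches, 0L)
  # reverse-complement placement is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg)))
  h2 <- align_segment(rc, seqs)
  expect_equal(h2$strand, "-")
  expect_equal(h2$offset, 10L)
  # no placement within 1 mismatch
  h3 <- align_segment(strrep("A", 25), seqs)
  expect_equal(nrow(h3), 0L)
  expect_false(attr(h3, "multimapped"))
  # planted at 4 distinct loci: discarded as multimapped
  seg4 <- oracle_rand_dna(25)
  seqs4 <- c(seqs,
             t1 = paste0(oracle_rand_dna(10), seg4, oracle_rand_dna(10)),
             t2 = paste0(seg4, oracle_rand_dna(30)),
             t3 = paste0(oracle_rand_dna(40), seg4),
             t4 = paste0(oracle_rand_dna(5), seg4, oracle_rand_dna(40)))
  h4 <- align_segment(seg4, seqs4)
  expect_equal(nrow(h4), 0L)
  expect_true(attr(h4, "multimapped"))
  expect_error(align_segment("ACGT", seqs), "25bp")
})

test_that("link candidates require orientation, strand and the gap window", {
  tx <- dplyr::bind_rows(
    transcript_tbl("A", "chr1", 1000, 5000, "+"),
    transcript_tbl("B", "chr1", 50000, 55000, "+"),
    transcript_tbl("C", "chr1", 300000, 305000, "+"),
    transcript_tbl("D", "chr1", 52000, 56000, "-"))
  hit <- function(seg, tid, strand) {
    tibble::tibble(read_id = "r1", segment = seg, transcript_id = tid,
                   offset = 0L, strand = strand, mismatches = 0L)
  }
  # proper orientation, same strand, 45kb gap
  cands <- find_link_candidates(dplyr::bind_rows(hit("5", "A", "+"),
                                                 hit("3", "B", "+")), tx)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$tx_upstream, "A")
  expect_equal(cands$tx_downstream, "B")
  expect_equal(cands$gap, 45000L)
  # beyond 200kb: no candidate
  far <- find_link_candidates(dplyr::bind_rows(hit("5", "A", "+"),
                                               hit("3", "C", "+")), tx)
  expect_equal(nrow(far), 0L)
  # exactly at the window boundary: kept
  tx2 <- dplyr::bind_rows(tx, transcript_tbl("E", "chr1", 205000, 206000, "+"))
  edge <- find_link_candidates(dplyr::bind_rows(hit("5", "A", "+"),
                                                hit("3", "E", "+")), tx2)
  expect_equal(edge$gap, 200000L)
  expect_equal(nrow(find_link_candidates(
    dplyr::bind_rows(hit("5", "A", "+"), hit("3", "E", "+")), tx2,
    max_gap = 199999L)), 0L)
  # transcripts on opposite genomic strands: no candidate
  opp <- find_link_candidates(dplyr::bind_rows(hit("5", "A", "+"),
                                               hit("3", "D", "+")), tx)
  expect_equal(nrow(opp), 0L)
  # segment hits on opposite orientations: no candidate
  mix <- find_link_candidates(dplyr::bind_rows(hit("5", "A", "+"),
                                               hit("3", "B", "-")), tx)
  expect_equal(nrow(mix), 0L)
})

# two-exon gene split into two single-exon fragments plus a spanning read
make_split_fixture <- function(intron_shift = 0L) {
  set.seed(31)
  exon1 <- oracle_rand_dna(120)
  intron <- paste0("GT", oracle_rand_dna(96), "AG")
  exon2 <- oracle_rand_dna(120)
  genome <- c(chr1 = paste0(oracle_rand_dna(50), exon1, intron, exon2,
                            oracle_rand_dna(50)))
  e1s <- 50L; e1e <- e1s + 120L
  e2s <- e1e + 100L; e2e <- e2s + 120L
  tx <- dplyr::bind_rows(
    transcript_tbl("up", "chr1", e1s, e1e, "+"),
    transcript_tbl("dn", "chr1", e2s, e2e, "+"))
  read_seq <- paste0(substr(exon1, 81, 120), substr(exon2, 1, 40))
  ann <- tibble::tibble(chrom = "chr1", start = e1e + intron_shift,
                        end = e2s + intron_shift, strand = "+")
  cand <- tibble::tibble(read_id = "r1", tx_upstream = "up",
                         tx_downstream = "dn", gap = 100L,
                         read_orientation = "+",
                         orientation_ok = TRUE, same_strand = TRUE)
  list(genome = genome, tx = tx, read = read_seq, ann = ann, cand = cand,
       e1e = e1e, e2s = e2s)
}

test_that("split refinement accepts annotated introns and merges cleanly", {
  fx <- make_split_fixture()
  res <- refine_link(fx$read, fx$genome, fx$cand, fx$tx, fx$ann)
  expect_equal(res$status, "merged")
  expect_equal(res$link$intron_start, fx$e1e)
  expect_equal(res$link$intron_end, fx$e2s)
  expect_equal(res$link$mismatches, 0L)
  merged <- merge_transcript_set(fx$tx, res$link)
  expect_equal(dplyr::n_distinct(merged$transcripts$transcript_id), 1L)
  expect_equal(merged$transcripts$start, c(50L, 270L))
  expect_equal(merged$transcripts$end, c(170L, 390L))
})

test_that("implied introns beyond the 10bp tolerance are rejected", {
  fx10 <- make_split_fixture(intron_shift = 10L)
  expect_equal(refine_link(fx10$read, fx10$genome, fx10$cand, fx10$tx,
                           fx10$ann)$status, "merged")
  fx11 <- make_split_fixture(intron_shift = 11L)
  expect_equal(refine_link(fx11$read, fx11$genome, fx11$cand, fx11$tx,
                           fx11$ann)$status, "rejected")
  # no annotated introns at all
  fx <- make_split_fixture()
  res <- refine_link(fx$read, fx$genome, fx$cand, fx$tx, fx$ann[0, ])
  expect_equal(res$status, "rejected")
  expect_equal(res$reason, "intron_not_annotated")
})

test_that("a read that aligns nowhere is reported as unalignable", {
  fx <- make_split_fixture()
  res <- refine_link(oracle_rand_dna(80), fx$genome, fx$cand, fx$tx, fx$ann,
                     max_mismatches = 2L)
  expect_equal(res$status, "rejected")
  expect_equal(res$reason, "no_spliced_alignment")
})

test_that("non-canonical junction merging attaches only at terminal exons", {
  set.seed(41)
  g <- c(chr1 = oracle_rand_dna(2000))
  tx <- dplyr::bind_rows(
    transcript_tbl("A", "chr1", c(100, 300), c(200, 400), "+"),
    transcript_tbl("B", "chr1", c(600, 800), c(700, 900), "+"))
  j <- tibble::tibble(chrom = "chr1", donor_end = 400L,
                      acceptor_start = 600L, name = "j1", support = 3L,
                      strand = "+", dinucleotides = "GC-AG",
                      canonical = FALSE)
  res <- merge_by_noncanonical_junction(tx, j)
  expect_equal(nrow(res$links), 1L)
  expect_equal(res$links$tx_upstream, "A")
  expect_equal(res$links$tx_downstream, "B")
  # canonical junctions are ignored by this operation
  jc <- dplyr::mutate(j, dinucleotides = "GT-AG", canonical = TRUE)
  expect_equal(nrow(merge_by_noncanonical_junction(tx, jc)$links), 0L)
  # junction donor interior to A: no merge
  ji <- dplyr::mutate(j, donor_end = 350L)
  res_i <- merge_by_noncanonical_junction(tx, ji)
  expect_equal(nrow(res_i$links), 0L)
  expect_equal(res_i$skipped$reason, "no_matching_transcript_end")
  # ambiguous attachment is skipped and logged
  tx3 <- dplyr::bind_rows(tx, transcript_tbl("A2", "chr1", 250, 400, "+"))
  res_a <- merge_by_noncanonical_junction(tx3, j)
  expect_equal(nrow(res_a$links), 0L)
  expect_equal(res_a$skipped$reason, "ambiguous_attachment")
})

test_that("junction dinucleotides and canonical flags respect strand", {
  genome <- c(c1 = paste0(oracle_rand_dna(10), "GT", oracle_rand_dna(6),
                          "AG", oracle_rand_dna(10)))
  j <- tibble::tibble(chrom = "c1", donor_end = 10L, acceptor_start = 20L,
                      strand = c("+", "-"))
  out <- annotate_junctions(j, genome)
  expect_equal(out$dinucleotides[1], "GT-AG")
  expect_true(out$canonical[1])
  expect_false(out$canonical[2])  # minus strand reads CT-AC here
})

test_that("merge closure is transitive and never loses exonic bases", {
  tx <- dplyr::bind_rows(
    transcript_tbl("A", "c1", 0, 100, "+"),
    transcript_tbl("B", "c1", 200, 300, "+"),
    transcript_tbl("C", "c1", 400, 500, "+"),
    transcript_tbl("Z", "c1", 900, 950, "+"))
  links <- tibble::tibble(tx_upstream = c("A", "B"),
                          tx_downstream = c("B", "C"),
                          intron_start = c(100L, 300L),
                          intron_end = c(200L, 400L))
  res <- merge_transcript_set(tx, links)
  expect_equal(dplyr::n_distinct(res$transcripts$transcript_id), 2L)
  expect_equal(res$provenance$n_members, 3L)
  merged_id <- res$provenance$merged_id
  merged <- res$transcripts[res$transcripts$transcript_id == merged_id, ]
  # exon base superset: union of source exons present in the merged model
  src_bases <- unlist(mapply(seq.int,
                             tx$start[tx$transcript_id %in% c("A", "B", "C")],
                             tx$end[tx$transcript_id %in% c("A", "B", "C")] - 1L,
                             SIMPLIFY = FALSE))
  mrg_bases <- unlist(mapply(seq.int, merged$start, merged$end - 1L,
                             SIMPLIFY = FALSE))
  expect_true(all(src_bases %in% mrg_bases))
  # agrees with brute-force transitive closure on random link sets
  set.seed(51)
  for (trial in 1:10) {
    n <- 12
    tx_r <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      transcript_tbl(paste0("t", i), "c1", (i - 1) * 1000,
                     (i - 1) * 1000 + 100, "+")
    }))
    pairs <- t(replicate(5, sort(sample(n, 2))))
    links_r <- tibble::tibble(
      tx_upstream = paste0("t", pairs[, 1]),
      tx_downstream = paste0("t", pairs[, 2]),
      intron_start = NA_integer_, intron_end = NA_integer_)
    res_r <- merge_transcript_set(tx_r, links_r)
    # brute-force closure via boolean matrix powers
    adj <- diag(n) > 0
    for (k in seq_len(nrow(pairs))) {
      adj[pairs[k, 1], pairs[k, 2]] <- TRUE
      adj[pairs[k, 2], pairs[k, 1]] <- TRUE
    }
    for (rep_ in seq_len(n)) adj <- (adj %*% adj) > 0
    n_comp <- nrow(unique(adj))
    expect_equal(dplyr::n_distinct(res_r$transcripts$transcript_id), n_comp)
  }
})
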