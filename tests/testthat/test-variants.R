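# Hard filters, genotype categories, normalization, known-variant matching
# and cross-dataset support.

test_that("hard filters use strict inequalities at every printed threshold", {
  base_snp <- make_variants("c1", 100, "A", "G", qd = 10, mq = 55, fs = 1,
                            mq_rank_sum = 0, read_pos_rank_sum = 0)
  run1 <- function(v, ...) apply_hard_filters(v, ...)
  # QD < 2.0 fails; exactly 2.0 passes
  expect_equal(nrow(run1(dplyr::mutate(base_snp, qd = 1.5))$failing), 1L)
  expect_equal(run1(dplyr::mutate(base_snp, qd = 1.5))$failing$filter_reasons,
               "QD")
  expect_equal(nrow(run1(dplyr::mutate(base_snp, qd = 2.0))$passing), 1L)
  # MQ < 40 fails
  expect_equal(run1(dplyr::mutate(base_snp, mq = 39.9))$failing$filter_reasons,
               "MQ")
  expect_equal(nrow(run1(dplyr::mutate(base_snp, mq = 40.0))$passing), 1L)
  # FS > 60 fails; exactly 60 passes
  expect_equal(run1(dplyr::mutate(base_snp, fs = 60.1))$failing$filter_reasons,
               "FS")
  expect_equal(nrow(run1(dplyr::mutate(base_snp, fs = 60.0))$passing), 1L)
  # rank sums
  expect_equal(run1(dplyr::mutate(base_snp, mq_rank_sum = -12.6))$failing$filter_reasons,
               "MQRankSum")
  expect_equal(nrow(run1(dplyr::mutate(base_snp, mq_rank_sum = -12.5))$passing), 1L)
  expect_equal(run1(dplyr::mutate(base_snp, read_pos_rank_sum = -8.1))$failing$filter_reasons,
               "ReadPosRankSum")
  # HaplotypeScore applies only in genomic mode
  hs <- dplyr::mutate(base_snp, haplotype_score = 13.1)
  expect_equal(nrow(run1(hs)$passing), 1L)
  expect_equal(run1(hs, use_haplotype_score = TRUE)$failing$filter_reasons,
               "HaplotypeScore")
  expect_equal(nrow(run1(dplyr::mutate(hs, haplotype_score = 13.0),
                         use_haplotype_score = TRUE)$passing), 1L)
  # indel rules
  indel <- make_variants("c1", 100, "AT", "A", qd = 10, fs = 1,
                         read_pos_rank_sum = 0)
  expect_equal(run1(dplyr::mutate(indel, fs = 250))$failing$filter_reasons,
               "FS")
  expect_equal(nrow(run1(dplyr::mutate(indel, fs = 200.0))$passing), 1L)
  expect_equal(run1(dplyr::mutate(indel, read_pos_rank_sum = -20.1))$failing$filter_reasons,
               "ReadPosRankSum")
  # snp-only rules do not apply to indels
  expect_equal(nrow(run1(dplyr::mutate(indel, mq = 10))$passing), 1L)
  # missing metric skips the rule rather than failing the record
  expect_equal(nrow(run1(dplyr::mutate(base_snp, qd = NA_real_))$passing), 1L)
  # multiple triggered rules are all named
  multi <- run1(dplyr::mutate(base_snp, qd = 1, mq = 10))$failing
  expect_equal(multi$filter_reasons, "QD,MQ")
})

test_that("the filter partitions input and weakening rules is monotone", {
  set.seed(81)
  n <- 200
  v <- make_variants("c1", seq_len(n), "A",
                     sample(c("G", "AT", "A"), n, TRUE),
                     qd = runif(n, 0, 10), mq = runif(n, 20, 60),
                     fs = runif(n, 0, 300),
                     read_pos_rank_sum = runif(n, -30, 5))
  v <- v[v$ref != v$alt, ]
  res <- apply_hard_filters(v)
  expect_equal(nrow(res$passing) + nrow(res$failing), nrow(v))
  # removing the QD rule never shrinks the passing set
  loose <- hard_filter_thresholds(snp = list(qd_min = -Inf),
                                  indel = list(qd_min = -Inf))
  res2 <- apply_hard_filters(v, loose)
  expect_gte(nrow(res2$passing), nrow(res$passing))
  expect_error(apply_hard_filters(
    dplyr::mutate(v[1, ], variant_class = "weird")), "unknown variant class")
})

test_that("genotype categories follow the allele pattern", {
  v <- make_variants("c1", 1:5, "A", "G",
                     genotype = c("1/1", "0/1", "1/2", NA, "0/0"))
  out <- classify_genotype_position(v)
  expect_equal(out$genotype_category,
               c("homozygous_alt", "mixed_allele", "other", "missing",
                 "other"))
  # phased separators are accepted
  expect_equal(classify_genotype_position(
    make_variants("c1", 1, "A", "G", genotype = "1|1"))$genotype_category,
    "homozygous_alt")
})

test_that("homopolymer indels normalize to one canonical left-aligned form", {
  genome <- c(g1 = "ACCCCGTTTA")
  # deletion of one C reported at the first vs the last C of the run
  first <- make_variants("g1", 1, "AC", "A")
  last <- make_variants("g1", 4, "CC", "C")
  n1 <- normalize_alleles(first, genome)
  n2 <- normalize_alleles(last, genome)
  expect_equal(n1[, c("pos", "ref", "alt")], n2[, c("pos", "ref", "alt")])
  expect_equal(n1$pos, 1L)
  # SNPs are already canonical
  snp <- make_variants("g1", 6, "G", "T")
  expect_equal(normalize_alleles(snp, genome)[, c("pos", "ref", "alt")],
               snp[, c("pos", "ref", "alt")])
  # shared-suffix trim: CT > GT at pos 5..6 becomes C > G at pos 5
  st <- make_variants("g1", 5, "CG", "TG")
  nst <- normalize_alleles(st, genome)
  expect_equal(nst$ref, "C"); expect_equal(nst$alt, "T")
  expect_equal(nst$pos, 5L)
  # idempotence
  expect_equal(normalize_alleles(n1, genome), n1)
  # reference mismatch is an error
  expect_error(normalize_alleles(make_variants("g1", 1, "T", "G"), genome),
               "reference mismatch")
})

test_that("normalization equivalence matches sequence application", {
  set.seed(82)
  genome <- rand_homopolymer_genome(2000)
  chromseq <- genome[["g1"]]
  for (trial in 1:40) {
    # pick a homopolymer run and a random in-run representation
    runs <- gregexpr("([ACGT])\\1{2,}", chromseq, perl = TRUE)[[1]]
    k <- sample(length(runs), 1)
    rs <- as.integer(runs[k])
    rl <- attr(runs, "match.length")[k]
    b <- substr(chromseq, rs, rs)
    if (rs < 2) next
    off <- sample(0:(rl - 2), 1)
    is_del <- runif(1) < 0.5
    if (is_del) {
      v <- make_variants("g1", rs + off - 1L,
                         paste0(substr(chromseq, rs + off - 1L, rs + off - 1L), b),
                         substr(chromseq, rs + off - 1L, rs + off - 1L))
    } else {
      v <- make_variants("g1", rs + off - 1L,
                         substr(chromseq, rs + off - 1L, rs + off - 1L),
                         paste0(substr(chromseq, rs + off - 1L, rs + off - 1L), b))
    }
    canon <- normalize_alleles(v, genome)
    # any other in-run representation canonicalizes identically and applies
    # to the same mutated sequence
    off2 <- sample(0:(rl - 2), 1)
    v2 <- v
    v2$pos <- rs + off2 - 1L
    v2$ref <- paste0(substr(chromseq, v2$pos, v2$pos),
                     if (is_del) b else "")
    v2$alt <- paste0(substr(chromseq, v2$pos, v2$pos),
                     if (is_del) "" else b)
    canon2 <- normalize_alleles(v2, genome)
    expect_equal(canon[, c("pos", "ref", "alt")],
                 canon2[, c("pos", "ref", "alt")])
    expect_identical(apply_to_chrom(chromseq, v$pos, v$ref, v$alt),
                     apply_to_chrom(chromseq, v2$pos, v2$ref, v2$alt))
  }
})

test_that("known-variant matching sees through representation differences", {
  genome <- c(g1 = "ACCCCGTTTA")
  q <- make_variants("g1", 1, "AC", "A")
  known_same <- make_variants("g1", 4, "CC", "C")   # same event, shifted
  res <- match_known_variants(q, known_same, genome)
  expect_true(res$alleles$known)
  expect_equal(res$fraction, 1)
  res0 <- match_known_variants(q, known_same[0, ], genome)
  expect_equal(res0$fraction, 0)
  # position-only mode
  other_allele <- make_variants("g1", 1, "AC", "T")
  respos <- match_known_variants(other_allele, known_same, genome,
                                 position_only = TRUE)
  expect_true(respos$alleles$known)
})

test_that("support table bins by dataset count and conserves totals", {
  set.seed(83)
  genome <- c(g1 = oracle_rand_dna(3000))
  n <- 60
  v <- make_variants("g1", sample(2:2900, n), "X", "X")
  v$ref <- substr(rep(genome, n), v$pos, v$pos)
  v$alt <- vapply(v$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
  v$variant_class <- variant_class(v$ref, v$alt)
  sets <- lapply(1:5, function(i) v[runif(n) < 0.4, ])
  res <- tabulate_dataset_support(v, sets, genome)
  tab <- res$table
  # per class, bins sum to the class total
  totals <- dplyr::count(
    dplyr::mutate(expand_alleles(v), variant_class = allele_class),
    variant_class)
  for (cl in unique(totals$variant_class)) {
    expect_equal(sum(tab$n[tab$variant_class == cl]),
                 totals$n[totals$variant_class == cl])
  }
  # invariance to comparison-set order
  res2 <- tabulate_dataset_support(v, rev(sets), genome)
  expect_equal(res2$table, res$table)
  # membership in k sets lands in bin k
  v1 <- v[1, ]
  res3 <- tabulate_dataset_support(v1, list(v1, v1, v1, v[2, ], v[3, ]),
                                   genome)
  expect_equal(res3$alleles$support, 3L)
})

test_that("multi-allelic records expand to per-allele rows", {
  v <- make_variants("c1", 10, "A", "G,T", ad = "5,6,7")
  ex <- expand_alleles(v)
  expect_equal(nrow(ex), 2L)
  expect_equal(ex$allele_index, c(1L, 2L))
  expect_equal(ex$alt, c("G", "T"))
  expect_equal(ex$allele_class, c("snp", "snp"))
})
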