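# Independent oracles and random-fixture builders used across the suite.
# Each oracle is deliberately implemented with a different algorithmic
# structure from the package routine it checks.

oracle_rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# quadratic affine-gap Smith-Waterman via explicit three-matrix DP
sw_oracle <- function(a, b, scheme) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0 || m == 0) return(0)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  NEG <- -1e18
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") scheme$match
        else scheme$mismatch
      E[i, j] <- max(E[i, j - 1] + scheme$gap_extend,
                     H[i, j - 1] + scheme$gap_open + scheme$gap_extend)
      F[i, j] <- max(F[i - 1, j] + scheme$gap_extend,
                     H[i - 1, j] + scheme$gap_open + scheme$gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# longest ATG->stop ORF by enumerating (start codon, first in-frame stop)
# pairs over codon vectors in all six frames
orf_oracle <- function(seq, both = TRUE) {
  seqs <- if (both) c(seq, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))) else seq
  best <- 0L
  for (s in seqs) {
    n <- nchar(s)
    for (f in 0:2) {
      starts <- seq(f + 1, n - 2, by = 3)
      if (length(starts) == 0) next
      codons <- substring(s, starts, starts + 2)
      atg_i <- which(codons == "ATG")
      stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
      for (i in atg_i) {
        after <- stop_i[stop_i > i]
        if (length(after) == 0) next
        len <- (after[1] - i + 1L) * 3L
        if (len > best) best <- len
      }
    }
  }
  best
}

# O(n^2) interval-overlap oracle: sources overlapping each query span
overlap_oracle <- function(q, s) {
  lapply(seq_len(nrow(q)), function(i) {
    hit <- s$chrom == q$chrom[i] & s$start < q$end[i] & s$end > q$start[i]
    sort(unique(s$source[hit]))
  })
}

# brute-force single-linkage clustering of transcripts by exonic overlap
cluster_oracle <- function(tx) {
  ids <- unique(tx$transcript_id)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- tx[tx$transcript_id == ids[i], ]
    b <- tx[tx$transcript_id == ids[j], ]
    hit <- FALSE
    for (x in seq_len(nrow(a))) for (y in seq_len(nrow(b))) {
      if (a$chrom[x] == b$chrom[y] &&
          (a$strand[x] == b$strand[y] || a$strand[x] == "." ||
             b$strand[y] == ".") &&
          a$start[x] < b$end[y] && a$end[x] > b$start[y]) hit <- TRUE
    }
    if (hit) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_along(ids), find, integer(1))
  split(ids, comp)
}

# random multi-exon transcript table on a fresh genome
rand_transcripts <- function(n_tx, chrom_len = 5000, chroms = c("c1", "c2")) {
  rows <- list()
  for (i in seq_len(n_tx)) {
    ch <- sample(chroms, 1)
    n_ex <- sample(1:4, 1)
    pos <- sample(1:(chrom_len %/% 2), 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + sample(20:120, 1)
      pos <- ends[k] + sample(10:80, 1)
    }
    rows[[i]] <- tibble::tibble(
      transcript_id = sprintf("t%03d", i), gene_id = NA_character_,
      chrom = ch, start = starts, end = ends,
      strand = sample(c("+", "-", "."), 1))
  }
  validate_transcripts(dplyr::bind_rows(rows))
}

# minimal single-sample VCF text for parser tests
vcf_text <- function(body_lines) {
  c("##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", sep = "\t"),
    body_lines)
}

# variant tibble builder with all model columns
make_variants <- function(chrom, pos, ref, alt, genotype = "1/1",
                          ad = NA_character_, qd = 10, mq = 55, fs = 1,
                          haplotype_score = NA_real_, mq_rank_sum = NA_real_,
                          read_pos_rank_sum = NA_real_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 genotype = genotype, ad = ad, qd = qd, mq = mq, fs = fs,
                 haplotype_score = haplotype_score,
                 mq_rank_sum = mq_rank_sum,
                 read_pos_rank_sum = read_pos_rank_sum,
                 variant_class = variant_class(ref, alt))
}

# genome with homopolymer-rich sequence for normalization tests
rand_homopolymer_genome <- function(len = 3000) {
  pieces <- character(0)
  total <- 0
  while (total < len) {
    if (stats::runif(1) < 0.35) {
      b <- sample(c("A", "C", "G", "T"), 1)
      run <- strrep(b, sample(3:8, 1))
    } else {
      run <- oracle_rand_dna(sample(5:15, 1))
    }
    pieces <- c(pieces, run)
    total <- total + nchar(run)
  }
  c(g1 = substr(paste(pieces, collapse = ""), 1, len))
}

# memoized synthetic pipeline runs (several files inspect the same run)
synth_cache <- new.env(parent = emptyenv())
cached_synth <- function(seed) {
  key <- as.character(seed)
  if (is.null(synth_cache[[key]])) {
    synth_cache[[key]] <- run_synthetic_pipeline(seed)
  }
  synth_cache[[key]]
}

# apply a single-allele variant to a chromosome string (sequence oracle)
apply_to_chrom <- function(chromseq, pos, ref, alt) {
  stopifnot(substr(chromseq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(chromseq, 1, pos - 1L), alt,
         substr(chromseq, pos + nchar(ref), nchar(chromseq)))
}
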