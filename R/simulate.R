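# Deterministic synthetic-data generator with planted ground truth.
#
# All coordinates are expressed in the reference-genome frame, as in a real
# pipeline. "Planted reference errors" are built constructively: each host
# gene's spliced sequence is designed with a long clean ORF, then the copy
# written into the reference genome is corrupted (a duplicated homopolymer
# base, a dropped base, a substitution creating a premature stop, or an
# inserted intron-length junk segment). The VCF edit that reverses the
# corruption is recorded as the planted variant, so applying the variant
# restores the designed ORF and the effect is extending by construction
# (and re-verified at emit time).

STOP_CODONS <- c("TAA", "TAG", "TGA")

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_codons <- function(n) {
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste0,
                      collapse = "")
  ok <- setdiff(all_codons, STOP_CODONS)
  sample(ok, n, replace = TRUE)
}

# A-free sequence/codons: with no adenine there can be no ATG (and no stop),
# used upstream of a planted frameshift so that no off-frame start codon can
# read through the corruption into the stop-free designed CDS.
rand_dna_noA <- function(n) {
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_codons_noA <- function(n) {
  pool <- apply(expand.grid(c("C", "G", "T"), c("C", "G", "T"),
                            c("C", "G", "T")), 1, paste0, collapse = "")
  sample(pool, n, replace = TRUE)
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a small genome with
#' multi-exon genes, fragmented transcript assemblies with linking long
#' reads, three partially overlapping annotation sources, and planted
#' reference-genome errors (homopolymer 1bp indels, premature-stop SNPs and
#' one intron-mimicking insertion) that extend ORFs and are homozygous in
#' reference-individual resequencing records.
#'
#' @param seed Integer seed; with a fixed seed all outputs are
#'   byte-identical across runs.
#' @param n_chroms Number of placed chromosomes (default 2).
#' @param chrom_length Upper bound on chromosome length in bp
#'   (default 100000); generation fails if the genes do not fit.
#' @param n_genes Total gene count (default 30).
#' @param exon_length_range,intron_length_range Per-exon/intron length
#'   ranges in bp.
#' @param fraction_noncanonical_introns Fraction of introns given a GC-AG
#'   (non-canonical) splice signal (default 0.1).
#' @param n_fragmented Genes fragmented into two models reunited by linking
#'   long reads (default 8).
#' @param n_junction_fragmented Genes fragmented at a non-canonical intron
#'   and reunited via the junction route (default 2).
#' @param n_linking_reads Linking reads per fragmentation (default 2).
#' @param n_decoy_reads Long reads contained in a single model (default 4).
#' @param read_error_rate Per-base substitution rate in long reads
#'   (default 0).
#' @param n_hom Planted homozygous reference errors, named by class
#'   (default snp 3, insertion 3, deletion 4 — one deletion is the
#'   intron mimic).
#' @param n_het,n_unsup ORF-extending decoys per class with heterozygous /
#'   absent genomic support (default 1 each per class).
#' @param n_neutral Neutral passing variants (default 4).
#' @param n_noise_transcripts Unsupported 1-exon assembly-noise transcripts
#'   (default 6, two of them on an unplaced contig).
#' @param n_comparison_datasets Cross-dataset support sets (default 5).
#' @param fraction_shared Probability each eligible variant appears in a
#'   comparison set (default 0.6).
#' @return List with class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2L,
                       chrom_length = 100000L,
                       n_genes = 30L,
                       exon_length_range = c(150L, 300L),
                       intron_length_range = c(80L, 400L),
                       fraction_noncanonical_introns = 0.1,
                       n_fragmented = 8L,
                       n_junction_fragmented = 2L,
                       n_linking_reads = 2L,
                       n_decoy_reads = 4L,
                       read_error_rate = 0,
                       n_hom = c(snp = 3L, insertion = 3L, deletion = 4L),
                       n_het = c(snp = 1L, insertion = 1L, deletion = 1L),
                       n_unsup = c(snp = 1L, insertion = 1L, deletion = 1L),
                       n_neutral = 4L,
                       n_noise_transcripts = 6L,
                       n_comparison_datasets = 5L,
                       fraction_shared = 0.6) {
  if (missing(seed)) abort("sim_config requires a seed")
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = chrom_length, n_genes = n_genes,
              exon_length_range = exon_length_range,
              intron_length_range = intron_length_range,
              fraction_noncanonical_introns = fraction_noncanonical_introns,
              n_fragmented = n_fragmented,
              n_junction_fragmented = n_junction_fragmented,
              n_linking_reads = n_linking_reads,
              n_decoy_reads = n_decoy_reads,
              read_error_rate = read_error_rate,
              n_hom = n_hom, n_het = n_het, n_unsup = n_unsup,
              n_neutral = n_neutral,
              n_noise_transcripts = n_noise_transcripts,
              n_comparison_datasets = n_comparison_datasets,
              fraction_shared = fraction_shared)
  structure(cfg, class = "sim_config")
}

# design one gene: reference exon/intron sequences plus (optionally) the
# corruption that plants an ORF-extending variant.
# corruption: NULL or list(type = snp|insertion|deletion|mimic, role)
design_gene <- function(gene_id, tx_id, strand, n_exons, el, il,
                        noncanonical, corruption) {
  Lc <- sum(el)  # reference spliced length
  utr5 <- 24L
  delta <- if (is.null(corruption)) 0L
    else switch(corruption$type, snp = 0L, insertion = 1L,
                deletion = -1L, mimic = -70L)
  # clean spliced length; corruption op transforms clean -> reference
  Lclean <- Lc + delta
  ncod <- (Lclean - 2L * utr5) %/% 3L
  codons <- rand_codons(ncod)
  codons[1] <- "ATG"
  codons[ncod] <- "TAA"

  site <- NULL
  if (!is.null(corruption)) {
    # pick a codon index whose corrupted footprint sits inside one
    # reference exon with margins
    span <- switch(corruption$type, snp = 9L, mimic = 76L, 12L)
    bounds <- cumsum(el)
    ok_j <- NULL
    for (j in 5:(ncod - 10L)) {
      a <- utr5 + 3L * (j - 1L) - 3L          # ref oriented interval start
      b <- a + span
      fa <- if (strand == "-") Lc - b else a  # ref forward-spliced interval
      fb <- if (strand == "-") Lc - a else b
      ex <- findInterval(fa, c(0L, bounds))
      in_one <- ex >= 1 && ex <= n_exons &&
        fa >= c(0L, bounds)[ex] + 8L && fb <= bounds[ex] - 8L
      if (in_one) { ok_j <- j; break }
    }
    if (is.null(ok_j)) abort("infeasible config: no corruption site fits")
    j <- ok_j
    # no off-frame ATG upstream of the corruption: A-free codons there
    if (j > 3) codons[2:(j - 2)] <- rand_codons_noA(j - 3L)
    if (corruption$type == "snp") {
      codons[j] <- "TGG"
    } else if (corruption$type %in% c("insertion", "deletion")) {
      if (j >= 2) codons[j - 1] <- "GAT"
      codons[j] <- "CCC"
      codons[j + 1] <- "CAA"
      # CAA + a TG-initial codon would spell an off-frame ATG
      if (j + 2 <= ncod && startsWith(codons[j + 2], "TG")) {
        codons[j + 2] <- "CCT"
      }
    } else if (corruption$type == "mimic" && j > 2) {
      codons[2:(j - 1)] <- rand_codons_noA(j - 2L)
    }
    site <- list(j = j, o0 = utr5 + 3L * (j - 1L))  # clean oriented offset
  }
  utr5_seq <- if (is.null(corruption)) rand_dna(utr5) else rand_dna_noA(utr5)
  clean <- paste0(utr5_seq, paste(codons, collapse = ""),
                  rand_dna(Lclean - 2L * utr5 - 3L * ncod + utr5))
  stopifnot(nchar(clean) == Lclean)

  ref <- clean
  run <- NULL
  if (!is.null(corruption)) {
    o0 <- site$o0
    if (corruption$type == "snp") {
      # designed TGG -> reference TGA: premature stop in the reference
      ref <- paste0(substr(clean, 1L, o0 + 2L), "A",
                    substr(clean, o0 + 4L, Lclean))
    } else if (corruption$type == "insertion") {
      # reference dropped one C from the CCCC run (clean run at o0..o0+3)
      ref <- paste0(substr(clean, 1L, o0), substr(clean, o0 + 2L, Lclean))
      run <- list(start_oriented = o0, len_ref = 3L, base = "C")
    } else if (corruption$type == "deletion") {
      # reference duplicated a C: run of 5 in the reference
      ref <- paste0(substr(clean, 1L, o0), "C", substr(clean, o0 + 1L, Lclean))
      run <- list(start_oriented = o0, len_ref = 5L, base = "C")
    } else if (corruption$type == "mimic") {
      before <- substr(clean, o0, o0)
      after <- substr(clean, o0 + 1L, o0 + 1L)
      # A-free junk carries no start or stop codon, so no spurious ORF can
      # begin inside it or read through it
      junk <- strsplit(rand_dna_noA(70L), "")[[1]]
      if (junk[1] == before) junk[1] <- setdiff(c("C", "G", "T"), before)[1]
      if (junk[70] == after) junk[70] <- setdiff(c("C", "G", "T"), after)[1]
      ref <- paste0(substr(clean, 1L, o0), paste(junk, collapse = ""),
                    substr(clean, o0 + 1L, Lclean))
    }
  }
  stopifnot(nchar(ref) == Lc)
  fwd_ref <- if (strand == "-") revcomp(ref) else ref
  fwd_clean <- if (strand == "-") revcomp(clean) else clean
  # split reference forward spliced sequence into exon pieces
  bounds <- cumsum(el)
  exon_seqs <- substring(fwd_ref, c(1L, head(bounds, -1) + 1L), bounds)
  # intron sequences with splice signals in the gene's orientation;
  # indexed by genomic position (k-th gap between genomic exons k, k+1)
  intron_seqs <- character(0)
  if (n_exons > 1) {
    intron_seqs <- vapply(seq_len(n_exons - 1L), function(k) {
      donor2 <- if (noncanonical[k]) "GC" else "GT"
      oriented <- paste0(donor2, rand_dna(il[k] - 4L), "AG")
      if (strand == "-") revcomp(oriented) else oriented
    }, character(1))
  }
  list(gene_id = gene_id, tx_id = tx_id, strand = strand,
       n_exons = n_exons, el = el, il = il,
       noncanonical = noncanonical,
       exon_seqs = exon_seqs, intron_seqs = intron_seqs,
       fwd_ref = fwd_ref, fwd_clean = fwd_clean,
       corruption = corruption, run = run, Lc = Lc)
}

# first difference between the reference and clean forward spliced strings,
# as an anchored VCF-style allele pair in spliced forward coordinates
spliced_edit <- function(fwd_ref, fwd_clean) {
  if (fwd_ref == fwd_clean) return(NULL)
  nr <- nchar(fwd_ref); na <- nchar(fwd_clean)
  r <- strsplit(fwd_ref, "")[[1]]; a <- strsplit(fwd_clean, "")[[1]]
  p <- 0L
  while (p < min(nr, na) && r[p + 1L] == a[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nr, na) - p && r[nr - s] == a[na - s]) s <- s + 1L
  if (nr == na) {
    # SNP
    return(list(spliced_pos = p + 1L, ref = substr(fwd_ref, p + 1L, nr - s),
                alt = substr(fwd_clean, p + 1L, na - s)))
  }
  stopifnot(p >= 1L)
  pos <- p
  ref <- substr(fwd_ref, p, nr - s)
  alt <- substr(fwd_clean, p, na - s)
  # minimal anchored representation (shared suffix then prefix trimmed)
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(spliced_pos = pos, ref = ref, alt = alt)
}

#' Generate the reference genome, annotations and planted truth
#'
#' Builds the reference genome (genes with GT-AG introns except a
#' configured non-canonical fraction, homopolymer-bearing coding exons so
#' slips are plantable, an unplaced contig), the three annotation sources
#' with per-gene Venn membership over all 8 regions, and the truth tables:
#' true transcripts, fragmentation plan, planted ORF-extending variants
#' with mechanism flags, per-gene annotation membership.
#'
#' @param config A [sim_config()].
#' @return List with class `sim_truth`.
#' @export
generate_reference_and_truth <- function(config) {
  set.seed(config$seed)
  n_hom <- config$n_hom; n_het <- config$n_het; n_unsup <- config$n_unsup
  n_single <- 2L
  n_var_hosts <- sum(n_hom) + sum(n_het) + sum(n_unsup)
  n_frag <- config$n_fragmented
  n_jfrag <- config$n_junction_fragmented
  n_genes <- config$n_genes
  if (n_single + n_var_hosts + n_frag + n_jfrag > n_genes) {
    abort("infeasible config: roles exceed n_genes")
  }
  n_plain <- n_genes - n_single - n_var_hosts - n_frag - n_jfrag

  roles <- c(rep("single", n_single),
             rep("hom", sum(n_hom)), rep("het", sum(n_het)),
             rep("unsup", sum(n_unsup)),
             rep("link_frag", n_frag), rep("junction_frag", n_jfrag),
             rep("plain", n_plain))
  var_class <- c(rep(NA, n_single),
                 rep(names(n_hom), n_hom), rep(names(n_het), n_het),
                 rep(names(n_unsup), n_unsup),
                 rep(NA, n_frag + n_jfrag + n_plain))
  # one homozygous deletion is the intron mimic
  mimic_idx <- which(roles == "hom" & var_class == "deletion")[1]

  # Venn membership: the 4 "none" regions go to single-exon genes (they
  # have no introns to demand annotation); the rest cycle the 7 non-empty
  # regions so all 8 regions are populated.
  regions7 <- c("E", "R", "O", "ER", "EO", "RO", "ERO")
  venn <- character(n_genes)
  venn[roles == "single"] <- "none"
  venn[roles != "single"] <- rep(regions7, length.out = sum(roles != "single"))

  # the intron-mimicking deletion needs its companion intron in OtherRefSeq,
  # so the host gene's span must be annotated there
  if (!is.na(mimic_idx) && !grepl("O", venn[mimic_idx])) {
    venn[mimic_idx] <- paste0(venn[mimic_idx], "O")
  }

  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  designs <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    role <- roles[g]
    n_exons <- switch(role,
                      single = 1L,
                      hom = , het = , unsup = sample(5:7, 1),
                      link_frag = sample(4:6, 1),
                      junction_frag = sample(4:5, 1),
                      plain = sample(2:5, 1))
    el <- sample(config$exon_length_range[1]:config$exon_length_range[2],
                 n_exons, replace = TRUE)
    if (role == "single") el <- sample(400:600, 1)
    if (g == mimic_idx) el <- pmax(el, 260L)
    il <- if (n_exons > 1) {
      sample(config$intron_length_range[1]:config$intron_length_range[2],
             n_exons - 1L, replace = TRUE)
    } else integer(0)
    nonc <- if (n_exons > 1) {
      stats::runif(n_exons - 1L) < config$fraction_noncanonical_introns
    } else logical(0)
    split_at <- NA_integer_
    if (role %in% c("link_frag", "junction_frag")) {
      split_at <- max(2L, n_exons %/% 2L)  # split after this exon
      if (role == "junction_frag") nonc[split_at] <- TRUE
      if (role == "link_frag") nonc[split_at] <- FALSE
    }
    corruption <- if (role %in% c("hom", "het", "unsup")) {
      list(type = if (g == mimic_idx) "mimic" else var_class[g],
           role = role)
    } else NULL
    designs[[g]] <- design_gene(sprintf("gene%02d", g), sprintf("tx%02d", g),
                                strands[g], n_exons, el, il, nonc, corruption)
    designs[[g]]$role <- role
    designs[[g]]$split_at <- split_at
    designs[[g]]$venn <- venn[g]
  }

  # place genes on chromosomes
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  chrom_seq <- setNames(rep("", config$n_chroms), chrom_names)
  exon_rows <- list()
  for (g in seq_len(n_genes)) {
    d <- designs[[g]]
    ch <- chrom_names[((g - 1L) %% config$n_chroms) + 1L]
    spacer <- rand_dna(sample(300:600, 1))
    cursor <- nchar(chrom_seq[[ch]]) + nchar(spacer)
    pieces <- character(0)
    starts <- integer(d$n_exons); ends <- integer(d$n_exons)
    pos <- cursor
    for (k in seq_len(d$n_exons)) {
      starts[k] <- pos
      ends[k] <- pos + nchar(d$exon_seqs[k])
      pieces <- c(pieces, d$exon_seqs[k])
      pos <- ends[k]
      if (k < d$n_exons) {
        pieces <- c(pieces, d$intron_seqs[k])
        pos <- pos + nchar(d$intron_seqs[k])
      }
    }
    chrom_seq[[ch]] <- paste0(chrom_seq[[ch]], spacer,
                              paste(pieces, collapse = ""))
    designs[[g]]$chrom <- ch
    designs[[g]]$exon_starts <- starts
    designs[[g]]$exon_ends <- ends
    exon_rows[[g]] <- tibble(transcript_id = d$tx_id, gene_id = d$gene_id,
                             chrom = ch, start = starts, end = ends,
                             strand = d$strand)
  }
  # noise transcripts in chromosome tails and on an unplaced contig
  noise_rows <- list()
  n_noise <- config$n_noise_transcripts
  un_name <- "chrUn_1"
  chrom_seq[[un_name]] <- ""
  for (i in seq_len(n_noise)) {
    on_un <- i <= 2L
    ch <- if (on_un) un_name else chrom_names[((i - 1L) %% config$n_chroms) + 1L]
    len <- sample(80:110, 1)
    start <- nchar(chrom_seq[[ch]]) + 100L
    chrom_seq[[ch]] <- paste0(chrom_seq[[ch]], rand_dna(100L), rand_dna(len))
    noise_rows[[i]] <- tibble(transcript_id = sprintf("noise%02d", i),
                              gene_id = NA_character_, chrom = ch,
                              start = start, end = start + len, strand = ".")
  }
  chrom_seq <- vapply(names(chrom_seq), function(ch) {
    paste0(chrom_seq[[ch]], rand_dna(200L))
  }, character(1))
  if (any(nchar(chrom_seq) > config$chrom_length)) {
    abort("infeasible config: genes do not fit in chrom_length")
  }
  genome <- chrom_seq

  genes_tx <- validate_transcripts(bind_rows(exon_rows))
  noise_tx <- validate_transcripts(bind_rows(noise_rows))

  # planted variants in genomic coordinates
  var_rows <- list()
  for (g in seq_len(n_genes)) {
    d <- designs[[g]]
    if (is.null(d$corruption)) next
    edit <- spliced_edit(d$fwd_ref, d$fwd_clean)
    bounds <- cumsum(d$el)
    ex <- findInterval(edit$spliced_pos - 1L, c(0L, bounds))
    gpos <- d$exon_starts[ex] + (edit$spliced_pos - c(0L, bounds)[ex])  # 1-based
    run_info <- NULL
    if (!is.null(d$run)) {
      rs_fwd <- if (d$strand == "-") d$Lc - d$run$start_oriented - d$run$len_ref
        else d$run$start_oriented
      ex_r <- findInterval(rs_fwd, c(0L, bounds))
      run_start_g <- d$exon_starts[ex_r] + (rs_fwd - c(0L, bounds)[ex_r]) + 1L
      base_fwd <- if (d$strand == "-") revcomp(d$run$base) else d$run$base
      run_info <- list(start = run_start_g, len = d$run$len_ref,
                       base = base_fwd)
    }
    cls <- variant_class(edit$ref, edit$alt)
    var_rows[[length(var_rows) + 1L]] <- tibble(
      variant_id = paste0("pv_", d$gene_id),
      chrom = d$chrom, pos = gpos, ref = edit$ref, alt = edit$alt,
      variant_class = cls, role = d$role,
      host_transcript = d$tx_id,
      homopolymer_slip = !is.null(run_info),
      intron_mimic = identical(d$corruption$type, "mimic"),
      run_start = if (is.null(run_info)) NA_integer_ else run_info$start,
      run_len = if (is.null(run_info)) NA_integer_ else run_info$len,
      run_base = if (is.null(run_info)) NA_character_ else run_info$base)
  }
  planted <- bind_rows(var_rows)

  # annotation sources: member genes contribute span (jittered) + introns
  src_names <- c(E = "Ensembl", R = "RefSeq", O = "OtherRefSeq")
  sets <- list()
  for (letter in names(src_names)) {
    spans <- list(); introns <- list()
    for (g in seq_len(n_genes)) {
      d <- designs[[g]]
      if (!grepl(letter, d$venn) || d$venn == "none") next
      j1 <- sample(0:30, 1); j2 <- sample(0:30, 1)
      spans[[length(spans) + 1L]] <- tibble(
        chrom = d$chrom, start = max(0L, min(d$exon_starts) - j1),
        end = max(d$exon_ends) + j2, gene_id = d$gene_id, strand = d$strand)
      if (d$n_exons > 1) {
        introns[[length(introns) + 1L]] <- tibble(
          chrom = d$chrom, start = d$exon_ends[-d$n_exons],
          end = d$exon_starts[-1], strand = d$strand)
      }
    }
    sets[[src_names[[letter]]]] <- list(spans = bind_rows(spans),
                                        introns = bind_rows(introns))
  }
  # intron-mimic: give OtherRefSeq an intron of the junk's length starting
  # within tolerance of the junk deletion start
  if (nrow(planted) > 0 && any(planted$intron_mimic)) {
    pm <- planted[planted$intron_mimic, ][1, ]
    del_len <- nchar(pm$ref) - 1L
    extra <- tibble(chrom = pm$chrom, start = pm$pos + 4L,
                    end = pm$pos + 4L + del_len,
                    strand = designs[[which(vapply(designs, function(d)
                      identical(d$tx_id, pm$host_transcript), logical(1)))]]$strand)
    sets$OtherRefSeq$introns <- bind_rows(sets$OtherRefSeq$introns, extra)
  }
  annotations <- bind_annotations(
    annotation_set("Ensembl", sets$Ensembl$spans, sets$Ensembl$introns),
    annotation_set("RefSeq", sets$RefSeq$spans, sets$RefSeq$introns),
    annotation_set("OtherRefSeq", sets$OtherRefSeq$spans,
                   sets$OtherRefSeq$introns))

  gene_meta <- tibble(
    gene_id = vapply(designs, `[[`, character(1), "gene_id"),
    transcript_id = vapply(designs, `[[`, character(1), "tx_id"),
    chrom = vapply(designs, `[[`, character(1), "chrom"),
    strand = vapply(designs, `[[`, character(1), "strand"),
    role = roles, venn_region = venn,
    n_exons = vapply(designs, `[[`, integer(1), "n_exons"),
    split_at = vapply(designs, function(d)
      if (is.na(d$split_at)) NA_integer_ else d$split_at, integer(1)))

  structure(list(
    config = config, genome = genome, genes = genes_tx, noise = noise_tx,
    gene_meta = gene_meta, designs = designs, planted = planted,
    annotations = annotations
  ), class = "sim_truth")
}

#' Fragment truth transcripts into an assembled set
#'
#' Link-fragmented and junction-fragmented genes are split at their
#' designated internal intron into two fragment models; all other genes
#' pass through intact; assembly-noise transcripts are appended. The
#' fragment-to-parent mapping is recorded.
#'
#' @param truth A `sim_truth`.
#' @param config The matching [sim_config()].
#' @return List: `transcripts` (assembled tibble), `fragments` (tibble:
#'   `parent_id`, `frag_a`, `frag_b`, `split_intron_start`,
#'   `split_intron_end`, `type`), `junctions` (junction tibble for the
#'   junction route, plus canonical decoys).
#' @export
fragment_transcripts <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  rows <- list(); frags <- list(); jrows <- list()
  for (d in truth$designs) {
    tx_rows <- truth$genes[truth$genes$transcript_id == d$tx_id, ]
    if (!d$role %in% c("link_frag", "junction_frag") || d$n_exons < 2L) {
      rows[[length(rows) + 1L]] <- tx_rows
      next
    }
    k <- d$split_at
    a <- tx_rows[seq_len(k), ]
    b <- tx_rows[(k + 1L):nrow(tx_rows), ]
    a$transcript_id <- paste0(d$tx_id, ".frag1")
    b$transcript_id <- paste0(d$tx_id, ".frag2")
    rows[[length(rows) + 1L]] <- bind_rows(a, b)
    frags[[length(frags) + 1L]] <- tibble(
      parent_id = d$tx_id, frag_a = a$transcript_id[1],
      frag_b = b$transcript_id[1],
      split_intron_start = d$exon_ends[k],
      split_intron_end = d$exon_starts[k + 1L],
      type = if (d$role == "link_frag") "link" else "junction")
    if (d$role == "junction_frag") {
      jrows[[length(jrows) + 1L]] <- tibble(
        chrom = d$chrom, donor_end = d$exon_ends[k],
        acceptor_start = d$exon_starts[k + 1L],
        name = paste0("ncj_", d$gene_id), support = 5L, strand = d$strand)
    }
  }
  # canonical decoy junctions from two intact multi-exon genes
  intact <- truth$gene_meta[truth$gene_meta$role == "plain" &
                              truth$gene_meta$n_exons >= 2, ]
  for (i in seq_len(min(2L, nrow(intact)))) {
    d <- truth$designs[[match(intact$gene_id[i], truth$gene_meta$gene_id)]]
    can <- which(!d$noncanonical)
    if (length(can) == 0) next
    jrows[[length(jrows) + 1L]] <- tibble(
      chrom = d$chrom, donor_end = d$exon_ends[can[1]],
      acceptor_start = d$exon_starts[can[1] + 1L],
      name = paste0("canj_", d$gene_id), support = 9L, strand = d$strand)
  }
  junctions <- if (length(jrows)) {
    annotate_junctions(bind_rows(jrows), truth$genome)
  } else {
    tibble(chrom = character(), donor_end = integer(),
           acceptor_start = integer(), name = character(),
           support = integer(), strand = character(),
           dinucleotides = character(), canonical = logical())
  }
  list(transcripts = validate_transcripts(
         bind_rows(bind_rows(rows), truth$noise)),
       fragments = bind_rows(frags),
       junctions = junctions)
}

#' Simulate linking and decoy long reads
#'
#' Per link fragmentation, `n_linking_reads` reads are sampled from the
#' parent's spliced sequence spanning the split intron (each arm at least
#' 30bp, within the flanking exons), alternating forward and
#' reverse-complement orientation; decoy reads are contained in single
#' models. Substitution errors are planted at the configured rate.
#' A small alignment-record table with known mismatch counts and pair
#' geometries is also emitted for the alignment-filter stage.
#'
#' @param truth A `sim_truth`.
#' @param fragmented Output of [fragment_transcripts()].
#' @param config The matching [sim_config()].
#' @return List: `long_reads` (read tibble), `read_truth` (tibble:
#'   `read_id`, `parent_id`, `linking`), `alignments`,
#'   `alignment_truth` (expected kept flag per record).
#' @export
simulate_reads <- function(truth, fragmented, config = truth$config) {
  set.seed(config$seed + 2L)
  reads <- list(); rtruth <- list()
  link_frags <- fragmented$fragments[fragmented$fragments$type == "link", ]
  for (i in seq_len(nrow(link_frags))) {
    fr <- link_frags[i, ]
    d <- truth$designs[[match(fr$parent_id,
                              vapply(truth$designs, `[[`, character(1), "tx_id"))]]
    bounds <- cumsum(d$el)
    k <- d$split_at
    b <- bounds[k]
    for (r in seq_len(config$n_linking_reads)) {
      a5 <- sample(30:min(55L, d$el[k] - 5L), 1)
      a3 <- sample(30:min(55L, d$el[k + 1L] - 5L), 1)
      seq <- substr(d$fwd_ref, b - a5 + 1L, b + a3)
      if (config$read_error_rate > 0) {
        ch <- strsplit(seq, "")[[1]]
        hit <- which(stats::runif(length(ch)) < config$read_error_rate)
        for (h in hit) ch[h] <- sample(setdiff(c("A", "C", "G", "T"), ch[h]), 1)
        seq <- paste(ch, collapse = "")
      }
      if (r %% 2L == 0L) seq <- revcomp(seq)
      rid <- sprintf("link_%s_%d", fr$parent_id, r)
      reads[[length(reads) + 1L]] <- tibble(
        read_id = rid, sequence = seq,
        quality = strrep("I", nchar(seq)), quality_encoding = "phred+33")
      rtruth[[length(rtruth) + 1L]] <- tibble(
        read_id = rid, parent_id = fr$parent_id, linking = TRUE)
    }
  }
  # decoys contained in one model
  hosts <- truth$gene_meta$transcript_id[truth$gene_meta$role == "plain"]
  for (i in seq_len(config$n_decoy_reads)) {
    tid <- hosts[((i - 1L) %% length(hosts)) + 1L]
    d <- truth$designs[[match(tid,
                              vapply(truth$designs, `[[`, character(1), "tx_id"))]]
    len <- sample(60:100, 1)
    start <- sample(seq_len(max(1L, d$Lc - len)), 1)
    rid <- sprintf("decoy_%02d", i)
    reads[[length(reads) + 1L]] <- tibble(
      read_id = rid, sequence = substr(d$fwd_ref, start, start + len - 1L),
      quality = strrep("I", len), quality_encoding = "phred+33")
    rtruth[[length(rtruth) + 1L]] <- tibble(
      read_id = rid, parent_id = tid, linking = FALSE)
  }
  # alignment records exercising the mismatch / pair-geometry filters
  al <- tibble(
    read_id = c("s1", "s2", "s3", "s4",
                "p1", "p1", "p2", "p2", "p3", "p3", "p4"),
    mate = c(NA, NA, NA, NA, 0L, 1L, 0L, 1L, 0L, 1L, 0L),
    chrom = c("chr1", "chr1", "chr2", "chr1",
              "chr1", "chr1", "chr1", "chr2", "chr1", "chr1", "chr1"),
    pos = c(100L, 200L, 300L, 400L,
            1000L, 1200L, 2000L, 2200L, 3000L, 900000L, 5000L),
    strand = c("+", "-", "+", "+",
               "+", "-", "+", "-", "+", "-", "+"),
    mismatch_count = c(0L, 3L, 4L, 2L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  al_truth <- tibble(
    read_id = al$read_id, mate = al$mate,
    expect_kept = c(TRUE, TRUE, FALSE, TRUE,
                    TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  list(long_reads = bind_rows(reads), read_truth = bind_rows(rtruth),
       alignments = al, alignment_truth = al_truth)
}

passing_metrics <- function(n, genomic = FALSE, with_ranksums = TRUE) {
  tibble(qd = round(stats::runif(n, 5, 30), 2),
         mq = round(stats::runif(n, 50, 60), 2),
         fs = round(stats::runif(n, 0, 10), 2),
         haplotype_score = if (genomic) round(stats::runif(n, 0, 5), 2)
           else NA_real_,
         mq_rank_sum = if (with_ranksums) round(stats::runif(n, -2, 2), 2)
           else NA_real_,
         read_pos_rank_sum = if (with_ranksums) round(stats::runif(n, -2, 2), 2)
           else NA_real_)
}

right_shifted_form <- function(v, genome) {
  # equivalent right-aligned representation of a homopolymer 1bp indel
  b <- v$run_base
  chromseq <- genome[[v$chrom]]
  re <- v$run_start + v$run_len - 1L  # 1-based last run base in the genome
  while (re + 1L <= nchar(chromseq) &&
         substr(chromseq, re + 1L, re + 1L) == b) re <- re + 1L
  if (nchar(v$ref) > nchar(v$alt)) {  # deletion
    list(pos = re - 1L, ref = paste0(b, b), alt = b)
  } else {                            # insertion
    list(pos = re, ref = b, alt = paste0(b, b))
  }
}

#' Simulate RNA, genomic and comparison variant call sets
#'
#' Planted ORF-extending errors appear in the RNA VCF and (for the
#' homozygous class) in the genomic VCF as GT 1/1 with passing metrics;
#' heterozygous decoys appear as GT 0/1; unsupported decoys are RNA-only.
#' Neutral passing variants and records violating exactly one named hard
#' filter rule are added, and each eligible variant enters each comparison
#' set with probability `fraction_shared` — homopolymer indels written at
#' a right-shifted offset in the even-numbered sets to exercise
#' normalization.
#'
#' @param truth A `sim_truth`.
#' @param genome Named character vector (the truth genome).
#' @param config The matching [sim_config()].
#' @return List: `rna` and `genomic` variant tibbles, `comparisons` (named
#'   list of variant tibbles), `variant_truth` (per planted/decoy record:
#'   role, expected filter outcome, mechanism flags, support count).
#' @export
simulate_variants_and_vcfs <- function(truth, genome = truth$genome,
                                       config = truth$config) {
  set.seed(config$seed + 3L)
  pl <- truth$planted
  as_variant <- function(df) {
    out <- empty_variants()[rep(1L, nrow(df))[0], ]
    bind_rows(out, df)
  }
  # --- extending records
  ext <- pl |>
    mutate(genotype = ifelse(.data$role == "het", "0/1", "1/1"),
           ad = ifelse(.data$role == "het",
                       paste(10L + seq_len(nrow(pl)) %% 7L,
                             12L + seq_len(nrow(pl)) %% 9L, sep = ","),
                       paste0("0,", 15L + seq_len(nrow(pl)) %% 25L)))
  mx <- passing_metrics(nrow(ext), genomic = FALSE,
                        with_ranksums = FALSE)
  mx$mq_rank_sum[ext$role == "het"] <-
    round(stats::runif(sum(ext$role == "het"), -2, 2), 2)
  mx$read_pos_rank_sum[ext$role == "het"] <-
    round(stats::runif(sum(ext$role == "het"), -2, 2), 2)
  rna_ext <- bind_cols(select(ext, "chrom", "pos", "ref", "alt",
                              "genotype", "ad", "variant_class"), mx)

  # --- neutral passing variants in 3' UTRs of homozygous hosts
  hom_hosts <- truth$gene_meta$transcript_id[truth$gene_meta$role == "hom"]
  neutral <- list()
  used_pos <- character(0)
  for (i in seq_len(config$n_neutral)) {
    found <- NULL
    # try 3'-UTR-ish positions of the homozygous hosts (starting from a
    # different host per variant) until a substitution leaves the ORF intact
    for (h in seq_along(hom_hosts)) {
      tid <- hom_hosts[((i + h - 2L) %% length(hom_hosts)) + 1L]
      d <- truth$designs[[match(tid, vapply(truth$designs, `[[`,
                                            character(1), "tx_id"))]]
      ts <- build_transcript_sequence(
        truth$genes[truth$genes$transcript_id == tid, ], genome)
      ref_len <- longest_orf_length(ts$seq)
      cand_gpos <- if (d$strand == "-") {
        (d$exon_starts[1L] + 4L):(d$exon_starts[1L] + 18L)
      } else {
        (d$exon_ends[d$n_exons] - 18L):(d$exon_ends[d$n_exons] - 4L)
      }
      for (gp in cand_gpos) {
        if (paste(d$chrom, gp) %in% used_pos) next
        rb <- genome_seq(genome, d$chrom, gp, gp + 1L)
        for (ab in setdiff(c("A", "C", "G", "T"), rb)) {
          ap <- apply_variant_to_transcript(ts, gp + 1L, rb, ab)
          if (ap$status == "ok" && longest_orf_length(ap$seq) == ref_len) {
            found <- tibble(chrom = d$chrom, pos = gp + 1L, ref = rb,
                            alt = ab, variant_class = "snp",
                            host_transcript = tid)
            break
          }
        }
        if (!is.null(found)) break
      }
      if (!is.null(found)) break
    }
    if (is.null(found)) abort("could not place a neutral variant")
    used_pos <- c(used_pos, paste(found$chrom, found$pos))
    neutral[[i]] <- found
  }
  neutral <- bind_rows(neutral)
  rna_neutral <- bind_cols(
    select(neutral, "chrom", "pos", "ref", "alt", "variant_class") |>
      mutate(genotype = "0/1",
             ad = paste(8L + seq_len(nrow(neutral)),
                        9L + seq_len(nrow(neutral)), sep = ",")),
    passing_metrics(nrow(neutral), genomic = FALSE))

  # --- records violating exactly one rule each
  fail_spec <- tibble(
    class = c("snp", "snp", "snp", "snp", "snp",
              "deletion", "deletion", "deletion"),
    rule = c("QD", "MQ", "FS", "MQRankSum", "ReadPosRankSum",
             "QD", "ReadPosRankSum", "FS"))
  other_hosts <- truth$gene_meta$transcript_id[
    truth$gene_meta$role %in% c("het", "unsup", "link_frag")]
  fails <- list()
  for (i in seq_len(nrow(fail_spec))) {
    tid <- other_hosts[((i - 1L) %% length(other_hosts)) + 1L]
    d <- truth$designs[[match(tid, vapply(truth$designs, `[[`,
                                          character(1), "tx_id"))]]
    gp <- d$exon_starts[1L] + 6L + i  # 0-based, inside the first exon
    m <- passing_metrics(1L, with_ranksums = TRUE)
    bad <- fail_spec$rule[i]
    if (fail_spec$class[i] == "snp") {
      rb <- genome_seq(genome, d$chrom, gp, gp + 1L)
      ab <- setdiff(c("A", "C", "G", "T"), rb)[1]
      row <- tibble(chrom = d$chrom, pos = gp + 1L, ref = rb, alt = ab,
                    variant_class = "snp")
      m$qd[bad == "QD"] <- 1.0
      m$mq[bad == "MQ"] <- 30.0
      m$fs[bad == "FS"] <- 80.0
      m$mq_rank_sum[bad == "MQRankSum"] <- -15.0
      m$read_pos_rank_sum[bad == "ReadPosRankSum"] <- -10.0
    } else {
      rb <- genome_seq(genome, d$chrom, gp, gp + 2L)
      row <- tibble(chrom = d$chrom, pos = gp + 1L, ref = rb,
                    alt = substr(rb, 1, 1), variant_class = "deletion")
      m$qd[bad == "QD"] <- 1.0
      m$read_pos_rank_sum[bad == "ReadPosRankSum"] <- -25.0
      m$fs[bad == "FS"] <- 250.0
    }
    fails[[i]] <- bind_cols(mutate(row, genotype = "0/1",
                                   ad = "7,8"), m)
  }
  rna_fail <- bind_rows(fails)

  rna <- as_variant(bind_rows(rna_ext, rna_neutral, rna_fail)) |>
    arrange(.data$chrom, .data$pos)

  # --- genomic VCF: hom (1/1), het (0/1), two neutrals (0/1), one failing
  gen_hom <- rna_ext[ext$role == "hom", ]
  gen_hom$genotype <- "1/1"
  gen_het <- rna_ext[ext$role == "het", ]
  gen_het$genotype <- "0/1"
  gen_neutral <- rna_neutral[seq_len(min(2L, nrow(rna_neutral))), ]
  gmx <- passing_metrics(nrow(gen_hom) + nrow(gen_het) + nrow(gen_neutral),
                         genomic = TRUE)
  genomic <- bind_rows(gen_hom, gen_het, gen_neutral)
  genomic[, names(gmx)] <- gmx
  genomic$mq_rank_sum[genomic$genotype == "1/1"] <- NA_real_
  genomic$read_pos_rank_sum[genomic$genotype == "1/1"] <- NA_real_
  # one genomic record failing the indel QD rule at a fresh site
  d1 <- truth$designs[[1L]]
  gp <- d1$exon_starts[1L] + 40L
  rb <- genome_seq(genome, d1$chrom, gp, gp + 2L)
  gfail <- bind_cols(
    tibble(chrom = d1$chrom, pos = gp + 1L, ref = rb,
           alt = substr(rb, 1, 1), variant_class = "deletion",
           genotype = "1/1", ad = "0,11"),
    within(passing_metrics(1L, genomic = TRUE), qd <- 1.0))
  genomic <- as_variant(bind_rows(genomic, gfail)) |>
    arrange(.data$chrom, .data$pos)

  # --- comparison sets
  eligible <- bind_rows(
    select(ext, "chrom", "pos", "ref", "alt", "variant_class",
           "homopolymer_slip", "run_start", "run_len", "run_base"),
    mutate(select(neutral, "chrom", "pos", "ref", "alt", "variant_class"),
           homopolymer_slip = FALSE, run_start = NA_integer_,
           run_len = NA_integer_, run_base = NA_character_))
  n_sets <- config$n_comparison_datasets
  membership <- matrix(stats::runif(nrow(eligible) * n_sets) <
                         config$fraction_shared,
                       nrow = nrow(eligible))
  comparisons <- list()
  for (s in seq_len(n_sets)) {
    rows <- list()
    for (i in which(membership[, s])) {
      v <- eligible[i, ]
      if (v$homopolymer_slip && s %% 2L == 0L) {
        rf <- right_shifted_form(v, genome)
        rows[[length(rows) + 1L]] <- tibble(
          chrom = v$chrom, pos = rf$pos, ref = rf$ref, alt = rf$alt,
          variant_class = v$variant_class, genotype = "1/1")
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          variant_class = v$variant_class, genotype = "1/1")
      }
    }
    comparisons[[paste0("breed", s)]] <-
      as_variant(if (length(rows)) bind_rows(rows) else
        tibble(chrom = character(), pos = integer()))
  }
  support_k <- rowSums(membership)

  variant_truth <- bind_rows(
    mutate(select(ext, "chrom", "pos", "ref", "alt", "variant_class",
                  "role", "host_transcript", "homopolymer_slip",
                  "intron_mimic"),
           expected_filter = "pass",
           support_k = support_k[seq_len(nrow(ext))]),
    mutate(select(neutral, "chrom", "pos", "ref", "alt", "variant_class",
                  "host_transcript"),
           role = "neutral", homopolymer_slip = FALSE, intron_mimic = FALSE,
           expected_filter = "pass",
           support_k = support_k[nrow(ext) + seq_len(nrow(neutral))]),
    mutate(select(rna_fail, "chrom", "pos", "ref", "alt", "variant_class"),
           role = "fail", host_transcript = NA_character_,
           homopolymer_slip = FALSE, intron_mimic = FALSE,
           expected_filter = fail_spec$rule, support_k = NA_real_))

  list(rna = rna, genomic = genomic, comparisons = comparisons,
       variant_truth = variant_truth)
}

#' Generate the complete synthetic dataset
#'
#' Runs reference/truth generation, fragmentation, read simulation and
#' variant simulation under one seed, then self-checks that every planted
#' extending variant indeed extends its host's longest ORF.
#'
#' @param config A [sim_config()] (or a bare seed).
#' @return List with class `sim_dataset`: `genome`, `annotations`,
#'   `transcripts` (assembled), `truth_transcripts`, `long_reads`,
#'   `alignments`, `junctions`, `rna_variants`, `genomic_variants`,
#'   `comparisons`, `truth` (the `sim_truth` plus fragment/read/variant
#'   truth tables), `evidence` (clean cDNA + long-read sequences).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- sim_config(config)
  truth <- generate_reference_and_truth(config)
  fragged <- fragment_transcripts(truth, config)
  reads <- simulate_reads(truth, fragged, config)
  vcfs <- simulate_variants_and_vcfs(truth, truth$genome, config)

  # emit-time self-check: every planted extending variant extends the ORF
  for (i in seq_len(nrow(truth$planted))) {
    v <- truth$planted[i, ]
    ts <- build_transcript_sequence(
      truth$genes[truth$genes$transcript_id == v$host_transcript, ],
      truth$genome)
    ap <- apply_variant_to_transcript(ts, v$pos, v$ref, v$alt)
    stopifnot(ap$status == "ok")
    if (longest_orf_length(ap$seq) <= longest_orf_length(ts$seq)) {
      abort(paste0("generator self-check failed: planted variant ",
                   v$variant_id, " does not extend the ORF"))
    }
  }
  evidence <- c(
    setNames(vapply(truth$designs, `[[`, character(1), "fwd_clean"),
             paste0("cdna_", vapply(truth$designs, `[[`, character(1),
                                    "tx_id"))),
    setNames(reads$long_reads$sequence, reads$long_reads$read_id))
  truth$fragments <- fragged$fragments
  truth$read_truth <- reads$read_truth
  truth$alignment_truth <- reads$alignment_truth
  truth$variant_truth <- vcfs$variant_truth
  structure(list(
    config = config, genome = truth$genome,
    annotations = truth$annotations,
    transcripts = fragged$transcripts,
    truth_transcripts = truth$genes,
    junctions = fragged$junctions,
    long_reads = reads$long_reads,
    alignments = reads$alignments,
    rna_variants = vcfs$rna, genomic_variants = vcfs$genomic,
    comparisons = vcfs$comparisons,
    evidence = evidence,
    truth = truth
  ), class = "sim_dataset")
}

#' Write a simulated dataset to files
#'
#' Emits the genome FASTA, assembled and truth GTFs, three annotation
#' BED12 files, long-read FASTQ, alignment TSV, junction TSV, RNA /
#' genomic / comparison VCFs and truth tables (TSV + JSON).
#'
#' @param sim A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_genome_fasta(sim$genome, fp("genome.fa"))
  write_gtf(sim$transcripts, fp("assembled.gtf"))
  write_gtf(sim$truth_transcripts, fp("truth.gtf"))
  for (src in sim$annotations$sources) {
    write_bed12_source(sim$annotations, src,
                       fp(paste0("annotation_", src, ".bed")))
  }
  write_fastq(sim$long_reads, fp("long_reads.fastq"))
  readr::write_tsv(sim$alignments, fp("alignments.tsv"))
  readr::write_tsv(sim$junctions, fp("junctions.tsv"))
  write_vcf(sim$rna_variants, fp("rna_variants.vcf"))
  write_vcf(sim$genomic_variants, fp("genomic_variants.vcf"))
  for (nm in names(sim$comparisons)) {
    write_vcf(sim$comparisons[[nm]], fp(paste0("comparison_", nm, ".vcf")))
  }
  readr::write_tsv(sim$truth$variant_truth, fp("truth_variants.tsv"))
  readr::write_tsv(sim$truth$fragments, fp("truth_fragments.tsv"))
  readr::write_tsv(sim$truth$gene_meta, fp("truth_genes.tsv"))
  jsonlite::write_json(
    list(seed = sim$config$seed,
         n_genes = sim$config$n_genes,
         n_planted_errors = nrow(sim$truth$planted)),
    fp("truth_summary.json"), auto_unbox = TRUE)
  invisible(dir)
}

# BED12 lines for one annotation source, reconstructing exon blocks from the
# gene span and its introns
write_bed12_source <- function(annotations, src, path) {
  spans <- annotations$gene_spans[annotations$gene_spans$source == src, ]
  introns <- annotations$introns[annotations$introns$source == src, ]
  lines <- character(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    gi <- introns[introns$chrom == sp$chrom & introns$start >= sp$start &
                    introns$end <= sp$end & introns$strand == sp$strand, ]
    gi <- arrange(gi, .data$start)
    ex_starts <- c(sp$start, gi$end)
    ex_ends <- c(gi$start, sp$end)
    sizes <- ex_ends - ex_starts
    offs <- ex_starts - sp$start
    lines[i] <- paste(sp$chrom, sp$start, sp$end, sp$gene_id, 0, sp$strand,
                      sp$start, sp$end, "0",
                      length(sizes),
                      paste0(paste(sizes, collapse = ","), ","),
                      paste0(paste(offs, collapse = ","), ","),
                      sep = "\t")
  }
  readr::write_lines(lines, path)
  invisible(path)
}
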