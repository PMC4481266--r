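# Readers/writers for the standard formats the pipeline touches.
# FASTA/FASTQ go through Biostrings; GTF, BED12 and VCF are read into the
# minimal tabular model the pipeline needs, with per-line error reporting
# and byte-stable deterministic output.

#' Read a genome FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet A,C,G,T,N.
#'
#' @param path FASTA file.
#' @return Named character vector (one element per chromosome).
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (any(duplicated(names(ss)))) abort("duplicate chromosome name in FASTA")
  if (any(Biostrings::width(ss) == 0)) abort("empty FASTA record")
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  bad <- grepl("[^ACGTN]", g)
  if (any(bad)) {
    abort(paste0("non-ACGTN characters in sequence(s): ",
                 paste(names(g)[bad], collapse = ", ")))
  }
  g
}

#' Write a genome FASTA file
#' @param genome Named character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a FASTQ file into a read table
#'
#' @param path FASTQ file.
#' @param quality_encoding `"phred+33"` (default) or `"phred+64"`.
#' @return Tibble: `read_id`, `sequence`, `quality`, `quality_encoding`.
#' @export
read_fastq <- function(path, quality_encoding = c("phred+33", "phred+64")) {
  quality_encoding <- match.arg(quality_encoding)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(toupper(as.character(ss))),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities)),
    quality_encoding = quality_encoding
  )
}

#' Write a read table as FASTQ
#' @param reads Read tibble (see [read_fastq()]).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$sequence) == nchar(reads$quality)))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", reads$quality))
  readr::write_lines(lines, path)
  invisible(path)
}

# mean phred score of a quality string under an encoding
mean_phred <- function(quality, encoding = "phred+33") {
  offset <- if (identical(encoding, "phred+64")) 64L else 33L
  vapply(quality, function(q) {
    if (nchar(q) == 0) return(NA_real_)
    mean(utf8ToInt(q) - offset)
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- GTF ------------------------------------------------------------------

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; exons are grouped by the `transcript_id`
#' attribute and converted from GTF 1-based inclusive coordinates to the
#' internal 0-based half-open convention. Other attributes are preserved as
#' opaque text in an `attributes` column and written back verbatim.
#'
#' @param path GTF file (or character vector of lines via a connection).
#' @return Validated transcript tibble.
#' @export
read_gtf <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(transcript_tbl(character(), character(), integer(), integer(),
                          character()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 9)) {
    abort(paste0("malformed GTF line ", idx[which(nf < 9)[1]],
                 ": expected 9 tab-separated fields"))
  }
  m <- do.call(rbind, parts)
  feat <- m[, 3]
  ex <- feat == "exon"
  if (!any(ex)) {
    return(transcript_tbl(character(), character(), integer(), integer(),
                          character()))
  }
  starts <- suppressWarnings(as.integer(m[ex, 4]))
  ends <- suppressWarnings(as.integer(m[ex, 5]))
  if (any(is.na(starts) | is.na(ends))) {
    bad <- idx[ex][which(is.na(starts) | is.na(ends))[1]]
    abort(paste0("malformed GTF line ", bad, ": non-numeric coordinates"))
  }
  attr_txt <- m[ex, 9]
  tid <- stringr::str_match(attr_txt, 'transcript_id "([^"]*)"')[, 2]
  if (any(is.na(tid))) {
    bad <- idx[ex][which(is.na(tid))[1]]
    abort(paste0("malformed GTF line ", bad, ": missing transcript_id"))
  }
  gid <- stringr::str_match(attr_txt, 'gene_id "([^"]*)"')[, 2]
  extra <- stringr::str_trim(
    gsub('(gene_id "[^"]*";\\s*)|(transcript_id "[^"]*";\\s*)', "", attr_txt))
  tx <- tibble(
    transcript_id = tid,
    gene_id = gid,
    chrom = m[ex, 1],
    start = starts - 1L,
    end = ends,
    strand = m[ex, 7],
    attributes = ifelse(nzchar(extra), extra, NA_character_)
  )
  out <- tryCatch(validate_transcripts(tx), error = function(e) {
    abort(paste0("GTF validation error: ", conditionMessage(e)))
  })
  out
}

#' Write transcript models as GTF
#'
#' Exon features with 1-based inclusive coordinates, ordered by
#' (chrom, start, transcript_id); byte-identical output for identical input.
#'
#' @param tx Transcript tibble.
#' @param path Output file.
#' @param source Value for the GTF source column.
#' @export
write_gtf <- function(tx, path, source = "txrefine") {
  tx <- validate_transcripts(tx)
  tx <- arrange(tx, .data$chrom, .data$start, .data$transcript_id)
  gid <- ifelse(is.na(tx$gene_id), tx$transcript_id, tx$gene_id)
  attrs <- paste0('gene_id "', gid, '"; transcript_id "', tx$transcript_id, '";')
  if ("attributes" %in% names(tx)) {
    extra <- tx$attributes
    attrs <- ifelse(is.na(extra) | !nzchar(extra), attrs,
                    paste(attrs, extra))
  }
  lines <- paste(tx$chrom, source, "exon", tx$start + 1L, tx$end, ".",
                 tx$strand, ".", attrs, sep = "\t")
  readr::write_lines(lines, path)
  invisible(path)
}

# ---- BED12 ----------------------------------------------------------------

#' Read an annotation source from a BED12 file
#'
#' Gene spans come from columns 1-3 (0-based half-open), strand from column
#' 6, and introns are derived from the gaps between blocks.
#'
#' @param path BED12 file.
#' @param source_label Label for the source, e.g. `"Ensembl"`, `"RefSeq"`,
#'   `"OtherRefSeq"`.
#' @return An annotation set: list with `gene_spans` and `introns` tibbles,
#'   both carrying a `source` column.
#' @export
read_bed12 <- function(path, source_label) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(annotation_set(source_label,
                          tibble(chrom = character(), start = integer(),
                                 end = integer(), gene_id = character(),
                                 strand = character()),
                          tibble(chrom = character(), start = integer(),
                                 end = integer(), strand = character())))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12)) {
    abort(paste0("BED12 line ", which(lengths(parts) < 12)[1],
                 ": fewer than 12 columns"))
  }
  spans <- list()
  introns <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    chrom <- p[1]
    cstart <- as.integer(p[2]); cend <- as.integer(p[3])
    strand <- p[6]
    n_blocks <- as.integer(p[10])
    sizes <- as.integer(strsplit(sub(",$", "", p[11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", p[12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      abort(paste0("BED12 line ", i,
                   ": blockCount inconsistent with block lists"))
    }
    spans[[i]] <- tibble(chrom = chrom, start = cstart, end = cend,
                         gene_id = p[4], strand = strand)
    if (n_blocks > 1) {
      bs <- cstart + offs
      be <- bs + sizes
      introns[[i]] <- tibble(chrom = chrom,
                             start = be[-n_blocks],
                             end = bs[-1],
                             strand = strand)
    }
  }
  annotation_set(source_label, bind_rows(spans),
                 if (length(introns)) bind_rows(introns)
                 else tibble(chrom = character(), start = integer(),
                             end = integer(), strand = character()))
}

#' Bundle gene spans and introns into an annotation set
#'
#' @param source_label Source name (distinct across a collection).
#' @param gene_spans Tibble `chrom`, `start`, `end`, `gene_id` (+ optional
#'   `strand`).
#' @param introns Tibble `chrom`, `start`, `end`, `strand`.
#' @return List with class `annotation_set`.
#' @export
annotation_set <- function(source_label, gene_spans, introns) {
  gene_spans <- as_tibble(gene_spans)
  introns <- as_tibble(introns)
  if (!"strand" %in% names(gene_spans)) gene_spans$strand <- "."
  gene_spans$source <- source_label
  introns$source <- source_label
  introns <- distinct(introns, .data$chrom, .data$start, .data$end,
                      .data$strand, .data$source)
  structure(list(source_label = source_label, gene_spans = gene_spans,
                 introns = introns),
            class = "annotation_set")
}

#' Combine annotation sets into pooled tables
#'
#' @param ... `annotation_set` objects with distinct source labels.
#' @return List with pooled `gene_spans` and `introns` tibbles (a `source`
#'   column distinguishes the sets).
#' @export
bind_annotations <- function(...) {
  sets <- list(...)
  labs <- vapply(sets, function(s) s$source_label, character(1))
  if (anyDuplicated(labs)) abort("annotation source labels must be distinct")
  list(
    sources = labs,
    gene_spans = bind_rows(lapply(sets, function(s) s$gene_spans)),
    introns = bind_rows(lapply(sets, function(s) s$introns))
  )
}

# ---- VCF ------------------------------------------------------------------

VCF_INFO_KEYS <- c("QD", "MQ", "FS", "HaplotypeScore", "MQRankSum",
                   "ReadPosRankSum")

#' Read variant records from a VCF file
#'
#' Parses the columns the pipeline uses: CHROM, POS, REF, ALT (multi-allelic
#' sites kept as one record), the first sample's GT and AD, and the INFO
#' metrics QD, MQ, FS, HaplotypeScore, MQRankSum, ReadPosRankSum. Missing
#' metrics are left absent (`NA`), never zero; a record without GT is
#' flagged genotype-missing rather than dropped.
#'
#' @param path VCF 4.x text file.
#' @return Variant tibble: `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-separated for multi-allelic sites), `genotype` (e.g. `"1/1"`,
#'   `NA` when missing), `ad` (comma-separated allele depths or `NA`), the
#'   six INFO metric columns (`qd`, `mq`, `fs`, `haplotype_score`,
#'   `mq_rank_sum`, `read_pos_rank_sum`) and `variant_class`.
#' @export
read_vcf <- function(path) {
  lines <- readr::read_lines(path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) return(empty_variants())
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) < 8)) {
    abort(paste0("malformed VCF line ", which(lengths(parts) < 8)[1],
                 ": fewer than 8 columns"))
  }
  n <- length(parts)
  get <- function(k) vapply(parts, `[`, character(1), k)
  ref <- toupper(get(4))
  alt <- toupper(get(5))
  if (any(grepl("[^ACGT,]", c(ref, alt)))) {
    abort("malformed allele string in VCF (alphabet is A,C,G,T)")
  }
  info <- get(8)
  info_num <- function(key) {
    v <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    suppressWarnings(as.numeric(v))
  }
  gt <- rep(NA_character_, n)
  ad <- rep(NA_character_, n)
  has_sample <- lengths(parts) >= 10
  if (any(has_sample)) {
    fmt <- strsplit(get(9)[has_sample], ":", fixed = TRUE)
    smp <- strsplit(vapply(parts[has_sample], `[`, character(1), 10),
                    ":", fixed = TRUE)
    gt[has_sample] <- mapply(function(f, s) {
      i <- match("GT", f)
      if (is.na(i) || i > length(s)) NA_character_ else s[[i]]
    }, fmt, smp)
    ad[has_sample] <- mapply(function(f, s) {
      i <- match("AD", f)
      if (is.na(i) || i > length(s)) NA_character_ else s[[i]]
    }, fmt, smp)
  }
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  out <- tibble(
    chrom = get(1),
    pos = as.integer(get(2)),
    ref = ref,
    alt = alt,
    genotype = gt,
    ad = ad,
    qd = info_num("QD"),
    mq = info_num("MQ"),
    fs = info_num("FS"),
    haplotype_score = info_num("HaplotypeScore"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum")
  )
  if (any(is.na(out$pos)) || any(out$pos < 1L)) abort("invalid POS in VCF")
  n_ad <- ifelse(is.na(out$ad), NA_integer_,
                 stringr::str_count(out$ad, ",") + 1L)
  n_alleles <- stringr::str_count(out$alt, ",") + 2L
  if (any(!is.na(n_ad) & n_ad != n_alleles)) {
    abort("AD length must equal 1 + number of ALT alleles")
  }
  out$variant_class <- variant_class(out$ref, out$alt)
  out
}

empty_variants <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), genotype = character(), ad = character(),
         qd = numeric(), mq = numeric(), fs = numeric(),
         haplotype_score = numeric(), mq_rank_sum = numeric(),
         read_pos_rank_sum = numeric(), variant_class = character())
}

#' Variant class from REF/ALT alleles
#'
#' `snp` for equal-length-1 alleles, `insertion`/`deletion` for pure length
#' changes, `mixed` otherwise (including multi-allelic sites whose alleles
#' disagree in class).
#'
#' @param ref,alt Character vectors; `alt` may be comma-separated.
#' @return Character vector of classes.
#' @export
variant_class <- function(ref, alt) {
  one <- function(r, a) {
    if (nchar(r) == 1 && nchar(a) == 1) return("snp")
    if (nchar(a) > nchar(r) && nchar(r) >= 1) {
      if (nchar(r) == 1) return("insertion")
    }
    if (nchar(r) > nchar(a) && nchar(a) >= 1) {
      if (nchar(a) == 1) return("deletion")
    }
    "mixed"
  }
  mapply(function(r, as_) {
    cl <- unique(vapply(strsplit(as_, ",")[[1]], one, character(1), r = r))
    if (length(cl) == 1) cl else "mixed"
  }, ref, alt, USE.NAMES = FALSE)
}

#' Write variant records as VCF
#'
#' A complete single-sample VCF 4.2 file with the INFO metrics the model
#' stores. An optional `filter` column is written into FILTER (pass records
#' get `PASS`, failing records a comma-free reason tag).
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param path Output file.
#' @param sample_name Sample column name.
#' @export
write_vcf <- function(variants, path, sample_name = "sample1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="FisherStrand">',
    '##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description="Haplotype score">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="MQ rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  fmt_num <- function(x) {
    ifelse(is.na(x), NA_character_,
           sub("\\.?0+$", "", sprintf("%.4f", x)))
  }
  info_cols <- list(QD = variants$qd, MQ = variants$mq, FS = variants$fs,
                    HaplotypeScore = variants$haplotype_score,
                    MQRankSum = variants$mq_rank_sum,
                    ReadPosRankSum = variants$read_pos_rank_sum)
  info <- rep("", nrow(variants))
  for (k in names(info_cols)) {
    v <- fmt_num(info_cols[[k]])
    piece <- ifelse(is.na(v), "", paste0(k, "=", v))
    info <- ifelse(nzchar(piece),
                   ifelse(nzchar(info), paste(info, piece, sep = ";"), piece),
                   info)
  }
  info[!nzchar(info)] <- "."
  filt <- if ("filter" %in% names(variants)) {
    ifelse(is.na(variants$filter) | !nzchar(variants$filter), "PASS",
           variants$filter)
  } else rep("PASS", nrow(variants))
  gt <- ifelse(is.na(variants$genotype), "./.", variants$genotype)
  smp <- ifelse(is.na(variants$ad), gt, paste(gt, variants$ad, sep = ":"))
  fmtf <- ifelse(is.na(variants$ad), "GT", "GT:AD")
  body <- paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
                ".", filt, info, fmtf, smp, sep = "\t")
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
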