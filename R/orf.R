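# Variant consequence on the longest open reading frame: spliced transcript
# sequences with a genomic<->transcript coordinate map, per-variant alternate
# sequences, longest-ORF scanning over six frames, effect classification,
# and candidate reference-error calls with mechanistic sub-classification
# (homopolymer slips, intron-mimicking deletions).

#' Build the spliced sequence of one transcript
#'
#' Exon sequences are concatenated 5' to 3'; minus-strand transcripts are
#' reverse-complemented (with the coordinate map adjusted), and strand `.`
#' transcripts are kept in forward genomic orientation (both strands are
#' scanned by the ORF step anyway).
#'
#' @param tx Transcript tibble rows of a single transcript.
#' @param genome Named character vector.
#' @return List with class `transcript_sequence`: `transcript_id`, `chrom`,
#'   `strand`, `seq` (oriented), `fwd_seq` (genomic-forward), `gmap`
#'   (0-based genomic position of each forward-sequence offset).
#' @export
build_transcript_sequence <- function(tx, genome) {
  tx <- validate_transcripts(tx, genome = genome)
  if (dplyr::n_distinct(tx$transcript_id) != 1L) {
    abort("build_transcript_sequence expects exactly one transcript")
  }
  tx <- arrange(tx, .data$start)
  pieces <- mapply(function(s, e) genome_seq(genome, tx$chrom[1], s, e),
                   tx$start, tx$end)
  fwd <- paste(pieces, collapse = "")
  gmap <- unlist(mapply(function(s, e) seq.int(s, e - 1L), tx$start, tx$end,
                        SIMPLIFY = FALSE))
  strand <- tx$strand[1]
  structure(list(
    transcript_id = tx$transcript_id[1],
    chrom = tx$chrom[1],
    strand = strand,
    fwd_seq = fwd,
    gmap = as.integer(gmap),
    seq = if (strand == "-") revcomp(fwd) else fwd
  ), class = "transcript_sequence")
}

#' Spliced sequences for a transcript set
#'
#' @param tx Transcript tibble.
#' @param genome Named character vector.
#' @return Named character vector of genomic-forward spliced sequences.
#' @export
transcript_sequence_set <- function(tx, genome) {
  ids <- unique(tx$transcript_id)
  out <- vapply(ids, function(id) {
    build_transcript_sequence(tx[tx$transcript_id == id, ], genome)$fwd_seq
  }, character(1))
  setNames(out, ids)
}

#' Map a genomic position to a transcript offset
#'
#' @param ts A `transcript_sequence`.
#' @param genomic_pos 0-based genomic position(s).
#' @return 0-based offset(s) in the oriented transcript sequence; `NA` for
#'   intronic or out-of-transcript positions.
#' @export
map_genomic_to_transcript <- function(ts, genomic_pos) {
  fwd_off <- match(genomic_pos, ts$gmap) - 1L
  if (ts$strand == "-") {
    L <- length(ts$gmap)
    ifelse(is.na(fwd_off), NA_integer_, L - 1L - fwd_off)
  } else {
    fwd_off
  }
}

#' Apply one variant allele to a transcript sequence
#'
#' The allele (VCF forward-strand representation, anchored for indels) is
#' applied in forward-genomic space and the result re-oriented to the
#' transcript strand. Variants not fully exonic are skipped with a reason.
#'
#' @param ts A `transcript_sequence`.
#' @param pos 1-based VCF position.
#' @param ref,alt Single REF/ALT allele pair.
#' @return List: `status` (`"ok"`, `"not_exonic"`, `"boundary_overlap"`),
#'   `seq` (alternate oriented sequence when `status == "ok"`).
#' @export
apply_variant_to_transcript <- function(ts, pos, ref, alt) {
  g0 <- seq.int(pos - 1L, pos + nchar(ref) - 2L)
  off <- match(g0, ts$gmap)      # 1-based offsets into fwd_seq
  if (all(is.na(off))) return(list(status = "not_exonic", seq = NULL))
  if (any(is.na(off))) return(list(status = "boundary_overlap", seq = NULL))
  if (length(off) > 1L && any(diff(off) != 1L)) {
    return(list(status = "boundary_overlap", seq = NULL))
  }
  fwd <- ts$fwd_seq
  new_fwd <- paste0(substr(fwd, 1L, off[1] - 1L), alt,
                    substr(fwd, off[length(off)] + 1L, nchar(fwd)))
  list(status = "ok",
       seq = if (ts$strand == "-") revcomp(new_fwd) else new_fwd)
}

codon_positions <- function(seq, codons) {
  # 0-based start positions of any of `codons` in `seq`
  out <- integer()
  for (cd in codons) {
    m <- gregexpr(cd, seq, fixed = TRUE)[[1]]
    if (m[1] != -1) out <- c(out, as.integer(m) - 1L)
  }
  sort(out)
}

scan_orfs_one <- function(seq) {
  # longest ATG..stop ORF (stop included) in the 3 forward frames of seq;
  # returns NULL or list(frame, start, end, length)
  atg <- codon_positions(seq, "ATG")
  stp <- codon_positions(seq, c("TAA", "TAG", "TGA"))
  best <- NULL
  for (f in 0:2) {
    a <- atg[atg %% 3L == f]
    s <- stp[stp %% 3L == f]
    if (length(a) == 0 || length(s) == 0) next
    # first stop strictly after each start
    idx <- findInterval(a, s) + 1L
    ok <- idx <= length(s) & s[pmin(idx, length(s))] > a
    if (!any(ok)) next
    a <- a[ok]; sfirst <- s[idx[ok]]
    len <- sfirst + 3L - a
    i <- which.max(len)
    # prefer the longest; ties by smaller start (which.max on equal lengths
    # picks the first, and starts are sorted ascending)
    cand <- list(frame = f, start = a[i], end = sfirst[i] + 3L,
                 length = len[i])
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start)) {
      best <- cand
    }
  }
  best
}

#' Longest open reading frame of a sequence
#'
#' The maximal ATG-to-stop ORF (stop codon included, no internal in-frame
#' stop) over the 3 frames of the sequence and, when
#' `scan_both_strands`, of its reverse complement. Ties prefer the forward
#' scan, then the smaller start offset. Mode `"stop_to_stop"` instead
#' measures maximal codon runs free of in-frame stops (the convention some
#' ORF finders default to).
#'
#' @param seq Nucleotide sequence.
#' @param scan_both_strands Scan the reverse complement too (default TRUE;
#'   appropriate when library strandedness is unreliable).
#' @param mode `"atg_to_stop"` (default) or `"stop_to_stop"`.
#' @return One-row tibble (`strand`, `frame`, `start`, `end`, `length`) or
#'   `NULL` when no ORF exists.
#' @export
longest_orf <- function(seq, scan_both_strands = TRUE,
                        mode = c("atg_to_stop", "stop_to_stop")) {
  mode <- match.arg(mode)
  seq <- toupper(seq)
  scan1 <- if (mode == "atg_to_stop") scan_orfs_one else scan_stop_to_stop_one
  best <- scan1(seq)
  best_strand <- "forward"
  if (scan_both_strands) {
    rc <- scan1(revcomp(seq))
    if (!is.null(rc) && (is.null(best) || rc$length > best$length)) {
      best <- rc
      best_strand <- "reverse"
    }
  }
  if (is.null(best)) return(NULL)
  tibble(strand = best_strand, frame = best$frame, start = best$start,
         end = best$end, length = best$length)
}

scan_stop_to_stop_one <- function(seq) {
  n <- nchar(seq)
  stp <- codon_positions(seq, c("TAA", "TAG", "TGA"))
  best <- NULL
  for (f in 0:2) {
    s <- stp[stp %% 3L == f]
    bounds <- c(f - 3L, s, n - ((n - f) %% 3L))
    for (i in seq_len(length(bounds) - 1L)) {
      start <- bounds[i] + 3L
      end <- bounds[i + 1L]
      len <- end - start
      if (len >= 3L && (is.null(best) || len > best$length)) {
        best <- list(frame = f, start = start, end = end, length = len)
      }
    }
  }
  best
}

#' Longest-ORF length helper
#'
#' @param seq Nucleotide sequence.
#' @inheritParams longest_orf
#' @return ORF length in nt (0 when no ORF).
#' @export
longest_orf_length <- function(seq, scan_both_strands = TRUE,
                               mode = "atg_to_stop") {
  o <- longest_orf(seq, scan_both_strands, mode)
  if (is.null(o)) 0L else o$length
}

#' Classify the ORF effect of each variant allele on its host transcripts
#'
#' Every (transcript, exonic allele) pair gets the longest-ORF length of
#' the reference and the variant-applied spliced sequence, computed under
#' identical settings, and an effect label: `extending`, `shortening` or
#' `neutral` from the sign of the length change. One variant is applied at
#' a time.
#'
#' @param tx Transcript tibble.
#' @param genome Named character vector.
#' @param alleles Per-allele variant tibble (normalized; see
#'   [normalize_alleles()]).
#' @param scan_both_strands Passed to [longest_orf()].
#' @return Tibble: `chrom`, `pos`, `ref`, `alt`, `allele_class`,
#'   `transcript_id`, `orf_ref`, `orf_alt`, `effect`, `status` (skip
#'   reasons propagate; skipped pairs have `NA` lengths/effect).
#' @export
classify_orf_effect <- function(tx, genome, alleles,
                                scan_both_strands = TRUE) {
  tx <- validate_transcripts(tx)
  out <- list()
  for (id in unique(tx$transcript_id)) {
    ts <- build_transcript_sequence(tx[tx$transcript_id == id, ], genome)
    va <- alleles[alleles$chrom == ts$chrom, ]
    if (nrow(va) == 0) next
    # candidate alleles: any ref base exonic in this transcript
    touches <- vapply(seq_len(nrow(va)), function(i) {
      any(seq.int(va$pos[i] - 1L, va$pos[i] + nchar(va$ref[i]) - 2L)
          %in% ts$gmap)
    }, logical(1))
    va <- va[touches, ]
    if (nrow(va) == 0) next
    orf_ref <- longest_orf_length(ts$seq, scan_both_strands)
    for (i in seq_len(nrow(va))) {
      ap <- apply_variant_to_transcript(ts, va$pos[i], va$ref[i], va$alt[i])
      if (ap$status != "ok") {
        out[[length(out) + 1L]] <- tibble(
          chrom = va$chrom[i], pos = va$pos[i], ref = va$ref[i],
          alt = va$alt[i], allele_class = va$allele_class[i],
          transcript_id = id, orf_ref = NA_integer_, orf_alt = NA_integer_,
          effect = NA_character_, status = ap$status)
        next
      }
      orf_alt <- longest_orf_length(ap$seq, scan_both_strands)
      effect <- if (orf_alt > orf_ref) "extending"
        else if (orf_alt < orf_ref) "shortening" else "neutral"
      out[[length(out) + 1L]] <- tibble(
        chrom = va$chrom[i], pos = va$pos[i], ref = va$ref[i],
        alt = va$alt[i], allele_class = va$allele_class[i],
        transcript_id = id, orf_ref = orf_ref, orf_alt = orf_alt,
        effect = effect, status = "ok")
    }
  }
  if (length(out)) bind_rows(out) else
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), allele_class = character(),
           transcript_id = character(), orf_ref = integer(),
           orf_alt = integer(), effect = character(), status = character())
}

#' Call candidate reference-genome errors
#'
#' For each ORF-extending variant, the genomic resequencing support class
#' is `homozygous` when a matching hard-filter-passing genomic record is
#' homozygous for the alternate allele, `heterozygous` when it is a mixed
#' (ref + alt) call, and `unsupported` when no matching genomic record
#' exists. Homozygous-class calls are candidate reference errors: the
#' reference individual's own DNA agrees with the RNA against the
#' reference sequence.
#'
#' @param effects Output of [classify_orf_effect()].
#' @param genomic_passing Hard-filter-passing genomic variant tibble.
#' @param genome Named character vector.
#' @param annotation_introns Pooled annotation introns (for the
#'   intron-mimic flag).
#' @param tolerance Intron-mimic proximity tolerance in bp (default 10).
#' @return Tibble: effect columns plus `support_class`,
#'   `candidate_reference_error`, `homopolymer_slip`, `intron_mimic`.
#' @export
call_reference_errors <- function(effects, genomic_passing, genome,
                                  annotation_introns = NULL,
                                  tolerance = 10L) {
  ext <- effects[!is.na(effects$effect) & effects$effect == "extending", ]
  if (nrow(ext) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), allele_class = character(),
                  transcript_id = character(), orf_ref = integer(),
                  orf_alt = integer(), effect = character(),
                  status = character(), support_class = character(),
                  candidate_reference_error = logical(),
                  homopolymer_slip = logical(), intron_mimic = logical()))
  }
  gen <- classify_genotype_position(genomic_passing)
  gal <- normalize_alleles(expand_alleles(gen), genome)
  gkey <- allele_key(gal)
  ekey <- allele_key(ext)
  m <- match(ekey, gkey)
  support <- ifelse(is.na(m), "unsupported",
                    ifelse(gal$genotype_category[m] == "homozygous_alt",
                           "homozygous",
                           ifelse(gal$genotype_category[m] == "mixed_allele",
                                  "heterozygous", "unsupported")))
  ext$support_class <- support
  ext$candidate_reference_error <- support == "homozygous"
  mech <- classify_error_mechanism(ext, genome, annotation_introns, tolerance)
  ext$homopolymer_slip <- mech$homopolymer_slip
  ext$intron_mimic <- mech$intron_mimic
  ext
}

#' Classify the mechanism behind an indel
#'
#' `homopolymer_slip` is true when every inserted or deleted base equals
#' the genomic base immediately adjacent to the event (either flank,
#' checked after normalization) — the classic Sanger/pyrosequencing
#' run-length error. `intron_mimic` is true for deletions whose length
#' equals some annotated intron's length with the deletion start within
#' `tolerance` bp of that intron's start — suggestive of mis-assembled
#' reference sequence at a splice boundary. SNPs get both flags false.
#'
#' @param alleles Normalized per-allele tibble.
#' @param genome Named character vector.
#' @param annotation_introns Pooled annotation introns (or `NULL`).
#' @param tolerance Proximity tolerance in bp (default 10).
#' @return Tibble with logical `homopolymer_slip` and `intron_mimic`.
#' @export
classify_error_mechanism <- function(alleles, genome,
                                     annotation_introns = NULL,
                                     tolerance = 10L) {
  n <- nrow(alleles)
  slip <- logical(n); mimic <- logical(n)
  for (i in seq_len(n)) {
    ref <- alleles$ref[i]; alt <- alleles$alt[i]
    chrom <- alleles$chrom[i]; pos <- alleles$pos[i]
    cls <- variant_class(ref, alt)
    if (!cls %in% c("insertion", "deletion")) next
    event <- if (cls == "insertion") substr(alt, 2, nchar(alt)) else
      substr(ref, 2, nchar(ref))
    bases <- unique(strsplit(event, "")[[1]])
    if (length(bases) == 1) {
      left <- genome_seq(genome, chrom, pos - 1L, pos)  # anchor base
      right_pos <- if (cls == "deletion") pos + nchar(ref) - 1L else pos
      chrom_len <- nchar(genome[[chrom]])
      right <- if (right_pos < chrom_len) {
        genome_seq(genome, chrom, right_pos, right_pos + 1L)
      } else ""
      slip[i] <- bases == left || bases == right
    }
    if (cls == "deletion" && !is.null(annotation_introns)) {
      del_len <- nchar(ref) - 1L
      del_start0 <- pos  # 0-based first deleted base
      ann <- annotation_introns[annotation_introns$chrom == chrom, ]
      if (nrow(ann) > 0) {
        mimic[i] <- any((ann$end - ann$start) == del_len &
                          abs(ann$start - del_start0) <= tolerance)
      }
    }
  }
  tibble(homopolymer_slip = slip, intron_mimic = mimic)
}
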