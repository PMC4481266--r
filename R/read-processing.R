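# Read trimming, alignment-record filtering, and long-read end-segment
# preparation. These are the desk-scale equivalents of the short-read QC
# steps that precede assembly: B-tail/N end trimming, 3' linker removal,
# mismatch and insert-size filtering of alignment records, and conversion of
# long reads into 2x25bp end-segment pairs used for fragment linking.

#' Trim N / quality-'B' runs from read ends
#'
#' Removes the maximal 5' and 3' runs of positions whose base is `N` or
#' whose quality character is `'B'` (the Illumina-1.5 low-quality read
#' segment marker; the comparison is by character under the declared
#' encoding, not by numeric threshold). Interior positions are untouched
#' and the operation is idempotent.
#'
#' @param reads Read tibble (`read_id`, `sequence`, `quality`,
#'   `quality_encoding`).
#' @return Read tibble with trimmed `sequence`/`quality` and a logical
#'   `fully_trimmed` column for reads trimmed to length zero.
#' @export
trim_read_ends <- function(reads) {
  trim1 <- function(seq, qual) {
    n <- nchar(seq)
    if (n == 0) return(c("", ""))
    bad <- strsplit(seq, "")[[1]] == "N" | strsplit(qual, "")[[1]] == "B"
    keep <- which(!bad)
    if (length(keep) == 0) return(c("", ""))
    c(substr(seq, keep[1], keep[length(keep)]),
      substr(qual, keep[1], keep[length(keep)]))
  }
  out <- t(mapply(trim1, reads$sequence, reads$quality))
  reads$sequence <- unname(out[, 1])
  reads$quality <- unname(out[, 2])
  reads$fully_trimmed <- !nzchar(reads$sequence)
  reads
}

#' Trim a 3' sequencing linker
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adapter, provided the overlap is at least `min_overlap`; quality is
#' trimmed in lockstep.
#'
#' @param reads Read tibble.
#' @param adapter Adapter/linker sequence (non-empty).
#' @param min_overlap Minimum suffix/prefix overlap (default 5).
#' @return Read tibble with trimmed sequences.
#' @export
trim_adapter_3p <- function(reads, adapter, min_overlap = 5L) {
  if (!nzchar(adapter)) abort("adapter sequence must be non-empty")
  trim1 <- function(seq) {
    L <- nchar(seq)
    max_ov <- min(L, nchar(adapter))
    for (ov in seq_len(max_ov)[order(seq_len(max_ov), decreasing = TRUE)]) {
      if (ov < min_overlap) break
      if (substr(seq, L - ov + 1L, L) == substr(adapter, 1L, ov)) {
        return(L - ov)
      }
    }
    L
  }
  keep_len <- vapply(reads$sequence, trim1, integer(1), USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, keep_len)
  reads$quality <- substr(reads$quality, 1L, keep_len)
  reads
}

#' Filter alignment records by mismatches and pair geometry
#'
#' Drops records with more than `max_mismatches` mismatches, and drops both
#' mates of a pair unless they are on the same chromosome, on opposite
#' strands, and their 5'-to-5' span lies within `[insert_min, insert_max]`.
#' Orphan mates (paired reads with a single surviving record) are dropped
#' and counted.
#'
#' @param alignments Tibble: `read_id`, `mate` (0/1 or `NA` for single-end),
#'   `chrom`, `pos` (0-based), `strand`, `mismatch_count`.
#' @param max_mismatches Maximum mismatches to keep a record (default 3).
#' @param insert_min,insert_max Allowed 5'-to-5' pair span in bp
#'   (defaults 1 and 500000).
#' @return List: `kept` (tibble), `dropped` (tibble with a `reason` column).
#' @export
filter_alignments <- function(alignments, max_mismatches = 3L,
                              insert_min = 1L, insert_max = 500000L) {
  al <- as_tibble(alignments)
  al$.row <- seq_len(nrow(al))
  reason <- rep(NA_character_, nrow(al))
  reason[al$mismatch_count > max_mismatches] <- "too_many_mismatches"

  paired <- !is.na(al$mate)
  if (any(paired)) {
    ok_mm <- is.na(reason)
    pr <- al[paired & ok_mm, ]
    by_read <- split(pr, pr$read_id)
    for (rid in names(by_read)) {
      g <- by_read[[rid]]
      rows <- g$.row
      if (nrow(g) != 2L || length(unique(g$mate)) != 2L) {
        reason[rows] <- "orphan_mate"
        next
      }
      same_chrom <- g$chrom[1] == g$chrom[2]
      opp_strand <- g$strand[1] != g$strand[2]
      span <- abs(g$pos[1] - g$pos[2]) + 1L
      if (!same_chrom || !opp_strand) {
        reason[rows] <- "improper_pair"
      } else if (span < insert_min || span > insert_max) {
        reason[rows] <- "insert_size"
      }
    }
    # a mate dropped for mismatches orphans its partner
    orphaned <- paired & is.na(reason) &
      al$read_id %in% al$read_id[paired & !is.na(reason)]
    reason[orphaned] <- "orphan_mate"
  }
  kept <- al[is.na(reason), setdiff(names(al), ".row")]
  dropped <- al[!is.na(reason), setdiff(names(al), ".row")]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = kept, dropped = dropped)
}

#' Convert long reads to 2x25bp end-segment pairs
#'
#' Reads of at least `min_length` nt contribute a 5' segment (bases 1-25)
#' and a 3' segment (last 25 bases). Pairs where either segment's mean
#' phred quality is below `min_quality` are skipped (boundary inclusive:
#' mean of exactly `min_quality` is kept).
#'
#' @param long_reads Read tibble.
#' @param min_length Minimum read length (default 50).
#' @param min_quality Minimum mean segment phred (default 28).
#' @param segment_length Segment size (default 25).
#' @param quality_mode `"mean"` (default) or `"min"` per-base minimum.
#' @return List: `pairs` tibble (`read_id`, `seg5_seq`, `seg5_qual`,
#'   `seg3_seq`, `seg3_qual`), and `skipped` counts by reason.
#' @export
prepare_segment_pairs <- function(long_reads, min_length = 50L,
                                  min_quality = 28, segment_length = 25L,
                                  quality_mode = c("mean", "min")) {
  quality_mode <- match.arg(quality_mode)
  L <- nchar(long_reads$sequence)
  too_short <- L < min_length
  r <- long_reads[!too_short, ]
  Lr <- nchar(r$sequence)
  seg5_seq <- substr(r$sequence, 1L, segment_length)
  seg5_qual <- substr(r$quality, 1L, segment_length)
  seg3_seq <- substr(r$sequence, Lr - segment_length + 1L, Lr)
  seg3_qual <- substr(r$quality, Lr - segment_length + 1L, Lr)
  enc <- if ("quality_encoding" %in% names(r) && nrow(r) > 0) {
    r$quality_encoding[1]
  } else "phred+33"
  segq <- function(q) {
    if (quality_mode == "mean") mean_phred(q, enc)
    else vapply(q, function(x) {
      offset <- if (identical(enc, "phred+64")) 64L else 33L
      min(utf8ToInt(x) - offset)
    }, numeric(1), USE.NAMES = FALSE)
  }
  low_q <- segq(seg5_qual) < min_quality | segq(seg3_qual) < min_quality
  pairs <- tibble(
    read_id = r$read_id[!low_q],
    seg5_seq = seg5_seq[!low_q], seg5_qual = seg5_qual[!low_q],
    seg3_seq = seg3_seq[!low_q], seg3_qual = seg3_qual[!low_q]
  )
  list(pairs = pairs,
       skipped = c(too_short = sum(too_short), low_quality = sum(low_q)))
}
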