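# Evidence-based filtering of single- and two-exon transcripts: exact local
# alignment against an evidence database (long reads plus coding sequences),
# raw scores converted to bits via the Karlin-Altschul rescaling, transcripts
# below the bit-score cutoff excluded.

#' Alignment scoring scheme
#'
#' Bundles the local-alignment rewards/penalties with the Karlin-Altschul
#' parameters used for the bit-score conversion. The defaults (+1/-2,
#' gap open -5, gap extend -2, lambda 1.28, K 0.46) are the standard
#' approximations for +1/-2 nucleotide scoring; all constants are
#' configuration, not assumptions baked into the filter.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Affine gap penalties (< 0); a gap of length L
#'   scores `gap_open + L * gap_extend`.
#' @param lambda Karlin-Altschul lambda (nats per raw-score unit, > 0).
#' @param K Karlin-Altschul K (0 < K < 1).
#' @return List with class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -2, lambda = 1.28, K = 0.46) {
  if (match <= 0 || mismatch >= 0 || gap_open >= 0 || gap_extend >= 0) {
    abort("match must be positive; penalties negative")
  }
  if (lambda <= 0 || K <= 0 || K >= 1) abort("need lambda > 0 and 0 < K < 1")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' Local alignment raw score
#'
#' Maximal Smith-Waterman local alignment score under the scheme, with
#' affine gap penalties. `N` never counts as a match. The score is 0 when
#' no positive-scoring local alignment exists (including empty input).
#'
#' @param seq_a,seq_b Nucleotide sequences over A,C,G,T,N.
#' @param scheme A [scoring_scheme()].
#' @return Numeric raw score (>= 0).
#' @export
local_align_score <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  .sw_score(toupper(seq_a), toupper(seq_b), scheme$match, scheme$mismatch,
            scheme$gap_open, scheme$gap_extend)
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * S - ln K) / ln 2` for `S > 0`; a raw score of 0 is
#' reported as 0 bits by convention.
#'
#' @param raw_score Raw score (>= 0), vectorized.
#' @param scheme A [scoring_scheme()].
#' @return Bit scores.
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  ifelse(raw_score > 0,
         (scheme$lambda * raw_score - log(scheme$K)) / log(2),
         0)
}

#' Filter single- and two-exon transcripts lacking evidence
#'
#' Transcripts with more than `max_exons_filtered` exons are always kept. A
#' transcript with 1 or 2 exons is kept only if its best local-alignment bit
#' score against any evidence sequence reaches `threshold_bits` (boundary
#' inclusive: exactly the threshold is kept).
#'
#' @param tx Transcript tibble.
#' @param genome Named character vector (used to build transcript
#'   sequences).
#' @param evidence Named character vector of evidence sequences (pooled
#'   long reads and coding sequences).
#' @param scheme A [scoring_scheme()].
#' @param threshold_bits Bit-score cutoff (default 400).
#' @param max_exons_filtered Exon-count ceiling for filtering (default 2).
#' @return List: `kept` and `excluded` transcript tibbles (a disjoint,
#'   exhaustive partition of the input) and `hits` (best hit per evaluated
#'   transcript: `transcript_id`, `subject_id`, `raw_score`, `bit_score`).
#' @export
filter_low_evidence <- function(tx, genome, evidence,
                                scheme = scoring_scheme(),
                                threshold_bits = 400,
                                max_exons_filtered = 2L) {
  tx <- validate_transcripts(tx)
  spans <- transcript_spans(tx)
  small_ids <- spans$transcript_id[spans$n_exons <= max_exons_filtered]
  if (length(small_ids) > 0 && length(evidence) == 0) {
    warn("empty evidence set: all 1-2 exon transcripts will be excluded")
  }
  seqs <- transcript_sequence_set(tx[tx$transcript_id %in% small_ids, ], genome)
  hits <- list()
  keep_small <- character()
  for (id in small_ids) {
    best_raw <- 0; best_subj <- NA_character_
    for (k in seq_along(evidence)) {
      raw <- local_align_score(seqs[[id]], evidence[[k]], scheme)
      if (raw > best_raw) {
        best_raw <- raw
        best_subj <- if (!is.null(names(evidence))) names(evidence)[k] else
          as.character(k)
      }
    }
    bits <- bit_score(best_raw, scheme)
    hits[[length(hits) + 1L]] <- tibble(
      transcript_id = id, subject_id = best_subj,
      raw_score = best_raw, bit_score = bits)
    if (bits >= threshold_bits) keep_small <- c(keep_small, id)
  }
  excl_ids <- setdiff(small_ids, keep_small)
  list(
    kept = tx[!tx$transcript_id %in% excl_ids, ],
    excluded = tx[tx$transcript_id %in% excl_ids, ],
    hits = if (length(hits)) bind_rows(hits) else
      tibble(transcript_id = character(), subject_id = character(),
             raw_score = numeric(), bit_score = numeric())
  )
}
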