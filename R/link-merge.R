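# Fragment linking: long reads whose 25bp end segments land in two different
# assembled transcripts propose a connection; the full read is then
# split-aligned across the gap and the implied intron accepted only when it
# lies within a small tolerance of an annotated intron. Non-canonical splice
# junctions provide a second, junction-based merge route. Accepted links are
# applied as connected components.

#' Align a 25bp end segment to transcript sequences
#'
#' Exhaustive scan of both orientations of every transcript sequence for
#' placements with at most `max_mismatches` mismatches. A segment with more
#' than `max_hits` placements is treated as multi-mapped and discarded
#' (returns zero hits, flagged via the `multimapped` attribute).
#'
#' @param segment Segment sequence (must be `segment_length` long).
#' @param tx_seqs Named character vector of spliced transcript sequences
#'   (genomic-forward orientation; see [build_transcript_sequence()]).
#' @param max_hits Maximum placements before the segment is discarded
#'   (default 3).
#' @param max_mismatches Maximum mismatches per placement (default 1).
#' @param segment_length Expected segment length (default 25).
#' @return Tibble: `transcript_id`, `offset` (0-based within the transcript
#'   sequence), `strand` (of the segment relative to the sequence),
#'   `mismatches`.
#' @export
align_segment <- function(segment, tx_seqs, max_hits = 3L,
                          max_mismatches = 1L, segment_length = 25L) {
  if (nchar(segment) != segment_length) {
    abort(paste0("segment must be ", segment_length, "bp"))
  }
  subject <- Biostrings::DNAStringSet(tx_seqs)
  hits <- list()
  for (st in c("+", "-")) {
    pat <- if (st == "+") segment else revcomp(segment)
    m <- Biostrings::vmatchPattern(pat, subject,
                                   max.mismatch = max_mismatches)
    for (i in seq_along(m)) {
      if (length(m[[i]]) == 0) next
      starts <- BiocGenerics::start(m[[i]])
      ok <- starts >= 1L &
        starts + segment_length - 1L <= Biostrings::width(subject)[i]
      for (s0 in starts[ok]) {
        ref <- substr(tx_seqs[[i]], s0, s0 + segment_length - 1L)
        mm <- sum(strsplit(ref, "")[[1]] != strsplit(pat, "")[[1]])
        if (mm <= max_mismatches) {
          hits[[length(hits) + 1L]] <- tibble(
            transcript_id = names(tx_seqs)[i],
            offset = s0 - 1L, strand = st, mismatches = mm)
        }
      }
    }
  }
  out <- if (length(hits)) distinct(bind_rows(hits)) else
    tibble(transcript_id = character(), offset = integer(),
           strand = character(), mismatches = integer())
  if (nrow(out) > max_hits) {
    out <- out[0, ]
    attr(out, "multimapped") <- TRUE
  } else {
    attr(out, "multimapped") <- FALSE
  }
  out
}

#' Align both segments of each end-segment pair
#'
#' @param pairs Segment-pair tibble from [prepare_segment_pairs()].
#' @param tx_seqs Named character vector of transcript sequences.
#' @inheritParams align_segment
#' @return Tibble of hits with `read_id` and `segment` (`"5"` or `"3"`).
#' @export
align_segment_pairs <- function(pairs, tx_seqs, max_hits = 3L,
                                max_mismatches = 1L) {
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    for (seg in c("5", "3")) {
      s <- if (seg == "5") pairs$seg5_seq[i] else pairs$seg3_seq[i]
      h <- align_segment(s, tx_seqs, max_hits, max_mismatches,
                         segment_length = nchar(s))
      if (nrow(h)) {
        h$read_id <- pairs$read_id[i]
        h$segment <- seg
        res[[length(res) + 1L]] <- h
      }
    }
  }
  if (length(res)) {
    select(bind_rows(res), "read_id", "segment", "transcript_id",
           "offset", "strand", "mismatches")
  } else {
    tibble(read_id = character(), segment = character(),
           transcript_id = character(), offset = integer(),
           strand = character(), mismatches = integer())
  }
}

#' Find potentially linking reads
#'
#' A read proposes a link when its two end segments hit two different
#' transcripts in proper orientation (segment strands equal, and the 5'
#' segment's transcript upstream in genomic order for `+` orientation,
#' downstream for `-`), the transcripts are on the same genomic strand
#' (`.` is compatible with either), and the genomic gap between the
#' transcript spans is at most `max_gap`.
#'
#' @param segment_hits Hits from [align_segment_pairs()].
#' @param tx Transcript tibble of the targets.
#' @param max_gap Maximum span gap in bp (default 200000).
#' @return Tibble: `read_id`, `tx_upstream`, `tx_downstream`, `gap`,
#'   `read_orientation` (`+` when the read runs genomic-forward),
#'   `orientation_ok`, `same_strand` (all emitted candidates satisfy both).
#' @export
find_link_candidates <- function(segment_hits, tx, max_gap = 200000L) {
  spans <- transcript_spans(tx)
  empty <- tibble(read_id = character(), tx_upstream = character(),
                  tx_downstream = character(), gap = integer(),
                  read_orientation = character(),
                  orientation_ok = logical(), same_strand = logical())
  if (nrow(segment_hits) == 0) return(empty)
  out <- list()
  for (rid in unique(segment_hits$read_id)) {
    h5 <- segment_hits[segment_hits$read_id == rid & segment_hits$segment == "5", ]
    h3 <- segment_hits[segment_hits$read_id == rid & segment_hits$segment == "3", ]
    if (nrow(h5) == 0 || nrow(h3) == 0) next
    for (i in seq_len(nrow(h5))) for (j in seq_len(nrow(h3))) {
      a <- h5[i, ]; b <- h3[j, ]
      if (a$transcript_id == b$transcript_id) next
      if (a$strand != b$strand) next
      sa <- spans[spans$transcript_id == a$transcript_id, ]
      sb <- spans[spans$transcript_id == b$transcript_id, ]
      if (sa$chrom != sb$chrom) next
      strands_ok <- sa$strand == sb$strand || sa$strand == "." ||
        sb$strand == "."
      if (!strands_ok) next
      # genomic-forward read: 5' segment's transcript must be upstream
      if (a$strand == "+") {
        up <- sa; dn <- sb
      } else {
        up <- sb; dn <- sa
      }
      if (up$end > dn$start) next
      gap <- dn$start - up$end
      if (gap > max_gap) next
      out[[length(out) + 1L]] <- tibble(
        read_id = rid, tx_upstream = up$transcript_id,
        tx_downstream = dn$transcript_id, gap = gap,
        read_orientation = a$strand,
        orientation_ok = TRUE, same_strand = TRUE)
    }
  }
  if (length(out)) distinct(bind_rows(out)) else empty
}

# min-mismatch contiguous placements of a pattern inside a region.
# Returns matrix: rows = placement offsets (0-based within region), cols =
# prefix lengths; entry = mismatch count of pattern[1..s] placed at offset p.
placement_costs <- function(pattern_chars, region_chars) {
  L <- length(pattern_chars)
  R <- length(region_chars)
  n_off <- R - L + 1L
  if (n_off < 1L) return(NULL)
  cost <- matrix(0L, nrow = n_off, ncol = L)
  for (i in seq_len(L)) {
    mism <- as.integer(region_chars[i:(i + n_off - 1L)] != pattern_chars[i])
    cost[, i] <- if (i == 1L) mism else cost[, i - 1L] + mism
  }
  cost
}

#' Refine a link candidate by split alignment of the full read
#'
#' The full read (oriented genomic-forward) is split at every position; the
#' prefix is placed contiguously within the upstream transcript's terminal
#' (3'-most) exon and the suffix within the downstream transcript's first
#' exon, minimizing total mismatches. The implied intron — prefix placement
#' end to suffix placement start — is accepted only if some annotated
#' intron on the same chromosome has both |donor - donor| and
#' |acceptor - acceptor| at most `tolerance`. Among mismatch-co-optimal
#' splits, one whose intron matches annotation is preferred.
#'
#' @param read_seq Full read sequence.
#' @param genome Named character vector.
#' @param candidate One row of [find_link_candidates()] output.
#' @param tx Transcript tibble containing both candidate transcripts.
#' @param annotation_introns Pooled annotation introns
#'   (tibble `chrom`, `start`, `end`).
#' @param tolerance Donor/acceptor tolerance in bp (default 10).
#' @param max_mismatches Total mismatch cap for the split alignment
#'   (default 2).
#' @return List with `status` (`"merged"` or `"rejected"`), `reason` when
#'   rejected, and on success `link` (tibble: `tx_upstream`,
#'   `tx_downstream`, `intron_start`, `intron_end`, `mismatches`,
#'   `read_id`).
#' @export
refine_link <- function(read_seq, genome, candidate, tx, annotation_introns,
                        tolerance = 10L, max_mismatches = 2L) {
  up <- tx[tx$transcript_id == candidate$tx_upstream, ]
  dn <- tx[tx$transcript_id == candidate$tx_downstream, ]
  chrom <- up$chrom[1]
  if (identical(candidate$read_orientation, "-")) read_seq <- revcomp(read_seq)
  rd <- strsplit(read_seq, "")[[1]]
  L <- length(rd)
  if (L < 2L) return(list(status = "rejected", reason = "read_too_short"))
  up_exon <- up[which.max(up$start), ]   # terminal exon of upstream model
  dn_exon <- dn[which.min(dn$start), ]   # first exon of downstream model
  regU <- strsplit(genome_seq(genome, chrom, up_exon$start, up_exon$end), "")[[1]]
  regD <- strsplit(genome_seq(genome, chrom, dn_exon$start, dn_exon$end), "")[[1]]

  best <- NULL
  ann <- annotation_introns[annotation_introns$chrom == chrom, ]
  for (s in seq_len(L - 1L)) {
    pre <- rd[seq_len(s)]
    suf <- rd[(s + 1L):L]
    costU <- placement_costs(pre, regU)
    costD <- placement_costs(suf, regD)
    if (is.null(costU) || is.null(costD)) next
    cu <- costU[, s]
    cd <- costD[, length(suf)]
    mu <- min(cu); md <- min(cd)
    total <- mu + md
    if (total > max_mismatches) next
    # donors for all optimal prefix placements; acceptors likewise
    donors <- up_exon$start + (which(cu == mu) - 1L) + s
    acceptors <- dn_exon$start + (which(cd == md) - 1L)
    for (d in donors) for (a in acceptors) {
      if (d >= a) next
      matched <- nrow(ann) > 0 &&
        any(abs(ann$start - d) <= tolerance & abs(ann$end - a) <= tolerance)
      cand <- list(total = total, d = d, a = a, matched = matched, s = s)
      if (is.null(best) ||
          cand$total < best$total ||
          (cand$total == best$total && cand$matched && !best$matched)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(status = "rejected", reason = "no_spliced_alignment"))
  }
  if (!best$matched) {
    return(list(status = "rejected", reason = "intron_not_annotated",
                intron = c(best$d, best$a), mismatches = best$total))
  }
  if (best$d < up_exon$end) {
    return(list(status = "rejected", reason = "junction_inside_exon"))
  }
  if (best$a > dn_exon$start) {
    return(list(status = "rejected", reason = "junction_inside_exon"))
  }
  list(status = "merged",
       link = tibble(tx_upstream = candidate$tx_upstream,
                     tx_downstream = candidate$tx_downstream,
                     intron_start = best$d, intron_end = best$a,
                     mismatches = best$total,
                     read_id = candidate$read_id))
}

#' Annotate splice junctions with dinucleotides and canonical flag
#'
#' The canonical splice signal is GT at the donor and AG at the acceptor in
#' the transcript's orientation; on the `-` strand the genomic forward
#' sequence therefore reads CT..AC. Strand `.` junctions are canonical if
#' either orientation gives GT-AG.
#'
#' @param junctions Tibble: `chrom`, `donor_end` (0-based exclusive end of
#'   the upstream exon), `acceptor_start` (0-based start of the downstream
#'   exon), `strand`.
#' @param genome Named character vector.
#' @return Input with `dinucleotides` (e.g. `"GT-AG"`, in transcript
#'   orientation) and logical `canonical` columns.
#' @export
annotate_junctions <- function(junctions, genome) {
  n <- nrow(junctions)
  dinuc <- character(n); canon <- logical(n)
  for (i in seq_len(n)) {
    j <- junctions[i, ]
    d2 <- genome_seq(genome, j$chrom, j$donor_end, j$donor_end + 2L)
    a2 <- genome_seq(genome, j$chrom, j$acceptor_start - 2L, j$acceptor_start)
    fwd <- paste0(d2, "-", a2)
    rev <- paste0(revcomp(a2), "-", revcomp(d2))
    if (j$strand == "-") {
      dinuc[i] <- rev
      canon[i] <- rev == "GT-AG"
    } else if (j$strand == "+") {
      dinuc[i] <- fwd
      canon[i] <- fwd == "GT-AG"
    } else {
      canon[i] <- fwd == "GT-AG" || rev == "GT-AG"
      dinuc[i] <- if (rev == "GT-AG" && fwd != "GT-AG") rev else fwd
    }
  }
  junctions$dinucleotides <- dinuc
  junctions$canonical <- canon
  junctions
}

#' Merge transcripts connected by a non-canonical splice junction
#'
#' A non-canonical junction joins transcripts A and B when its donor
#' coincides exactly with the end of A's last exon and its acceptor with
#' the start of B's first exon, on the same chromosome with compatible
#' strands. Junctions matching more than one transcript end on either side
#' are ambiguous and skipped. Canonical (GT-AG) junctions are ignored by
#' this operation.
#'
#' @param tx Transcript tibble.
#' @param junctions Junction tibble with a `canonical` column (see
#'   [annotate_junctions()]).
#' @return List: `links` (tibble `tx_upstream`, `tx_downstream`,
#'   `intron_start`, `intron_end`, `junction`) and `skipped` (tibble with
#'   reasons).
#' @export
merge_by_noncanonical_junction <- function(tx, junctions) {
  spans <- transcript_spans(tx)
  last_ex <- tx |> group_by(.data$transcript_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              last_end = max(.data$end), first_start = min(.data$start),
              .groups = "drop")
  links <- list(); skipped <- list()
  nc <- junctions[!junctions$canonical, , drop = FALSE]
  for (i in seq_len(nrow(nc))) {
    j <- nc[i, ]
    a_hit <- last_ex[last_ex$chrom == j$chrom &
                       last_ex$last_end == j$donor_end, ]
    b_hit <- last_ex[last_ex$chrom == j$chrom &
                       last_ex$first_start == j$acceptor_start, ]
    if (j$strand != ".") {
      a_hit <- a_hit[a_hit$strand %in% c(j$strand, "."), ]
      b_hit <- b_hit[b_hit$strand %in% c(j$strand, "."), ]
    }
    jname <- if ("name" %in% names(j)) j$name else paste0("j", i)
    if (nrow(a_hit) == 0 || nrow(b_hit) == 0) {
      skipped[[length(skipped) + 1L]] <-
        tibble(junction = jname, reason = "no_matching_transcript_end")
      next
    }
    if (nrow(a_hit) > 1 || nrow(b_hit) > 1) {
      skipped[[length(skipped) + 1L]] <-
        tibble(junction = jname, reason = "ambiguous_attachment")
      next
    }
    if (a_hit$transcript_id == b_hit$transcript_id) {
      skipped[[length(skipped) + 1L]] <-
        tibble(junction = jname, reason = "self_link")
      next
    }
    strands_ok <- a_hit$strand == b_hit$strand || a_hit$strand == "." ||
      b_hit$strand == "."
    if (!strands_ok) {
      skipped[[length(skipped) + 1L]] <-
        tibble(junction = jname, reason = "strand_conflict")
      next
    }
    links[[length(links) + 1L]] <- tibble(
      tx_upstream = a_hit$transcript_id,
      tx_downstream = b_hit$transcript_id,
      intron_start = j$donor_end, intron_end = j$acceptor_start,
      junction = jname)
  }
  list(
    links = if (length(links)) bind_rows(links) else
      tibble(tx_upstream = character(), tx_downstream = character(),
             intron_start = integer(), intron_end = integer(),
             junction = character()),
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(junction = character(), reason = character())
  )
}

#' Apply accepted links as connected components
#'
#' Link pairs are closed transitively (A-B and B-C yield one merged model of
#' A, B, C). Each component's exons are unioned (overlaps coalesced) and the
#' merged model replaces its members; exonic bases are never lost.
#'
#' @param tx Transcript tibble.
#' @param links Tibble with `tx_upstream`, `tx_downstream` columns and,
#'   optionally, `intron_start`/`intron_end` of the linking intron; when
#'   present, terminal exons are first extended to the junction (boundary
#'   joins), which can only add exonic bases.
#' @return List: `transcripts` (updated tibble), `provenance` (tibble:
#'   `merged_id`, `member_ids` comma-separated, `n_members`).
#' @export
merge_transcript_set <- function(tx, links) {
  if (nrow(links) > 0 && all(c("intron_start", "intron_end") %in% names(links))) {
    for (i in seq_len(nrow(links))) {
      if (is.na(links$intron_start[i])) next
      iu <- which(tx$transcript_id == links$tx_upstream[i])
      iu <- iu[which.max(tx$start[iu])]
      if (length(iu) && tx$end[iu] < links$intron_start[i]) {
        tx$end[iu] <- links$intron_start[i]
      }
      id_ <- which(tx$transcript_id == links$tx_downstream[i])
      id_ <- id_[which.min(tx$start[id_])]
      if (length(id_) && tx$start[id_] > links$intron_end[i]) {
        tx$start[id_] <- links$intron_end[i]
      }
    }
  }
  if (nrow(links) == 0) {
    return(list(transcripts = tx,
                provenance = tibble(merged_id = character(),
                                    member_ids = character(),
                                    n_members = integer())))
  }
  g <- igraph::graph_from_data_frame(
    links[, c("tx_upstream", "tx_downstream")], directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  merged_rows <- list(); prov <- list()
  drop_ids <- character()
  for (members in membership) {
    members <- sort(members)
    rows <- tx[tx$transcript_id %in% members, ]
    strands <- setdiff(unique(rows$strand), ".")
    if (length(strands) > 1) {
      abort(paste0("cannot merge transcripts on conflicting strands: ",
                   paste(members, collapse = ", ")))
    }
    strand <- if (length(strands)) strands else "."
    ir <- IRanges::reduce(IRanges::IRanges(rows$start + 1L, rows$end))
    new_id <- paste(members, collapse = "+")
    merged_rows[[length(merged_rows) + 1L]] <- tibble(
      transcript_id = new_id,
      gene_id = first(rows$gene_id[!is.na(rows$gene_id)], default = NA_character_),
      chrom = rows$chrom[1],
      start = BiocGenerics::start(ir) - 1L,
      end = BiocGenerics::end(ir),
      strand = strand)
    prov[[length(prov) + 1L]] <- tibble(
      merged_id = new_id, member_ids = paste(members, collapse = ","),
      n_members = length(members))
    drop_ids <- c(drop_ids, members)
  }
  out <- bind_rows(tx[!tx$transcript_id %in% drop_ids, ],
                   bind_rows(merged_rows))
  list(transcripts = validate_transcripts(out), provenance = bind_rows(prov))
}

#' Merge fragmented transcripts using linking long reads and junctions
#'
#' End-to-end fragment merging: long reads are converted to 2x25bp segment
#' pairs, aligned to the transcript sequences, link candidates are refined
#' by split alignment against the annotation, non-canonical junctions
#' contribute additional links, and all accepted links are applied as
#' connected components. A review report lists every link with its
#' supporting evidence (the programmatic stand-in for manual evaluation of
#' the connections).
#'
#' @param tx Transcript tibble (the fragmented assembly).
#' @param genome Named character vector.
#' @param long_reads Read tibble.
#' @param annotation_introns Pooled annotation introns.
#' @param junctions Optional junction tibble (see [annotate_junctions()]).
#' @param max_gap,tolerance,max_hits,max_mismatches_segment,max_mismatches_split
#'   Stage parameters (defaults 200000, 10, 3, 1, 2).
#' @param min_length,min_quality Segment-pair preparation parameters
#'   (defaults 50, 28).
#' @return List: `transcripts` (merged set), `links` (accepted link table),
#'   `rejections` (tibble of rejected candidates with reasons),
#'   `provenance` (merged components).
#' @export
merge_fragmented_transcripts <- function(tx, genome, long_reads,
                                         annotation_introns,
                                         junctions = NULL,
                                         max_gap = 200000L, tolerance = 10L,
                                         max_hits = 3L,
                                         max_mismatches_segment = 1L,
                                         max_mismatches_split = 2L,
                                         min_length = 50L, min_quality = 28) {
  tx <- validate_transcripts(tx)
  seqs <- transcript_sequence_set(tx, genome)
  prep <- prepare_segment_pairs(long_reads, min_length = min_length,
                                min_quality = min_quality)
  hits <- align_segment_pairs(prep$pairs, seqs, max_hits = max_hits,
                              max_mismatches = max_mismatches_segment)
  cands <- find_link_candidates(hits, tx, max_gap = max_gap)
  links <- list(); rejections <- list()
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    read_seq <- long_reads$sequence[match(cand$read_id, long_reads$read_id)]
    res <- refine_link(read_seq, genome, cand, tx, annotation_introns,
                       tolerance = tolerance,
                       max_mismatches = max_mismatches_split)
    if (res$status == "merged") {
      links[[length(links) + 1L]] <- res$link
    } else {
      rejections[[length(rejections) + 1L]] <- tibble(
        read_id = cand$read_id, tx_upstream = cand$tx_upstream,
        tx_downstream = cand$tx_downstream, reason = res$reason)
    }
  }
  link_tbl <- if (length(links)) {
    distinct(bind_rows(links), .data$tx_upstream, .data$tx_downstream,
             .data$intron_start, .data$intron_end, .keep_all = TRUE)
  } else {
    tibble(tx_upstream = character(), tx_downstream = character(),
           intron_start = integer(), intron_end = integer(),
           mismatches = integer(), read_id = character())
  }
  if (!is.null(junctions) && nrow(junctions) > 0) {
    jm <- merge_by_noncanonical_junction(tx, junctions)
    if (nrow(jm$links)) {
      link_tbl <- bind_rows(link_tbl,
                            mutate(jm$links, mismatches = NA_integer_,
                                   read_id = paste0("junction:", .data$junction)) |>
                              select(-"junction"))
    }
  }
  merged <- merge_transcript_set(tx, link_tbl)
  list(transcripts = merged$transcripts,
       links = link_tbl,
       rejections = if (length(rejections)) bind_rows(rejections) else
         tibble(read_id = character(), tx_upstream = character(),
                tx_downstream = character(), reason = character()),
       provenance = merged$provenance)
}
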