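# Scoring assembled transcripts against annotation sources: gene-locus
# clustering by exonic overlap, span overlap with annotated gene loci
# (strand-agnostic), exact intron concordance (strand-aware), and the Venn /
# loci / alternative-splicing summaries.

venn_letter <- function(source) {
  map <- c(Ensembl = "E", RefSeq = "R", OtherRefSeq = "O")
  ifelse(source %in% names(map), map[source], substr(source, 1, 1))
}

venn_region <- function(sources_list, all_sources) {
  letters_ordered <- venn_letter(all_sources)
  vapply(sources_list, function(s) {
    if (length(s) == 0) return("none")
    paste(letters_ordered[all_sources %in% s], collapse = "")
  }, character(1))
}

#' Cluster transcripts into gene loci
#'
#' Default mode groups transcripts by single-linkage connected components
#' under the relation "share at least 1bp of exonic overlap on the same
#' chromosome and strand" (strand `.` overlaps both). Mode `"gene_id"`
#' instead groups by pre-assigned gene identifiers. Locus ids are
#' deterministic, numbered by (chrom, span start).
#'
#' @param tx Transcript tibble.
#' @param mode `"overlap"` (default) or `"gene_id"`.
#' @return Tibble: `locus_id`, `chrom`, `strand`, `start`, `end`,
#'   `transcript_id` (one row per member transcript).
#' @export
cluster_loci <- function(tx, mode = c("overlap", "gene_id")) {
  mode <- match.arg(mode)
  tx <- validate_transcripts(tx)
  spans <- transcript_spans(tx)
  if (nrow(spans) == 0) {
    return(tibble(locus_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  transcript_id = character()))
  }
  if (mode == "gene_id") {
    grp <- ifelse(is.na(spans$gene_id), spans$transcript_id, spans$gene_id)
    membership <- split(spans$transcript_id, grp)
  } else {
    ids <- spans$transcript_id
    edges <- list()
    for (ch in unique(tx$chrom)) {
      ex <- tx[tx$chrom == ch, ]
      ir <- IRanges::IRanges(ex$start + 1L, ex$end)
      ov <- IRanges::findOverlaps(ir, ir)
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      keep <- qi < si
      qi <- qi[keep]; si <- si[keep]
      if (length(qi) == 0) next
      sa <- ex$strand[qi]; sb <- ex$strand[si]
      compat <- sa == sb | sa == "." | sb == "."
      diff_tx <- ex$transcript_id[qi] != ex$transcript_id[si]
      keep2 <- compat & diff_tx
      if (any(keep2)) {
        edges[[length(edges) + 1L]] <- tibble(
          a = ex$transcript_id[qi[keep2]], b = ex$transcript_id[si[keep2]])
      }
    }
    g <- igraph::graph_from_data_frame(
      if (length(edges)) distinct(bind_rows(edges)) else
        tibble(a = character(), b = character()),
      directed = FALSE, vertices = ids)
    comp <- igraph::components(g)
    membership <- split(names(comp$membership), comp$membership)
  }
  loci <- purrr::map_dfr(membership, function(members) {
    s <- spans[spans$transcript_id %in% members, ]
    strands <- setdiff(unique(s$strand), ".")
    tibble(chrom = s$chrom[1],
           strand = if (length(strands) == 1) strands else ".",
           start = min(s$start), end = max(s$end),
           transcript_id = list(members))
  })
  loci <- arrange(loci, .data$chrom, .data$start)
  loci$locus_id <- sprintf("locus_%04d", seq_len(nrow(loci)))
  tidyr::unnest(loci, "transcript_id") |>
    select("locus_id", "chrom", "strand", "start", "end", "transcript_id")
}

#' Overlap transcripts with annotated gene loci
#'
#' Per transcript, the set of annotation sources whose gene spans share at
#' least 1bp with the transcript span on the same chromosome. Strand is
#' ignored: the comparison is purely chr:start-stop.
#'
#' @param tx Transcript tibble.
#' @param annotations Pooled annotation from [bind_annotations()].
#' @return Tibble: `transcript_id`, `sources` (list column of source
#'   labels), `region` (Venn region label, `"none"` when empty).
#' @export
overlap_gene_annotations <- function(tx, annotations) {
  spans <- transcript_spans(tx)
  gs <- annotations$gene_spans
  sources <- annotations$sources
  hit_sources <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) hit_sources[[i]] <- character()
  for (ch in unique(spans$chrom)) {
    qi_all <- which(spans$chrom == ch)
    gsub_ <- gs[gs$chrom == ch, ]
    if (nrow(gsub_) == 0) next
    q <- IRanges::IRanges(spans$start[qi_all] + 1L, spans$end[qi_all])
    s <- IRanges::IRanges(gsub_$start + 1L, gsub_$end)
    ov <- IRanges::findOverlaps(q, s)
    for (k in seq_along(ov)) {
      qi <- qi_all[S4Vectors::queryHits(ov)[k]]
      src <- gsub_$source[S4Vectors::subjectHits(ov)[k]]
      hit_sources[[qi]] <- union(hit_sources[[qi]], src)
    }
  }
  hit_sources <- lapply(hit_sources, function(s) sources[sources %in% s])
  regions <- venn_region(hit_sources, sources)
  tibble(transcript_id = spans$transcript_id,
         sources = hit_sources,
         region = regions)
}

#' Exact intron concordance against annotation sources
#'
#' Per intron, the set of sources containing an intron with identical
#' chromosome, start, end and strand. Strand `.` introns match an annotated
#' intron on either strand; annotated `.` introns match either strand too.
#'
#' @param tx_introns Intron tibble from [introns_of()].
#' @param annotations Pooled annotation from [bind_annotations()].
#' @return `tx_introns` with `sources` (list column) and `region` columns.
#' @export
intron_concordance <- function(tx_introns, annotations) {
  ann <- annotations$introns
  sources <- annotations$sources
  key <- function(chrom, start, end) paste(chrom, start, end, sep = ":")
  out_sources <- vector("list", nrow(tx_introns))
  for (i in seq_len(nrow(tx_introns))) out_sources[[i]] <- character()
  for (src in sources) {
    a <- ann[ann$source == src, ]
    if (nrow(a) == 0) next
    akey <- key(a$chrom, a$start, a$end)
    qkey <- key(tx_introns$chrom, tx_introns$start, tx_introns$end)
    m <- match(qkey, akey)
    hit <- !is.na(m)
    if (!any(hit)) next
    strand_ok <- tx_introns$strand[hit] == a$strand[m[hit]] |
      tx_introns$strand[hit] == "." | a$strand[m[hit]] == "."
    # multiple annotated introns can share coordinates on opposite strands
    if (any(!strand_ok)) {
      for (idx in which(hit)[!strand_ok]) {
        ok <- any(akey == qkey[idx] &
                    (a$strand == tx_introns$strand[idx] |
                       a$strand == "." | tx_introns$strand[idx] == "."))
        if (ok) out_sources[[idx]] <- union(out_sources[[idx]], src)
      }
    }
    for (idx in which(hit)[strand_ok]) {
      out_sources[[idx]] <- union(out_sources[[idx]], src)
    }
  }
  out_sources <- lapply(out_sources, function(s) sources[sources %in% s])
  tx_introns$sources <- out_sources
  tx_introns$region <- venn_region(out_sources, sources)
  tx_introns
}

#' Summarize annotation concordance
#'
#' Venn-region tallies for transcripts and introns, gene-locus counts at
#' the 2-or-more and 3-or-more exon levels, a transcripts-per-locus
#' histogram, and the breakdown of unannotated transcripts (unplaced
#' chromosomes, single-exon).
#'
#' @param tx Transcript tibble.
#' @param loci Output of [cluster_loci()].
#' @param categories Output of [overlap_gene_annotations()].
#' @param intron_sets Output of [intron_concordance()].
#' @param unplaced_pattern Regex identifying unplaced chromosome names
#'   (default `"Un"`).
#' @return List with class `concordance_summary`: `transcript_venn`,
#'   `intron_venn` (region, n), `loci_counts` (min_exons, n_loci),
#'   `tx_per_locus` (min_exons, n_transcripts, n_loci), `unannotated`
#'   (one-row tibble), `totals`.
#' @export
summarize_annotation <- function(tx, loci, categories, intron_sets,
                                 unplaced_pattern = "Un") {
  spans <- transcript_spans(tx)
  tv <- count(categories, .data$region, name = "n")
  iv <- count(as_tibble(intron_sets[, "region", drop = FALSE]),
              .data$region, name = "n")
  loci_ex <- loci |>
    left_join(select(spans, "transcript_id", "n_exons"), by = "transcript_id")
  loci_counts <- tibble(
    min_exons = c(2L, 3L),
    n_loci = c(
      dplyr::n_distinct(loci_ex$locus_id[loci_ex$n_exons >= 2L]),
      dplyr::n_distinct(loci_ex$locus_id[loci_ex$n_exons >= 3L])))
  tx_per_locus <- bind_rows(lapply(c(2L, 3L), function(k) {
    sub <- loci_ex[loci_ex$n_exons >= k, ]
    if (nrow(sub) == 0) {
      return(tibble(min_exons = k, n_transcripts = integer(),
                    n_loci = integer()))
    }
    sub |> count(.data$locus_id, name = "n_transcripts") |>
      count(.data$n_transcripts, name = "n_loci") |>
      mutate(min_exons = k) |>
      select("min_exons", "n_transcripts", "n_loci")
  }))
  none_ids <- categories$transcript_id[categories$region == "none"]
  none_spans <- spans[spans$transcript_id %in% none_ids, ]
  unpl <- grepl(unplaced_pattern, none_spans$chrom)
  single <- none_spans$n_exons == 1L
  unannotated <- tibble(
    n_none = nrow(none_spans),
    n_none_unplaced = sum(unpl),
    n_none_single_exon = sum(single),
    n_none_unplaced_single_exon = sum(unpl & single))
  structure(list(
    transcript_venn = tv,
    intron_venn = iv,
    loci_counts = loci_counts,
    tx_per_locus = tx_per_locus,
    unannotated = unannotated,
    totals = tibble(n_transcripts = nrow(spans),
                    n_introns = nrow(intron_sets),
                    n_loci = dplyr::n_distinct(loci$locus_id))
  ), class = "concordance_summary")
}
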