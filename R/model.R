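# Shared genomic data model: transcripts and introns are plain tibbles with a
# fixed column contract, genomes are named uppercase character vectors.
# Internal coordinates are 0-based half-open everywhere; GTF is converted at
# the boundary (1-based inclusive) and VCF POS stays 1-based.

#' Build a transcript exon table
#'
#' Transcript models are tibbles with one row per exon and columns
#' `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`. Coordinates
#' are 0-based half-open. This constructor sorts exons and validates the
#' model invariants: exons of one transcript share a chromosome and strand
#' (`+`, `-` or `.`), do not overlap, and are separated by introns of at
#' least 1 bp.
#'
#' @param transcript_id Character vector, one value per exon row.
#' @param chrom,start,end Exon coordinates (0-based half-open).
#' @param strand `"+"`, `"-"` or `"."` (unstranded libraries).
#' @param gene_id Optional gene identifiers (`NA` allowed).
#' @return A validated transcript tibble.
#' @export
#' @examples
#' transcript_tbl("t1", "chr1", c(99, 300), c(200, 400), "+")
transcript_tbl <- function(transcript_id, chrom, start, end, strand = ".",
                           gene_id = NA_character_) {
  tx <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand)
  )
  validate_transcripts(tx)
}

#' Validate a transcript exon table
#'
#' @param tx A transcript tibble (see [transcript_tbl()]).
#' @param genome Optional genome (named character vector); when supplied,
#'   exon ends are checked against chromosome lengths.
#' @return `tx`, with exons sorted by (chrom, start, transcript_id), invisibly
#'   validated.
#' @export
validate_transcripts <- function(tx, genome = NULL) {
  req <- c("transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(req, names(tx))
  if (length(missing_cols) > 0) {
    abort(paste0("transcript table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"gene_id" %in% names(tx)) tx$gene_id <- NA_character_
  tx <- as_tibble(tx)
  tx$start <- as.integer(tx$start)
  tx$end <- as.integer(tx$end)
  if (nrow(tx) == 0) return(tx)
  if (any(!tx$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  bad <- tx$start < 0L | tx$start >= tx$end
  if (any(bad)) {
    abort(paste0("invalid exon interval in transcript(s): ",
                 paste(unique(tx$transcript_id[bad]), collapse = ", ")))
  }
  if (!is.null(genome)) {
    len <- nchar(genome)[tx$chrom]
    if (any(is.na(len))) {
      abort("transcript chromosome absent from genome")
    }
    if (any(tx$end > len)) {
      abort(paste0("exon beyond chromosome end in transcript(s): ",
                   paste(unique(tx$transcript_id[tx$end > len]),
                         collapse = ", ")))
    }
  }
  tx <- arrange(tx, .data$chrom, .data$transcript_id, .data$start)
  per <- split(seq_len(nrow(tx)), tx$transcript_id)
  for (id in names(per)) {
    i <- per[[id]]
    if (length(unique(tx$chrom[i])) != 1L || length(unique(tx$strand[i])) != 1L) {
      abort(paste0("transcript '", id, "' mixes chromosomes or strands"))
    }
    if (length(i) > 1L) {
      s <- tx$start[i]; e <- tx$end[i]
      # introns must be >= 1 bp: each start must exceed the previous end
      if (any(s[-1] <= e[-length(e)])) {
        abort(paste0("transcript '", id,
                     "' has overlapping or abutting exons (intron length < 1)"))
      }
    }
  }
  arrange(tx, .data$chrom, .data$start, .data$transcript_id)
}

#' Introns of a transcript table
#'
#' One row per gap between consecutive exons of a transcript, carrying the
#' transcript strand. An intron's identity — (chrom, start, end, strand) —
#' is the unit used for exact concordance against annotation sources.
#'
#' @param tx Transcript tibble.
#' @return Tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open; `start` is the first intronic base).
#' @export
introns_of <- function(tx) {
  tx <- validate_transcripts(tx)
  tx |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      donor = list(head(.data$end, -1L)),
      acceptor = list(tail(.data$start, -1L)),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("donor", "acceptor")) |>
    mutate(start = .data$donor, end = .data$acceptor) |>
    select("transcript_id", "chrom", "start", "end", "strand")
}

#' Per-transcript span table
#'
#' @param tx Transcript tibble.
#' @return One row per transcript: `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `n_exons`.
#' @export
transcript_spans <- function(tx) {
  tx |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      strand = first(.data$strand),
      n_exons = n(),
      .groups = "drop"
    )
}

# 0-based half-open substring of a genome chromosome
genome_seq <- function(genome, chrom, start, end) {
  s <- genome[[chrom]]
  if (is.null(s)) abort(paste0("chromosome '", chrom, "' not in genome"))
  if (start < 0 || end > nchar(s)) abort("genome slice out of bounds")
  substr(s, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
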