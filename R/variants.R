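# Variant hard filtering, genotype-category classification, indel
# normalization (left alignment), known-variant comparison and
# cross-dataset support tabulation.

#' Hard-filter thresholds
#'
#' The rule set applied to variant calls: SNPs fail on QD < 2.0,
#' MQ < 40.0, FS > 60.0, HaplotypeScore > 13.0 (genomic data only),
#' MQRankSum < -12.5, or ReadPosRankSum < -8.0; indels fail on QD < 2.0,
#' ReadPosRankSum < -20.0, or FS > 200.0. All inequalities are strict: a
#' metric exactly at its threshold passes.
#'
#' @param snp,indel Named lists overriding individual thresholds.
#' @return List with class `hard_filter_thresholds`.
#' @export
hard_filter_thresholds <- function(snp = list(), indel = list()) {
  s <- utils::modifyList(
    list(qd_min = 2.0, mq_min = 40.0, fs_max = 60.0,
         haplotype_score_max = 13.0, mq_rank_sum_min = -12.5,
         read_pos_rank_sum_min = -8.0), snp)
  i <- utils::modifyList(
    list(qd_min = 2.0, read_pos_rank_sum_min = -20.0, fs_max = 200.0), indel)
  structure(list(snp = s, indel = i), class = "hard_filter_thresholds")
}

#' Apply hard filters to variant records
#'
#' A record fails if any applicable rule triggers. A missing metric skips
#' its rule rather than failing the record (callers omit rank-sum metrics
#' at homozygous sites, and those are exactly the candidate reference
#' errors of interest). The HaplotypeScore rule is applied only in genomic
#' mode (`use_haplotype_score = TRUE`). Records with class `insertion`,
#' `deletion` or `mixed` are filtered under the indel rules.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param thresholds A [hard_filter_thresholds()].
#' @param use_haplotype_score Apply the HaplotypeScore rule (default FALSE).
#' @return List: `passing`, `failing` (with a `filter_reasons` column
#'   naming every triggered rule).
#' @export
apply_hard_filters <- function(variants,
                               thresholds = hard_filter_thresholds(),
                               use_haplotype_score = FALSE) {
  v <- as_tibble(variants)
  known_classes <- c("snp", "insertion", "deletion", "mixed")
  if (any(!v$variant_class %in% known_classes)) {
    abort(paste0("unknown variant class: ",
                 paste(setdiff(v$variant_class, known_classes), collapse = ", ")))
  }
  is_snp <- v$variant_class == "snp"
  reasons <- vector("list", nrow(v))
  add <- function(reasons, idx, tag) {
    for (i in which(idx)) reasons[[i]] <- c(reasons[[i]], tag)
    reasons
  }
  s <- thresholds$snp; ind <- thresholds$indel
  reasons <- add(reasons, is_snp & !is.na(v$qd) & v$qd < s$qd_min, "QD")
  reasons <- add(reasons, is_snp & !is.na(v$mq) & v$mq < s$mq_min, "MQ")
  reasons <- add(reasons, is_snp & !is.na(v$fs) & v$fs > s$fs_max, "FS")
  if (use_haplotype_score) {
    reasons <- add(reasons, is_snp & !is.na(v$haplotype_score) &
                     v$haplotype_score > s$haplotype_score_max,
                   "HaplotypeScore")
  }
  reasons <- add(reasons, is_snp & !is.na(v$mq_rank_sum) &
                   v$mq_rank_sum < s$mq_rank_sum_min, "MQRankSum")
  reasons <- add(reasons, is_snp & !is.na(v$read_pos_rank_sum) &
                   v$read_pos_rank_sum < s$read_pos_rank_sum_min,
                 "ReadPosRankSum")
  reasons <- add(reasons, !is_snp & !is.na(v$qd) & v$qd < ind$qd_min, "QD")
  reasons <- add(reasons, !is_snp & !is.na(v$read_pos_rank_sum) &
                   v$read_pos_rank_sum < ind$read_pos_rank_sum_min,
                 "ReadPosRankSum")
  reasons <- add(reasons, !is_snp & !is.na(v$fs) & v$fs > ind$fs_max, "FS")
  fail <- lengths(reasons) > 0
  failing <- v[fail, ]
  failing$filter_reasons <- vapply(reasons[fail], paste, character(1),
                                   collapse = ",")
  list(passing = v[!fail, ], failing = failing)
}

#' Classify the genotype category of each variant position
#'
#' Identical non-reference alleles (e.g. `1/1`) are `homozygous_alt`; one
#' reference plus one alternate allele (`0/1`) is `mixed_allele`; two
#' different non-reference alleles (`1/2`) are `other`; absent or
#' uncalled genotypes are `missing`. Homozygous-reference calls fall in
#' `other` (they assert no variant).
#'
#' @param variants Variant tibble.
#' @return Input with a `genotype_category` column.
#' @export
classify_genotype_position <- function(variants) {
  cat1 <- function(gt) {
    if (is.na(gt)) return("missing")
    al <- strsplit(gt, "[/|]")[[1]]
    if (any(al == ".") || length(al) != 2) return("missing")
    a <- suppressWarnings(as.integer(al))
    if (any(is.na(a))) return("missing")
    if (a[1] == a[2] && a[1] > 0) return("homozygous_alt")
    if (xor(a[1] == 0, a[2] == 0)) return("mixed_allele")
    "other"
  }
  variants$genotype_category <- vapply(variants$genotype, cat1, character(1),
                                       USE.NAMES = FALSE)
  variants
}

#' Expand variant records to one row per alternate allele
#'
#' Multi-allelic sites are stored as one record ("variant position");
#' per-allele analyses iterate the alternate alleles. Adds `allele_index`
#' (1-based index into ALT) and `allele_class`.
#'
#' @param variants Variant tibble.
#' @return Per-allele tibble (original columns preserved; `alt` holds a
#'   single allele per row).
#' @export
expand_alleles <- function(variants) {
  v <- as_tibble(variants)
  v$.record <- seq_len(nrow(v))
  out <- tidyr::separate_rows(v, "alt", sep = ",")
  out <- out |> group_by(.data$.record) |>
    mutate(allele_index = row_number()) |> ungroup()
  out$allele_class <- variant_class(out$ref, out$alt)
  select(out, -".record")
}

# canonical left-aligned minimal form of one (chrom, pos, ref, alt) allele
normalize_allele_one <- function(chrom, pos, ref, alt, genome) {
  chromseq <- genome[[chrom]]
  if (is.null(chromseq)) abort(paste0("chromosome '", chrom, "' not in genome"))
  obs <- substr(chromseq, pos, pos + nchar(ref) - 1L)
  if (obs != ref) {
    abort(paste0("reference mismatch at ", chrom, ":", pos,
                 " (VCF ref '", ref, "', genome '", obs, "')"))
  }
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 && !(lr == 1 && la == 1) &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) {
        if (pos == 1L) abort("cannot left-align past chromosome start")
        b <- substr(chromseq, pos - 1L, pos - 1L)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  while (nchar(ref) >= 2 && nchar(alt) >= 2 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant alleles to canonical left-aligned form
#'
#' Shared suffix then shared prefix bases are trimmed (retaining one anchor
#' base for indels) and indels are shifted left through homopolymer runs to
#' the unique canonical representation, so that the same event reported at
#' different offsets within a run compares equal. Operates on per-allele
#' rows (see [expand_alleles()]); the operation is idempotent.
#'
#' @param alleles Per-allele tibble (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param genome Named character vector.
#' @return Input with `pos`, `ref`, `alt` canonicalized and `allele_class`
#'   recomputed.
#' @export
normalize_alleles <- function(alleles, genome) {
  n <- nrow(alleles)
  if (n == 0) return(alleles)
  for (i in seq_len(n)) {
    r <- normalize_allele_one(alleles$chrom[i], alleles$pos[i],
                              alleles$ref[i], alleles$alt[i], genome)
    alleles$pos[i] <- r$pos
    alleles$ref[i] <- r$ref
    alleles$alt[i] <- r$alt
  }
  alleles$allele_class <- variant_class(alleles$ref, alleles$alt)
  alleles
}

#' Normalize single-alt variant records
#'
#' Record-level wrapper over [normalize_alleles()]; multi-allelic records
#' are expanded, normalized per allele, and must share a canonical position
#' to be recombined (otherwise they are left expanded with a warning).
#'
#' @param variants Variant tibble.
#' @param genome Named character vector.
#' @return Variant tibble with canonical `pos`/`ref`/`alt`.
#' @export
normalize_variant <- function(variants, genome) {
  multi <- grepl(",", variants$alt)
  if (!any(multi)) {
    out <- normalize_alleles(variants, genome)
    out$variant_class <- variant_class(out$ref, out$alt)
    return(out)
  }
  ex <- expand_alleles(variants)
  ex <- normalize_alleles(ex, genome)
  warn("multi-allelic records normalized per allele and left expanded")
  ex$variant_class <- ex$allele_class
  ex
}

allele_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

#' Match variants against a known-variant set
#'
#' Both sides are expanded per allele and normalized; a match requires
#' equal (chrom, canonical pos, ref, alt), or equal (chrom, canonical pos)
#' in position-only mode.
#'
#' @param variants Variant tibble.
#' @param known Known-variant tibble.
#' @param genome Named character vector.
#' @param position_only Match by position alone (default FALSE).
#' @return List: `alleles` (per-allele tibble with logical `known`),
#'   `fraction` (matched alleles / total alleles).
#' @export
match_known_variants <- function(variants, known, genome,
                                 position_only = FALSE) {
  q <- normalize_alleles(expand_alleles(variants), genome)
  k <- normalize_alleles(expand_alleles(known), genome)
  if (position_only) {
    q$known <- paste(q$chrom, q$pos) %in% paste(k$chrom, k$pos)
  } else {
    q$known <- allele_key(q) %in% allele_key(k)
  }
  list(alleles = q,
       fraction = if (nrow(q)) mean(q$known) else 0)
}

#' Tabulate cross-dataset support
#'
#' For each variant allele, counts the number `k` of comparison datasets
#' containing it (after normalization on both sides) and bins per variant
#' class by `k`; `k = 0` is the "not validated" bin. Per class, the bins
#' sum to the class total, and the table is invariant to comparison-set
#' order.
#'
#' @param variants Variant tibble.
#' @param comparison_sets Named list of variant tibbles.
#' @param genome Named character vector.
#' @return List: `table` (tibble `variant_class`, `support` 0..N, `n`),
#'   `alleles` (per-allele tibble with a `support` column).
#' @export
tabulate_dataset_support <- function(variants, comparison_sets, genome) {
  q <- normalize_alleles(expand_alleles(variants), genome)
  qk <- allele_key(q)
  support <- rep(0L, nrow(q))
  for (cs in comparison_sets) {
    ck <- allele_key(normalize_alleles(expand_alleles(cs), genome))
    support <- support + as.integer(qk %in% ck)
  }
  q$support <- support
  grid <- tidyr::expand_grid(
    variant_class = union(c("snp", "insertion", "deletion"),
                          unique(q$allele_class)),
    support = 0:length(comparison_sets))
  tab <- q |>
    mutate(variant_class = .data$allele_class) |>
    count(.data$variant_class, .data$support, name = "n") |>
    dplyr::right_join(grid, by = c("variant_class", "support")) |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
    arrange(.data$variant_class, .data$support)
  list(table = tab, alleles = q)
}
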