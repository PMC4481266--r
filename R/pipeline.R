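# End-to-end orchestration: read evidence -> fragment merging -> evidence
# filter -> annotation comparison -> variant filtering/classification ->
# ORF consequence -> candidate reference-error calls, with a structured
# report of every stage.

#' Pipeline parameters
#'
#' All stage parameters in one place, at the documented defaults: link
#' window 200,000 bp, intron tolerance 10 bp, bit-score cutoff 400, hard
#' filters per [hard_filter_thresholds()], segment preparation at 50 nt /
#' 25 bp / mean quality 28, at most 3 segment placements with at most 1
#' mismatch.
#'
#' @param ... Overrides for any parameter.
#' @return List of parameters.
#' @export
pipeline_params <- function(...) {
  p <- list(
    max_gap = 200000L, tolerance = 10L,
    max_hits = 3L, max_mismatches_segment = 1L, max_mismatches_split = 2L,
    min_length = 50L, min_quality = 28,
    scheme = scoring_scheme(), threshold_bits = 400,
    max_exons_filtered = 2L,
    thresholds = hard_filter_thresholds(),
    scan_both_strands = TRUE,
    unplaced_pattern = "Un",
    locus_mode = "overlap")
  utils::modifyList(p, list(...))
}

#' Run the full refinement pipeline
#'
#' Stages, in order: fragment merging from linking long reads and
#' non-canonical junctions; evidence filtering of 1-2-exon transcripts;
#' annotation comparison (loci, span overlap, intron concordance); variant
#' hard filtering and genotype classification (RNA and genomic sets);
#' cross-dataset support; ORF-consequence analysis and candidate
#' reference-error calls. Stages lacking their inputs are skipped. The
#' pipeline is a pure function of its inputs: identical inputs give an
#' identical report.
#'
#' @param genome Named character vector.
#' @param transcripts Assembled transcript tibble.
#' @param annotations Pooled annotation from [bind_annotations()].
#' @param long_reads Optional read tibble (fragment linking).
#' @param junctions Optional junction tibble (junction merging).
#' @param evidence Optional named character vector (evidence filter).
#' @param rna_variants,genomic_variants Optional variant tibbles.
#' @param comparison_sets Named list of variant tibbles (dataset support).
#' @param params A [pipeline_params()].
#' @param stages Character vector of stages to run (default all):
#'   `"link_merge"`, `"evidence_filter"`, `"annotation"`, `"variants"`,
#'   `"orf"`.
#' @return List with class `refine_report`.
#' @export
run_pipeline <- function(genome, transcripts, annotations,
                         long_reads = NULL, junctions = NULL,
                         evidence = NULL,
                         rna_variants = NULL, genomic_variants = NULL,
                         comparison_sets = list(),
                         params = pipeline_params(),
                         stages = c("link_merge", "evidence_filter",
                                    "annotation", "variants", "orf")) {
  tx <- validate_transcripts(transcripts)
  counts <- list(transcripts_in = dplyr::n_distinct(tx$transcript_id))
  links <- NULL; rejections <- NULL

  if ("link_merge" %in% stages && !is.null(long_reads)) {
    lm <- merge_fragmented_transcripts(
      tx, genome, long_reads, annotations$introns, junctions,
      max_gap = params$max_gap, tolerance = params$tolerance,
      max_hits = params$max_hits,
      max_mismatches_segment = params$max_mismatches_segment,
      max_mismatches_split = params$max_mismatches_split,
      min_length = params$min_length, min_quality = params$min_quality)
    tx <- lm$transcripts
    links <- lm$links
    rejections <- lm$rejections
    counts$links_accepted <- nrow(lm$links)
    counts$links_rejected <- nrow(lm$rejections)
    counts$transcripts_after_merge <- dplyr::n_distinct(tx$transcript_id)
  }

  evidence_hits <- NULL
  if ("evidence_filter" %in% stages && !is.null(evidence)) {
    fl <- filter_low_evidence(tx, genome, evidence,
                              scheme = params$scheme,
                              threshold_bits = params$threshold_bits,
                              max_exons_filtered = params$max_exons_filtered)
    counts$transcripts_kept <- dplyr::n_distinct(fl$kept$transcript_id)
    counts$transcripts_excluded <-
      dplyr::n_distinct(fl$excluded$transcript_id)
    tx <- fl$kept
    evidence_hits <- fl$hits
  }

  concordance <- NULL; loci <- NULL
  if ("annotation" %in% stages) {
    loci <- cluster_loci(tx, mode = params$locus_mode)
    categories <- overlap_gene_annotations(tx, annotations)
    isets <- intron_concordance(introns_of(tx), annotations)
    concordance <- summarize_annotation(tx, loci, categories, isets,
                                        unplaced_pattern = params$unplaced_pattern)
    counts$loci <- dplyr::n_distinct(loci$locus_id)
  }

  rna_pass <- NULL; rna_fail <- NULL
  genomic_pass <- NULL; genomic_fail <- NULL
  genotype_counts <- NULL; support <- NULL
  if ("variants" %in% stages && !is.null(rna_variants)) {
    hf <- apply_hard_filters(rna_variants, params$thresholds,
                             use_haplotype_score = FALSE)
    rna_pass <- classify_genotype_position(hf$passing)
    rna_fail <- hf$failing
    counts$rna_variants_in <- nrow(rna_variants)
    counts$rna_variants_pass <- nrow(rna_pass)
    counts$rna_variants_fail <- nrow(rna_fail)
    genotype_counts <- count(rna_pass, .data$genotype_category, name = "n")
    if (!is.null(genomic_variants)) {
      gf <- apply_hard_filters(genomic_variants, params$thresholds,
                               use_haplotype_score = TRUE)
      genomic_pass <- classify_genotype_position(gf$passing)
      genomic_fail <- gf$failing
      counts$genomic_variants_in <- nrow(genomic_variants)
      counts$genomic_variants_pass <- nrow(genomic_pass)
    }
    if (length(comparison_sets) > 0) {
      support <- tabulate_dataset_support(rna_pass, comparison_sets, genome)
    }
  }

  effects <- NULL; error_calls <- NULL; table2 <- NULL; mechanisms <- NULL
  if ("orf" %in% stages && !is.null(rna_pass)) {
    alleles <- normalize_alleles(expand_alleles(rna_pass), genome)
    effects <- classify_orf_effect(tx, genome, alleles,
                                   scan_both_strands = params$scan_both_strands)
    error_calls <- call_reference_errors(
      effects, if (is.null(genomic_pass)) empty_variants() else genomic_pass,
      genome, annotations$introns, tolerance = params$tolerance)
    counts$effects_evaluated <- nrow(effects)
    counts$extending <- sum(effects$effect == "extending", na.rm = TRUE)
    counts$candidate_reference_errors <-
      sum(error_calls$candidate_reference_error)
    grid <- tidyr::expand_grid(
      support_class = c("homozygous", "heterozygous", "unsupported"),
      allele_class = c("snp", "insertion", "deletion"))
    table2 <- error_calls |>
      count(.data$support_class, .data$allele_class, name = "n") |>
      dplyr::right_join(grid, by = c("support_class", "allele_class")) |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
      arrange(match(.data$support_class,
                    c("homozygous", "heterozygous", "unsupported")),
              match(.data$allele_class, c("snp", "insertion", "deletion")))
    mechanisms <- tibble(
      n_homopolymer_slip = sum(error_calls$homopolymer_slip),
      n_intron_mimic = sum(error_calls$intron_mimic),
      n_candidate_errors = sum(error_calls$candidate_reference_error))
  }

  structure(list(
    stage_counts = tibble(stage = names(counts),
                          n = unlist(counts, use.names = FALSE)),
    transcripts = tx,
    links = links, rejections = rejections,
    evidence_hits = evidence_hits,
    loci = loci,
    concordance = concordance,
    rna_passing = rna_pass, rna_failing = rna_fail,
    genomic_passing = genomic_pass, genomic_failing = genomic_fail,
    genotype_counts = genotype_counts,
    support = support,
    effects = effects,
    error_calls = error_calls,
    table2 = table2,
    mechanisms = mechanisms,
    params = params
  ), class = "refine_report")
}

#' Simulate a dataset and run the full pipeline
#'
#' The single-command demo mode: generates the synthetic dataset for a
#' seed and runs every stage on it.
#'
#' @param config A [sim_config()] or bare seed.
#' @param params A [pipeline_params()].
#' @return List: `sim` (the dataset), `report` (the `refine_report`).
#' @export
run_synthetic_pipeline <- function(config, params = pipeline_params()) {
  sim <- simulate_dataset(config)
  report <- run_pipeline(
    genome = sim$genome, transcripts = sim$transcripts,
    annotations = sim$annotations, long_reads = sim$long_reads,
    junctions = sim$junctions, evidence = sim$evidence,
    rna_variants = sim$rna_variants,
    genomic_variants = sim$genomic_variants,
    comparison_sets = sim$comparisons, params = params)
  list(sim = sim, report = report)
}

#' @export
print.refine_report <- function(x, ...) {
  cat("Transcript refinement report\n")
  for (i in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-28s %d\n", x$stage_counts$stage[i],
                x$stage_counts$n[i]))
  }
  if (!is.null(x$mechanisms)) {
    cat(sprintf("  candidate reference errors: %d (%d homopolymer slips, %d intron mimics)\n",
                x$mechanisms$n_candidate_errors,
                x$mechanisms$n_homopolymer_slip,
                x$mechanisms$n_intron_mimic))
  }
  invisible(x)
}

#' Tidy a pipeline report into one long tally table
#'
#' @param x A `refine_report`.
#' @param ... Unused.
#' @return Tibble: `component`, `key`, `n`.
#' @export
tidy.refine_report <- function(x, ...) {
  out <- list(mutate(x$stage_counts, component = "stage",
                     key = .data$stage) |>
                select("component", "key", "n"))
  if (!is.null(x$concordance)) {
    out <- c(out, list(
      mutate(x$concordance$transcript_venn, component = "transcript_venn",
             key = .data$region) |> select("component", "key", "n"),
      mutate(x$concordance$intron_venn, component = "intron_venn",
             key = .data$region) |> select("component", "key", "n"),
      mutate(x$concordance$loci_counts, component = "loci",
             key = paste0("min_exons_", .data$min_exons),
             n = .data$n_loci) |> select("component", "key", "n")))
  }
  if (!is.null(x$genotype_counts)) {
    out <- c(out, list(
      mutate(x$genotype_counts, component = "genotype_category",
             key = .data$genotype_category) |>
        select("component", "key", "n")))
  }
  if (!is.null(x$table2)) {
    out <- c(out, list(
      mutate(x$table2, component = "orf_extending_support",
             key = paste(.data$support_class, .data$allele_class,
                         sep = "_")) |>
        select("component", "key", "n")))
  }
  bind_rows(out)
}

#' One-row summary of a pipeline report
#'
#' @param x A `refine_report`.
#' @param ... Unused.
#' @return One-row tibble of the headline counts.
#' @export
glance.refine_report <- function(x, ...) {
  get_count <- function(k) {
    i <- match(k, x$stage_counts$stage)
    if (is.na(i)) NA_integer_ else x$stage_counts$n[i]
  }
  tibble(
    n_transcripts_in = get_count("transcripts_in"),
    n_transcripts_final = dplyr::n_distinct(x$transcripts$transcript_id),
    n_links = get_count("links_accepted"),
    n_loci = get_count("loci"),
    n_rna_variants_pass = get_count("rna_variants_pass"),
    n_extending = get_count("extending"),
    n_candidate_errors = get_count("candidate_reference_errors"),
    n_homopolymer_slip = if (is.null(x$mechanisms)) NA_integer_ else
      x$mechanisms$n_homopolymer_slip,
    n_intron_mimic = if (is.null(x$mechanisms)) NA_integer_ else
      x$mechanisms$n_intron_mimic)
}

#' Write a pipeline report to TSV and JSON files
#'
#' Emits the stage counts, Venn tallies, locus tables, support table (wide,
#' one column per dataset count plus "not_validated"), the ORF-extending
#' support-class by variant-class matrix, per-variant effect and error-call
#' tables, and a single JSON rendering of all tallies.
#'
#' @param report A `refine_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  readr::write_tsv(report$stage_counts, fp("stage_counts.tsv"))
  if (!is.null(report$concordance)) {
    s <- report$concordance
    readr::write_tsv(s$transcript_venn, fp("transcript_venn.tsv"))
    readr::write_tsv(s$intron_venn, fp("intron_venn.tsv"))
    readr::write_tsv(s$loci_counts, fp("loci_counts.tsv"))
    readr::write_tsv(s$tx_per_locus, fp("transcripts_per_locus.tsv"))
    readr::write_tsv(s$unannotated, fp("unannotated_breakdown.tsv"))
  }
  if (!is.null(report$support)) {
    wide <- report$support$table |>
      mutate(bin = ifelse(.data$support == 0L, "not_validated",
                          as.character(.data$support))) |>
      select("variant_class", "bin", "n") |>
      tidyr::pivot_wider(names_from = "bin", values_from = "n")
    readr::write_tsv(wide, fp("support_table.tsv"))
  }
  if (!is.null(report$table2)) {
    wide2 <- tidyr::pivot_wider(report$table2,
                                names_from = "allele_class",
                                values_from = "n")
    readr::write_tsv(wide2, fp("orf_extending_support.tsv"))
  }
  if (!is.null(report$effects)) {
    readr::write_tsv(report$effects, fp("orf_effects.tsv"))
  }
  if (!is.null(report$error_calls)) {
    readr::write_tsv(report$error_calls, fp("reference_error_calls.tsv"))
  }
  if (!is.null(report$links)) {
    readr::write_tsv(report$links, fp("merge_links.tsv"))
    readr::write_tsv(report$rejections, fp("merge_rejections.tsv"))
  }
  jsonlite::write_json(tidy(report), fp("report.json"), digits = NA)
  invisible(dir)
}
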