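# ggplot2 views of the main result tables.

#' Plot annotation Venn-region tallies
#'
#' Bar chart of transcript and intron counts per annotation Venn region
#' (E = Ensembl, R = RefSeq, O = OtherRefSeq; combined labels mark
#' overlap of multiple sources).
#'
#' @param summary A `concordance_summary`.
#' @return A ggplot.
#' @export
plot_annotation_venn <- function(summary) {
  df <- bind_rows(
    mutate(summary$transcript_venn, what = "transcripts"),
    mutate(summary$intron_venn, what = "introns"))
  lev <- c("E", "R", "O", "ER", "EO", "RO", "ERO", "none")
  df$region <- factor(df$region, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n,
                                   fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "annotation sources overlapped", y = "count",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the transcripts-per-locus histogram
#'
#' @param summary A `concordance_summary`.
#' @return A ggplot.
#' @export
plot_transcripts_per_locus <- function(summary) {
  df <- mutate(summary$tx_per_locus,
               min_exons = paste0(">= ", .data$min_exons, " exons"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_transcripts,
                                   y = .data$n_loci,
                                   fill = .data$min_exons)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "transcripts per gene locus", y = "gene loci",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the cross-dataset support table
#'
#' @param support Output of [tabulate_dataset_support()] (or the `support`
#'   element of a report).
#' @return A ggplot.
#' @export
plot_support_table <- function(support) {
  df <- support$table |>
    mutate(bin = ifelse(.data$support == 0L, "not validated",
                        as.character(.data$support)))
  df$bin <- factor(df$bin, levels = c(as.character(
    sort(unique(df$support[df$support > 0]))), "not validated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n,
                                   fill = .data$variant_class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "datasets containing the variant", y = "variants",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ORF-extending support matrix
#'
#' Tile view of the support-class by variant-class matrix of ORF-extending
#' variants.
#'
#' @param table2 The `table2` element of a report.
#' @return A ggplot.
#' @export
plot_orf_extending_support <- function(table2) {
  ggplot2::ggplot(table2,
                  ggplot2::aes(x = .data$allele_class,
                               y = .data$support_class,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "variant class", y = "genomic support") +
    ggplot2::theme_minimal()
}

#' Autoplot a pipeline report
#'
#' @param object A `refine_report`.
#' @param type One of `"venn"`, `"loci"`, `"support"`, `"table2"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.refine_report <- function(object, type = c("venn", "loci",
                                                    "support", "table2"),
                                   ...) {
  type <- match.arg(type)
  switch(type,
         venn = plot_annotation_venn(object$concordance),
         loci = plot_transcripts_per_locus(object$concordance),
         support = plot_support_table(object$support),
         table2 = plot_orf_extending_support(object$table2))
}
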