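## RNA-Seq machinery: RPKM from exonic counts, the RPKM > 1 expressed
## filter, > 2.5-fold differential sets, and co-factor-dependent gene
## subsets.

#' Reads per kilobase per million (RPKM)
#'
#' `count / (exonic_length_bp / 1e3) / (total_exonic_reads / 1e6)`.
#'
#' @param count Exonic read count(s).
#' @param exonic_length_bp Summed exon length per gene (>= 1).
#' @param total_exonic_reads Library total of exonic reads (>= 1).
#' @export
rpkm <- function(count, exonic_length_bp, total_exonic_reads) {
  if (any(total_exonic_reads < 1)) abort("total_exonic_reads must be >= 1")
  if (any(exonic_length_bp < 1)) abort("exonic_length_bp must be >= 1")
  count / (exonic_length_bp / 1e3) / (total_exonic_reads / 1e6)
}

#' Build a gene-level expression table
#'
#' @param genes Tibble with `gene_id` and `exonic_length` columns.
#' @param counts Exonic read counts aligned with `genes` rows.
#' @param total_exonic_reads Library total of exonic reads used as the RPKM
#'   denominator; defaults to `sum(counts)`. Supply the library-wide total
#'   when `genes` covers only part of the transcriptome.
#' @return Tibble `gene_id`, `exonic_length`, `count`, `rpkm`, `expressed`
#'   (RPKM > 1).
#' @export
expression_table <- function(genes, counts, total_exonic_reads = NULL) {
  total <- total_exonic_reads %||% sum(counts)
  if (total < 1) abort("library has no exonic reads")
  tibble(
    gene_id = genes$gene_id,
    exonic_length = genes$exonic_length,
    count = counts,
    rpkm = rpkm(counts, genes$exonic_length, total)
  ) |>
    dplyr::mutate(expressed = .data$rpkm > 1)
}

#' Differentially expressed genes between two conditions
#'
#' The universe is genes expressed (RPKM > 1) in either condition. With a
#' 0.1-RPKM pseudocount, genes whose B/A RPKM ratio strictly exceeds `fold`
#' are `up`, those whose A/B ratio strictly exceeds `fold` are `down`.
#'
#' @param table_a,table_b Expression tables ([expression_table()]) over a
#'   matched gene universe (condition A = earlier/reference, B = later).
#' @param fold Strict fold-change cutoff (default 2.5).
#' @param pseudocount RPKM pseudocount (default 0.1).
#' @return Tibble over the expressed universe with `gene_id`, `rpkm_a`,
#'   `rpkm_b`, `log2_ratio` and factor `direction` (up/down/none).
#' @export
differential_genes <- function(table_a, table_b, fold = 2.5,
                               pseudocount = 0.1) {
  stopifnot(identical(table_a$gene_id, table_b$gene_id))
  out <- tibble(
    gene_id = table_a$gene_id,
    rpkm_a = table_a$rpkm,
    rpkm_b = table_b$rpkm
  ) |>
    dplyr::filter(.data$rpkm_a > 1 | .data$rpkm_b > 1) |>
    dplyr::mutate(
      ratio = (.data$rpkm_b + pseudocount) / (.data$rpkm_a + pseudocount),
      log2_ratio = log2(.data$ratio),
      direction = factor(
        dplyr::case_when(
          .data$ratio > fold ~ "up",
          1 / .data$ratio > fold ~ "down",
          TRUE ~ "none"
        ),
        levels = c("up", "down", "none")
      )
    ) |>
    dplyr::select(-"ratio")
  out
}

#' Genes whose induction depends on a co-factor
#'
#' Among genes up-regulated in the control timecourse, a gene is dependent
#' when its induced-condition expression in knockout cells is more than
#' `fold` lower than in control cells (same RPKM pseudocount).
#'
#' @param up_genes Character vector of up-regulated gene ids (from
#'   [differential_genes()] on the control timecourse).
#' @param table_control,table_ko Expression tables at the induced condition
#'   for control and knockout cells.
#' @param fold Strict fold cutoff (default 2.5).
#' @param pseudocount RPKM pseudocount (default 0.1).
#' @return Tibble with `gene_id`, `rpkm_control`, `rpkm_ko`, logical
#'   `dependent`; rows are the up-regulated genes.
#' @export
dependent_genes <- function(up_genes, table_control, table_ko, fold = 2.5,
                            pseudocount = 0.1) {
  stopifnot(identical(table_control$gene_id, table_ko$gene_id))
  tibble(
    gene_id = table_control$gene_id,
    rpkm_control = table_control$rpkm,
    rpkm_ko = table_ko$rpkm
  ) |>
    dplyr::filter(.data$gene_id %in% up_genes) |>
    dplyr::mutate(
      dependent = (.data$rpkm_control + pseudocount) /
        (.data$rpkm_ko + pseudocount) > fold
    )
}
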