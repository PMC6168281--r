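# SNP and individual quality control on the raw genotype table.

# Long SNP tibble (snp_id, id, call) -> individuals x SNPs integer matrix.
snp_matrix <- function(snps) {
  ids <- unique(snps$id)
  sid <- unique(snps$snp_id)
  m <- matrix(NA_integer_, length(ids), length(sid),
              dimnames = list(ids, sid))
  m[cbind(match(snps$id, ids), match(snps$snp_id, sid))] <-
    geno_to_code(snps$call)
  m
}

snp_contigs <- function(snps) {
  u <- dplyr::distinct(snps, .data$snp_id, .keep_all = TRUE)
  stats::setNames(u$contig_id, u$snp_id)
}

#' Filter SNPs on allele count and call rate
#'
#' Removes sites with more than two alleles and sites genotyped in fewer
#' than `min_occurrence` of all samples, the standard QC applied to
#' genotyping-by-sequencing SNP calls.
#'
#' @param raw Long SNP tibble with columns `snp_id`, `id`, `call`, and
#'   optionally `n_alleles` (from [read_vcf()]; sites lacking it are
#'   assumed biallelic).
#' @param min_occurrence Minimum fraction of samples with a call.
#' @return The filtered tibble, with a `qc_report` attribute tabulating
#'   removals. Warns (rather than fails) if nothing survives.
#' @export
filter_snps <- function(raw, min_occurrence = 0.10) {
  n_samples <- dplyr::n_distinct(raw$id)
  per_snp <- raw |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(
      called = sum(!is.na(.data$call)),
      multiallelic = if ("n_alleles" %in% names(raw)) {
        any(.data$n_alleles > 2, na.rm = TRUE)
      } else FALSE,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      low_call = .data$called < min_occurrence * n_samples,
      keep = !.data$multiallelic & !.data$low_call
    )
  keep_ids <- per_snp$snp_id[per_snp$keep]
  if (!length(keep_ids)) {
    warning("no SNPs survive QC filtering")
  }
  out <- dplyr::filter(raw, .data$snp_id %in% keep_ids)
  attr(out, "qc_report") <- tibble::tibble(
    n_input = nrow(per_snp),
    n_multiallelic = sum(per_snp$multiallelic),
    n_low_call = sum(per_snp$low_call & !per_snp$multiallelic),
    n_retained = length(keep_ids)
  )
  out
}

#' Filter individuals on genotyping completeness
#'
#' Drops individuals whose mean read depth (when available) falls at or
#' below `min_depth` or with at most `min_called` genotyped SNPs.
#'
#' @param snps Long SNP tibble (`snp_id`, `id`, `call`).
#' @param min_called Individuals must have more than this many called
#'   genotypes.
#' @param min_depth Depth threshold; used only when `depth_tbl` is given.
#' @param depth_tbl Optional tibble (`id`, `mean_depth`).
#' @return Filtered tibble with a `dropped_individuals` attribute.
#' @export
filter_individuals <- function(snps, min_called = 1000, min_depth = 15,
                               depth_tbl = NULL) {
  per_ind <- snps |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n_called = sum(!is.na(.data$call)), .groups = "drop")
  bad <- per_ind$id[per_ind$n_called <= min_called]
  if (!is.null(depth_tbl)) {
    bad <- union(bad, depth_tbl$id[depth_tbl$mean_depth <= min_depth])
  }
  out <- dplyr::filter(snps, !(.data$id %in% bad))
  attr(out, "dropped_individuals") <- bad
  out
}
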