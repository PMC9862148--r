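#' Genotype table container
#'
#' Holds biallelic SNP calls for a set of subjects: a per-SNP info table
#' (id, position, alleles, gene assignment, functional class) plus two
#' SNP-by-subject matrices, `gt` (normalized unphased genotypes such as
#' `"A/G"`, `NA` = missing) and `gc` (per-call confidence scores in `[0, 1]`,
#' GenCall-style). Genotypes are stored with alleles sorted, so equality
#' comparisons ignore allele order and phase.
#'
#' @param info Tibble with columns `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'   and optionally `gene_symbol`, `functional_class`.
#' @param gt Character matrix (SNP x subject) of `"A/B"` genotypes or `NA`.
#' @param gc Numeric matrix (same shape) of confidence scores; must be
#'   present wherever `gt` is called.
#' @return A `genotype_table`.
#' @export
genotype_table <- function(info, gt, gc) {
  info <- tibble::as_tibble(info)
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(info))) {
    ts_abort("genotype table info needs snp_id, chrom, pos, ref, alt",
             "argument_error")
  }
  if (!("gene_symbol" %in% names(info))) info$gene_symbol <- NA_character_
  if (!("functional_class" %in% names(info))) {
    info$functional_class <- NA_character_
  }
  gt <- as.matrix(gt); gc <- as.matrix(gc)
  if (!identical(dim(gt), dim(gc)) || nrow(gt) != nrow(info)) {
    ts_abort("gt and gc must be SNP x subject matrices matching info",
             "argument_error")
  }
  if (is.null(colnames(gt))) {
    ts_abort("gt must carry subject ids as column names", "argument_error")
  }
  # positions strictly increasing within each chromosome
  for (ch in unique(info$chrom)) {
    p <- info$pos[info$chrom == ch]
    if (any(diff(p) <= 0)) {
      ts_abort(sprintf("positions must be strictly increasing within %s", ch),
               "argument_error")
    }
  }
  if (any(!is.na(gt) & is.na(gc))) {
    ts_abort("every called genotype must carry a confidence score",
             "argument_error")
  }
  gt[] <- normalize_gt(as.vector(gt))
  rownames(gt) <- rownames(gc) <- info$snp_id
  colnames(gc) <- colnames(gt)
  structure(list(info = info, gt = gt, gc = gc), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d SNPs x %d subjects (%d missing calls)\n",
              nrow(x$gt), ncol(x$gt), sum(is.na(x$gt))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$gt)

#' Subject ids of a genotype table
#' @param table A [genotype_table()].
#' @return Character vector.
#' @export
genotype_subjects <- function(table) colnames(table$gt)

#' Subset a genotype table by SNP ids
#' @param table A [genotype_table()].
#' @param snp_ids SNP ids to keep (order preserved from the table).
#' @return A [genotype_table()].
#' @export
subset_snps <- function(table, snp_ids) {
  keep <- table$info$snp_id %in% snp_ids
  genotype_table(table$info[keep, , drop = FALSE],
                 table$gt[keep, , drop = FALSE],
                 table$gc[keep, , drop = FALSE])
}
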