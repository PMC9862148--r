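#' GenCall-style no-call quality control
#'
#' Applies the array QC rule per sample independently: every call whose
#' confidence score is less than or equal to `threshold` is set missing
#' (too far from its cluster centroid to be reliably genotyped); all other
#' calls are unchanged. Idempotent on already-missing calls.
#'
#' @param table A [genotype_table()].
#' @param threshold No-call threshold in `[0, 1]`; default 0.15.
#' @return A [genotype_table()] with low-confidence calls masked.
#' @export
apply_gencall_qc <- function(table, threshold = 0.15) {
  stopifnot(inherits(table, "genotype_table"))
  assert_prob(threshold, "threshold")
  gt <- table$gt
  gt[!is.na(table$gc) & table$gc <= threshold] <- NA_character_
  out <- genotype_table(table$info, gt, table$gc)
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Remove SNPs invariant across the family
#'
#' Retains only SNPs for which at least two of the listed subjects have
#' different called genotypes. SNPs with a missing call in any listed subject
#' are dropped as well (conservative: a partially-missing SNP cannot be
#' certified variable).
#'
#' @param table A [genotype_table()].
#' @param subject_ids Subjects defining invariance; default all subjects in
#'   the table (i.e. the whole family).
#' @return Filtered [genotype_table()].
#' @export
drop_family_invariant_snps <- function(table, subject_ids = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  subject_ids <- subject_ids %||% colnames(table$gt)
  if (length(subject_ids) == 0L) {
    ts_abort("subject_ids must be non-empty", "argument_error")
  }
  if (!all(subject_ids %in% colnames(table$gt))) {
    ts_abort("unknown subject ids", "argument_error")
  }
  sub <- table$gt[, subject_ids, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  variable <- apply(sub, 1L, function(g) length(unique(g[!is.na(g)])) > 1L)
  keep <- complete & variable
  out <- genotype_table(table$info[keep, , drop = FALSE],
                        table$gt[keep, , drop = FALSE],
                        table$gc[keep, , drop = FALSE])
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Find SNPs co-segregating with affection status
#'
#' The discordant-sibling pattern: a SNP matches when the two affected
#' siblings carry the same genotype (compared as unordered allele pairs) and
#' the unaffected twin's genotype differs from that shared genotype. SNPs
#' with a missing call in any of the three siblings are excluded. The input
#' should already be quality-controlled ([apply_gencall_qc()]) and
#' invariant-filtered ([drop_family_invariant_snps()]).
#'
#' @param table A [genotype_table()].
#' @param affected_ids Character vector of length 2: the affected siblings.
#' @param discordant_id The unaffected twin's id.
#' @return A `cosegregation_result`: list with `matching_snps`,
#'   `per_gene_counts`, `per_class_counts`, `n_panel_variable`,
#'   `panel_proportion` and (initially `NA`) `background_proportion`.
#' @export
find_cosegregating_snps <- function(table, affected_ids, discordant_id) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(affected_ids) != 2L) {
    ts_abort("affected_ids must have length 2", "argument_error")
  }
  ids <- c(affected_ids, discordant_id)
  if (anyDuplicated(ids) || !all(ids %in% colnames(table$gt))) {
    ts_abort("sibling ids must be distinct subjects of the table",
             "argument_error")
  }
  g1 <- table$gt[, affected_ids[1]]
  g2 <- table$gt[, affected_ids[2]]
  gd <- table$gt[, discordant_id]
  complete <- !(is.na(g1) | is.na(g2) | is.na(gd))
  match <- complete & g1 == g2 & gd != g1
  match[is.na(match)] <- FALSE
  snps <- table$info$snp_id[match]

  gene <- table$info$gene_symbol[match]
  gene[is.na(gene)] <- "(unassigned)"
  cls <- table$info$functional_class[match]
  cls[is.na(cls)] <- "unannotated"
  n_var <- nrow(table$gt)
  structure(list(
    matching_snps = snps,
    per_gene_counts = if (length(gene)) table(gene) else
      table(factor(character(0))),
    per_class_counts = if (length(cls)) table(cls) else
      table(factor(character(0))),
    n_panel_variable = n_var,
    panel_proportion = if (n_var > 0) length(snps) / n_var else NA_real_,
    background_proportion = NA_real_
  ), class = "cosegregation_result")
}

#' @export
print.cosegregation_result <- function(x, ...) {
  cat(sprintf("<cosegregation_result> %d matching of %d variable SNPs (%.1f%%)\n",
              length(x$matching_snps), x$n_panel_variable,
              100 * x$panel_proportion))
  invisible(x)
}

#' Assign SNPs to panel genes
#'
#' Each SNP lying inside (or within `flank_bp` of) a panel gene interval gets
#' that `gene_symbol`; overlapping candidate assignments are resolved toward
#' the gene whose interval midpoint is nearest (and reported via a message).
#' An existing `functional_class` annotation column is honoured; where it is
#' absent an approximate interval rule fills it in: inside a gene body ->
#' `intronic`, within the flank only -> `intergenic`, outside the panel ->
#' `unannotated`.
#'
#' @param table A [genotype_table()].
#' @param panel A [gene_panel()].
#' @return A [genotype_table()] with `gene_symbol`/`functional_class` filled.
#' @export
annotate_snps <- function(table, panel) {
  stopifnot(inherits(table, "genotype_table"), inherits(panel, "gene_panel"))
  flank <- attr(panel, "flank_bp") %||% 0L
  snp_gr <- GenomicRanges::GRanges(
    table$info$chrom,
    IRanges::IRanges(table$info$pos, table$info$pos))
  gene_gr <- GenomicRanges::GRanges(
    panel$chrom,
    IRanges::IRanges(pmax(1L, panel$start - flank), panel$end + flank))
  body_gr <- GenomicRanges::GRanges(
    panel$chrom, IRanges::IRanges(panel$start, panel$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)

  gene_symbol <- rep(NA_character_, nrow(table$info))
  in_body <- rep(FALSE, nrow(table$info))
  if (length(qh)) {
    mid <- (panel$start + panel$end) / 2
    dist <- abs(table$info$pos[qh] - mid[sh])
    ord <- order(qh, dist)
    qh <- qh[ord]; sh <- sh[ord]; first <- !duplicated(qh)
    if (any(duplicated(qh))) {
      message(sprintf(
        "annotate_snps: %d SNP(s) overlapped multiple genes; nearest midpoint used",
        length(unique(qh[duplicated(qh)]))))
    }
    gene_symbol[qh[first]] <- panel$symbol[sh[first]]
    bh <- GenomicRanges::findOverlaps(snp_gr, body_gr)
    in_body[unique(S4Vectors::queryHits(bh))] <- TRUE
  }
  info <- table$info
  info$gene_symbol <- gene_symbol
  has_class <- !is.na(info$functional_class)
  fallback <- ifelse(!is.na(gene_symbol),
                     ifelse(in_body, "intronic", "intergenic"),
                     "unannotated")
  info$functional_class[!has_class] <- fallback[!has_class]
  out <- genotype_table(info, table$gt, table$gc)
  attr(out, "truth") <- attr(table, "truth")
  out
}

#' Compare the panel co-segregation proportion against the genome background
#'
#' Computes the proportion of pattern-matching SNPs among variable SNPs
#' identically for the panel result and for a background table (which must
#' exclude panel SNPs): the background table is passed through the same
#' invariant filter and pattern match. A zero-variable background yields a
#' missing proportion.
#'
#' @param panel_result A `cosegregation_result` from
#'   [find_cosegregating_snps()].
#' @param genome_table A QC'd background [genotype_table()].
#' @param cohort A [family_cohort()] supplying the sibling ids.
#' @return The `panel_result` with `background_proportion` filled, plus
#'   attribute `background_n_variable`.
#' @export
background_comparison <- function(panel_result, genome_table, cohort) {
  stopifnot(inherits(panel_result, "cosegregation_result"),
            inherits(genome_table, "genotype_table"),
            inherits(cohort, "family_cohort"))
  filt <- drop_family_invariant_snps(genome_table)
  if (nrow(filt$gt) == 0L) {
    panel_result$background_proportion <- NA_real_
    attr(panel_result, "background_n_variable") <- 0L
    return(panel_result)
  }
  bg <- find_cosegregating_snps(filt, cohort$affected_sibling_ids,
                                cohort$discordant_id)
  panel_result$background_proportion <- bg$panel_proportion
  attr(panel_result, "background_n_variable") <- bg$n_panel_variable
  panel_result
}

#' Write co-segregation results
#'
#' `coseg_results.json` holds counts and proportions; `coseg_snps.tsv` lists
#' the matching SNPs with annotations.
#'
#' @param result A `cosegregation_result`.
#' @param table The annotated [genotype_table()] the result came from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_coseg_results <- function(result, table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    n_matching = length(result$matching_snps),
    n_panel_variable = result$n_panel_variable,
    panel_proportion = result$panel_proportion,
    background_proportion = result$background_proportion,
    per_gene_counts = as.list(result$per_gene_counts),
    per_class_counts = as.list(result$per_class_counts),
    matching_snps = result$matching_snps
  ), file.path(dir, "coseg_results.json"), auto_unbox = TRUE, digits = NA)
  keep <- table$info$snp_id %in% result$matching_snps
  utils::write.table(table$info[keep, ], file.path(dir, "coseg_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
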