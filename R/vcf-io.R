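#' Write a genotype table as VCF 4.2
#'
#' One file for the whole family, with FORMAT fields `GT` (unphased genotype)
#' and `GC` (per-call confidence score, GenCall-style). Output is plain text
#' and byte-stable: identical tables produce identical files.
#'
#' @param table A [genotype_table()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  info <- table$info
  subjects <- colnames(table$gt)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=twinscope",
    paste0("##contig=<ID=", unique(info$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GC,Number=1,Type=Float,Description=\"Call confidence score\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subjects), collapse = "\t")
  )
  gt_code <- function(i, s) {
    g <- table$gt[i, s]
    if (is.na(g)) return("./.")
    al <- strsplit(g, "/", fixed = TRUE)[[1]]
    idx <- ifelse(al == info$ref[i], 0L, 1L)
    paste(sort(idx), collapse = "/")
  }
  body <- vapply(seq_len(nrow(info)), function(i) {
    calls <- vapply(subjects, function(s) {
      gc <- table$gc[i, s]
      paste0(gt_code(i, s), ":",
             ifelse(is.na(gc), ".", sprintf("%.4f", gc)))
    }, character(1))
    ann <- character(0)
    if (!is.na(info$gene_symbol[i])) {
      ann <- c(ann, paste0("GENE=", info$gene_symbol[i]))
    }
    if (!is.na(info$functional_class[i])) {
      ann <- c(ann, paste0("FCLASS=", info$functional_class[i]))
    }
    paste(c(info$chrom[i], info$pos[i], info$snp_id[i], info$ref[i],
            info$alt[i], ".", "PASS",
            if (length(ann)) paste(ann, collapse = ";") else ".",
            "GT:GC", calls), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a family VCF into a genotype table
#'
#' Parses with `vcfR` and reconstructs the SNP-by-subject genotype and
#' confidence matrices. Genotypes are normalized to unordered allele pairs;
#' `./.` becomes a missing call.
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_table()].
#' @export
read_family_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gc_raw <- vcfR::extract.gt(v, element = "GC", as.numeric = TRUE)
  grab <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0(key, "=[^;]+"), fix$INFO))
    out <- rep(NA_character_, nrow(fix))
    out[grepl(paste0(key, "="), fix$INFO)] <- sub(paste0(key, "="), "", m)
    out
  }
  info <- tibble::tibble(
    snp_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    gene_symbol = grab("GENE"), functional_class = grab("FCLASS")
  )
  decode <- function(code, ref, alt) {
    if (is.na(code) || code %in% c("./.", ".")) return(NA_character_)
    idx <- as.integer(strsplit(code, "[/|]")[[1]])
    paste(sort(c(ref, alt)[idx + 1L]), collapse = "/")
  }
  gt <- matrix(NA_character_, nrow(info), ncol(gt_raw),
               dimnames = list(info$snp_id, colnames(gt_raw)))
  for (j in seq_len(ncol(gt_raw))) {
    gt[, j] <- vapply(seq_len(nrow(info)), function(i)
      decode(gt_raw[i, j], info$ref[i], info$alt[i]), character(1))
  }
  genotype_table(info, gt, gc_raw)
}

#' Write / read the pedigree sidecar
#'
#' Six-column PED-like TSV (`family_id`, `subject_id`, `father_id`,
#' `mother_id`, `sex`, `role`) plus an `affected` column. Sex is coded 0
#' (unknown) for parents whose ids do not disambiguate and 2 for the siblings
#' (the reference family's siblings are female).
#'
#' @param cohort A [family_cohort()].
#' @param path TSV path.
#' @return `path` invisibly; `read_pedigree()` returns a [family_cohort()].
#' @export
write_pedigree <- function(cohort, path) {
  stopifnot(inherits(cohort, "family_cohort"))
  s <- cohort$subjects
  parents <- s$subject_id[s$role == "parent"]
  ped <- data.frame(
    family_id = "FAM1",
    subject_id = s$subject_id,
    father_id = ifelse(s$role == "parent", "0", parents[2]),
    mother_id = ifelse(s$role == "parent", "0", parents[1]),
    sex = ifelse(s$role == "parent", 0L, 2L),
    role = s$role,
    affected = as.integer(s$affected)
  )
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  family_cohort(tibble::tibble(
    subject_id = ped$subject_id,
    role = ped$role,
    affected = as.logical(ped$affected)
  ))
}
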