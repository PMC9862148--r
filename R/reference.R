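#' Reference values from the SRD discordant-twin family case study
#'
#' The pipeline was designed around a single nuclear-family case study of
#' specific reading disability. These helpers return the published summary
#' numbers of that family as in-code tables; the underlying subject-level data
#' are protected and never shipped. They serve two purposes: (i) the
#' synthetic-data generator uses them as its default "study conditions"
#' (planted asymmetry indices, sibling-similarity targets), and (ii)
#' consistency checks verify the pipeline's tally identities against them.
#'
#' `case_gene_counts()`: co-segregating SNPs per gene (genes where the two
#' affected siblings shared a genotype and the unaffected twin differed).
#' `case_class_counts()`: the same SNPs by functional class.
#' `case_variable_snps()`: the number of family-variable panel SNPs that
#' entered the pattern filter.
#' `case_asymmetry()`: per-sibling hemispheric asymmetry indices
#' `(L - R)/((L + R)/2)` for the reading-related regions, for cortical
#' thickness, grey-matter volume and cortical surface area.
#' `case_icc()`: pairwise intraclass correlations per phenotype for
#' whole-cortex and reading-region sets.
#'
#' @return Tibbles (or a named numeric vector for the count helpers).
#' @name case_reference
NULL

#' @rdname case_reference
#' @export
case_gene_counts <- function() {
  c(ZNF385D = 33, LPHN3 = 17, CNTNAP2 = 9, FGF18 = 2, NOP9 = 2,
    CMIP = 11, MYO18B = 4, RBFOX2 = 1)
}

#' @rdname case_reference
#' @export
case_class_counts <- function() {
  c(intronic = 57, exonic = 1, utr3 = 1, intergenic = 20)
}

#' @rdname case_reference
#' @export
case_variable_snps <- function() 684L

#' @rdname case_reference
#' @export
case_asymmetry <- function() {
  rois <- c("fusiform", "banks_superior_temporal_sulcus", "pars_opercularis",
            "pars_triangularis", "supramarginal", "transverse_temporal",
            "superior_temporal")
  subj <- c("proband", "td_twin", "older_sib")
  vals <- list(
    thickness = rbind(
      proband   = c(-0.008, -0.113, -0.022,  0.021, -0.018,  0.020, -0.008),
      td_twin   = c( 0.027, -0.012, -0.022,  0.043,  0.019, -0.217, -0.078),
      older_sib = c( 0.047,  0.009,  0.027, -0.001,  0.012,  0.084, -0.006)),
    volume = rbind(
      proband   = c(-0.075, -0.079,  0.042, -0.117,  0.185,  0.126,  0.043),
      td_twin   = c( 0.037, -0.240,  0.083,  0.004,  0.593,  0.247,  0.141),
      older_sib = c(-0.078,  0.123,  0.051, -0.136,  0.082,  0.359,  0.117)),
    area = rbind(
      proband   = c(-0.084, -0.007,  0.072, -0.121,  0.225,  0.203,  0.024),
      td_twin   = c(-0.016, -0.213,  0.113,  0.015,  0.551,  0.435,  0.203),
      older_sib = c(-0.113,  0.077,  0.076, -0.105,  0.054,  0.320,  0.127))
  )
  out <- lapply(names(vals), function(ph) {
    m <- vals[[ph]]
    tibble::tibble(
      subject_id = rep(subj, each = length(rois)),
      roi = rep(rois, times = length(subj)),
      phenotype = ph,
      index = as.vector(t(m))
    )
  })
  dplyr::bind_rows(out)
}

#' @rdname case_reference
#' @export
case_icc <- function() {
  tibble::tibble(
    phenotype  = rep(c("thickness", "volume", "area"), each = 6L),
    region_set = rep(rep(c("whole_cortex", "reading"), each = 3L), times = 3L),
    pair       = rep(c("twin-twin", "SRD", "TD-OS"), times = 6L),
    icc = c(
      0.85, 0.87, 0.82,   # thickness, whole cortex
      0.66, 0.76, 0.54,   # thickness, reading set
      0.97, 0.98, 0.97,   # volume, whole cortex
      0.97, 0.99, 0.95,   # volume, reading set
      0.97, 0.99, 0.96,   # area, whole cortex
      0.96, 0.99, 0.95    # area, reading set
    )
  )
}
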