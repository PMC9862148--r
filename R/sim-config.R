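#' Simulation configuration for the synthetic family generator
#'
#' One config object fixes every data-generating choice, so that any artifact
#' regenerated from the same config is byte-identical. The defaults are the
#' study conditions of the reference case family: an 800-SNP reading-gene
#' panel of which 14.5% are family-invariant (leaving 684 variable SNPs) and
#' 79 are planted with the SRD co-segregation pattern; sibling-similarity
#' targets equal to the case's reading-region intraclass correlations; mask
#' slice counts in the 30-70-per-axis range on a shared 96^3 template grid.
#'
#' @param n_snps_panel Number of panel SNPs (default 800).
#' @param n_snps_background Number of genome-background SNPs (default 2000).
#' @param coseg_fraction Fraction of panel SNPs planted with the
#'   co-segregation pattern (affected siblings share a genotype, unaffected
#'   twin differs). Default `79/800`, so the planted count is exactly 79.
#' @param missing_rate Per-call probability of a low-confidence call
#'   (GenCall-style score drawn at or below the 0.15 no-call threshold).
#'   Default 0.01.
#' @param invariant_rate Fraction of panel SNPs identical across all five
#'   family members. Default 0.145 (800 x 0.145 = 116, leaving 684 variable).
#' @param similarity_profile Sibling-pair correlation targets per phenotype:
#'   a tibble with columns `phenotype`, `pair` (`twin-twin`, `SRD`, `TD-OS`)
#'   and `target` in `[0, 1]`. Default: the case study's reading-region ICCs.
#' @param asymmetry_profile Optional tibble `subject_id`, `roi`, `phenotype`,
#'   `index` of asymmetry indices to plant exactly; indices must lie in
#'   `[-2, 2]`. Default `NULL` (none planted).
#' @param noise_sd Standard deviation of item-level measurement noise added
#'   after the similarity structure is planted, in standardized units
#'   (default 0.05).
#' @param mask_slices_per_axis Integer range (length 2) for nonzero mask
#'   slice counts per anatomical axis. Default `c(30, 70)`.
#' @param grid_shape Template grid dimensions, default `c(96, 96, 96)`
#'   (sagittal, coronal, axial).
#' @param mask_profile Optional per-ROI subject shape offsets: tibble with
#'   columns `roi`, `subject_id`, `scale` (relative semi-axis scale offset).
#'   Subjects whose offsets are close produce masks whose luminosity
#'   distributions are close. Default `NULL` (no planted structure).
#' @param mask_jitter SD of the random per-subject relative size jitter
#'   applied on top of `mask_profile` (default 0.02).
#' @param seed Integer seed fixing all randomness end-to-end.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps_panel = 800L,
                       n_snps_background = 2000L,
                       coseg_fraction = 79 / 800,
                       missing_rate = 0.01,
                       invariant_rate = 0.145,
                       similarity_profile = NULL,
                       asymmetry_profile = NULL,
                       noise_sd = 0.05,
                       mask_slices_per_axis = c(30L, 70L),
                       grid_shape = c(96L, 96L, 96L),
                       mask_profile = NULL,
                       mask_jitter = 0.02,
                       seed = 1L) {
  n_snps_panel <- assert_count(n_snps_panel, "n_snps_panel", min = 1L)
  n_snps_background <- assert_count(n_snps_background, "n_snps_background")
  assert_prob(coseg_fraction, "coseg_fraction")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(invariant_rate, "invariant_rate")
  if (coseg_fraction + invariant_rate > 1) {
    ts_abort("coseg_fraction + invariant_rate must not exceed 1",
             "config_error")
  }
  if (is.null(similarity_profile)) {
    ref <- case_icc()
    ref <- ref[ref$region_set == "reading", ]
    similarity_profile <- tibble::tibble(
      phenotype = ref$phenotype, pair = ref$pair, target = ref$icc)
  }
  similarity_profile <- tibble::as_tibble(similarity_profile)
  if (!all(c("phenotype", "pair", "target") %in% names(similarity_profile)) ||
      any(similarity_profile$target < 0 | similarity_profile$target > 1)) {
    ts_abort("similarity_profile needs columns phenotype, pair, target with targets in [0, 1]",
             "config_error")
  }
  if (!is.null(asymmetry_profile)) {
    asymmetry_profile <- tibble::as_tibble(asymmetry_profile)
    req <- c("subject_id", "roi", "phenotype", "index")
    if (!all(req %in% names(asymmetry_profile))) {
      ts_abort("asymmetry_profile needs columns subject_id, roi, phenotype, index",
               "config_error")
    }
    if (any(abs(asymmetry_profile$index) > 2)) {
      ts_abort("asymmetry indices must lie in [-2, 2]", "config_error")
    }
    asymmetry_profile$roi <- canonical_roi(asymmetry_profile$roi)
  }
  if (length(mask_slices_per_axis) != 2L ||
      mask_slices_per_axis[1] > mask_slices_per_axis[2] ||
      mask_slices_per_axis[1] < 1L) {
    ts_abort("mask_slices_per_axis must be an increasing range with min >= 1",
             "config_error")
  }
  if (length(grid_shape) != 3L || any(grid_shape < 1)) {
    ts_abort("grid_shape must be 3 positive integers", "config_error")
  }
  if (any(mask_slices_per_axis[2] > grid_shape)) {
    ts_abort("mask_slices_per_axis must fit within every grid dimension",
             "geometry_error")
  }
  structure(list(
    n_snps_panel = n_snps_panel,
    n_snps_background = n_snps_background,
    coseg_fraction = coseg_fraction,
    missing_rate = missing_rate,
    invariant_rate = invariant_rate,
    similarity_profile = similarity_profile,
    asymmetry_profile = asymmetry_profile,
    noise_sd = noise_sd,
    mask_slices_per_axis = as.integer(mask_slices_per_axis),
    grid_shape = as.integer(grid_shape),
    mask_profile = mask_profile,
    mask_jitter = mask_jitter,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# run code under a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
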