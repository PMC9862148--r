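#' Simulate sibling morphometry with planted similarity and asymmetry
#'
#' Generates the three siblings' regional morphometry (one value per ROI,
#' hemisphere and phenotype) so that the empirical inter-sibling correlation
#' matrix over the (ROI, hemisphere) items equals the configured
#' `similarity_profile` targets exactly before measurement noise: latent item
#' vectors are mean-centred and orthonormalized, then mixed through a square
#' root of the target correlation matrix. Independent Gaussian measurement
#' noise (`cfg$noise_sd`, standardized units) is added afterwards, so
#' downstream ICC estimates concentrate tightly around the targets. Where
#' `cfg$asymmetry_profile` specifies an index for a (subject, ROI, phenotype)
#' cell, the left/right values are replaced by the exact solution
#' `L = m (1 + a/2)`, `R = m (1 - a/2)` with `m` the cell's generated mean,
#' so the asymmetry index round-trips to machine precision.
#'
#' @param cohort A [family_cohort()].
#' @param roi_set Character vector of ROI names (canonicalized).
#' @param cfg A [sim_config()].
#' @param seed_offset Added to `cfg$seed` (default 0).
#' @return A `morphometry_table` for the three siblings with attribute
#'   `truth` (the planted profiles).
#' @export
simulate_morphometry <- function(cohort, roi_set, cfg, seed_offset = 0L) {
  stopifnot(inherits(cohort, "family_cohort"), inherits(cfg, "sim_config"))
  roi_set <- unique(canonical_roi(roi_set))
  if (length(roi_set) < 2L) {
    ts_abort("roi_set must contain at least 2 ROIs", "argument_error")
  }
  sibs <- sibling_ids(cohort)          # affected twin, TD twin, older sib
  items <- expand.grid(roi = roi_set, hemi = c("lh", "rh"),
                       stringsAsFactors = FALSE)
  n <- nrow(items)
  scales <- list(thickness = c(mu = 2.6, sd = 0.25),
                 area      = c(mu = 3000, sd = 500),
                 volume    = c(mu = 8000, sd = 1500))

  with_seed(cfg$seed + 101L + seed_offset, {
    out <- lapply(names(scales), function(ph) {
      C <- pair_targets_to_corr(cfg$similarity_profile, ph)
      X <- plant_correlated_items(n, C)       # n x 3, exact sample corr C
      sc <- scales[[ph]]
      v <- sc["mu"] + sc["sd"] * X
      v <- v + stats::rnorm(length(v), 0, cfg$noise_sd * sc["sd"])
      v <- pmax(v, 0.02 * sc["mu"])           # guard strict positivity
      tibble::tibble(
        subject_id = rep(sibs, each = n),
        hemi = rep(items$hemi, times = 3L),
        roi = rep(items$roi, times = 3L),
        phenotype = ph,
        value = as.vector(v)
      )
    })
    long <- dplyr::bind_rows(out)

    ap <- cfg$asymmetry_profile
    if (!is.null(ap)) long <- plant_asymmetry(long, ap)
    tab <- morphometry_table(long)
    attr(tab, "truth") <- list(similarity = cfg$similarity_profile,
                               asymmetry = ap)
    tab
  })
}

# 3x3 correlation matrix in sibling order (affected twin, TD twin, older sib)
pair_targets_to_corr <- function(profile, phenotype) {
  p <- profile[profile$phenotype == phenotype, ]
  need <- c("twin-twin", "SRD", "TD-OS")
  if (!all(need %in% p$pair)) {
    ts_abort(sprintf("similarity_profile must give all three pairs for %s",
                     phenotype), "config_error")
  }
  tt <- p$target[match("twin-twin", p$pair)]
  srd <- p$target[match("SRD", p$pair)]
  tdos <- p$target[match("TD-OS", p$pair)]
  C <- matrix(c(1, tt, srd,
                tt, 1, tdos,
                srd, tdos, 1), 3L, 3L)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    ts_abort("similarity targets do not form a valid correlation matrix",
             "config_error")
  }
  C
}

# n x 3 matrix whose columns are mean-zero, sample-sd one, with sample
# correlation matrix exactly C (up to PSD rank deficiency, e.g. targets of 1)
plant_correlated_items <- function(n, C) {
  if (n < 4L) ts_abort("need at least 4 items to plant 3-subject structure",
                       "argument_error")
  Z <- matrix(stats::rnorm(n * 3L), n, 3L)
  Zc <- sweep(Z, 2L, colMeans(Z))
  E <- qr.Q(qr(Zc))[, 1:3]                      # orthonormal, mean-zero
  # pivoted Cholesky handles rank-deficient targets (e.g. correlations of 1)
  ch <- suppressWarnings(chol(C, pivot = TRUE))
  r <- attr(ch, "rank"); piv <- attr(ch, "pivot")
  if (r < 3L) ch[(r + 1L):3L, ] <- 0
  R <- ch[, order(piv), drop = FALSE]           # t(R) %*% R == C
  E %*% R * sqrt(n - 1)
}

# overwrite L/R for profiled cells so the index is exact
plant_asymmetry <- function(long, ap) {
  for (i in seq_len(nrow(ap))) {
    sel <- long$subject_id == ap$subject_id[i] & long$roi == ap$roi[i] &
      long$phenotype == ap$phenotype[i]
    if (!any(sel)) next
    m <- mean(long$value[sel])
    if (!is.finite(m) || m <= 0) m <- 1
    a <- ap$index[i]
    long$value[sel & long$hemi == "lh"] <- m * (1 + a / 2)
    long$value[sel & long$hemi == "rh"] <- m * (1 - a / 2)
  }
  long
}
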