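#' Intraclass correlation of two measurement vectors
#'
#' Single-measure ICC from the classical ANOVA mean squares, for `n` items
#' ("targets") measured by `k = 2` raters — here, two siblings measured over
#' the same (ROI, hemisphere) items. Three forms:
#' `ICC(1,1)` one-way random; `ICC(2,1)` two-way random, absolute agreement
#' (sensitive to a constant shift between raters); `ICC(3,1)` two-way mixed,
#' consistency (shift-invariant).
#'
#' @param x Numeric matrix, items x raters (>= 3 rows, >= 2 columns).
#' @param form `"ICC(1,1)"`, `"ICC(2,1)"` or `"ICC(3,1)"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List with `icc`, `ci95` (length-2), `p_value`, `n_items`, `form`.
#' @export
icc_single <- function(x, form = "ICC(2,1)", conf_level = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  form <- match.arg(form, c("ICC(1,1)", "ICC(2,1)", "ICC(3,1)"))
  if (n < 3L) ts_abort("at least 3 items are required", "insufficient_data")
  if (k < 2L) ts_abort("at least 2 raters are required", "insufficient_data")
  grand <- mean(x)
  rowm <- rowMeans(x); colm <- colMeans(x)
  SST <- sum((x - grand)^2)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  SSW <- SST - SSR
  MSW <- SSW / (n * (k - 1))
  if (SSR <= .Machine$double.eps * max(1, SST)) {
    ts_abort("zero variance across items: ICC undefined (degenerate input)",
             "degenerate_input")
  }
  alpha <- 1 - conf_level
  eps <- 1e-12
  if (form == "ICC(1,1)") {
    icc <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    if (MSW > eps * MSR) {
      F0 <- MSR / MSW
      p <- stats::pf(F0, n - 1, n * (k - 1), lower.tail = FALSE)
      FL <- F0 / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
      FU <- F0 * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else { p <- 0; ci <- c(1, 1) }
  } else if (form == "ICC(3,1)") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE > eps * MSR) {
      F0 <- MSR / MSE
      df2 <- (n - 1) * (k - 1)
      p <- stats::pf(F0, n - 1, df2, lower.tail = FALSE)
      FL <- F0 / stats::qf(1 - alpha / 2, n - 1, df2)
      FU <- F0 * stats::qf(1 - alpha / 2, df2, n - 1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    } else { p <- 0; ci <- c(1, 1) }
  } else {
    icc <- (MSR - MSE) /
      (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE > eps * MSR || MSC > eps * MSR) {
      df2 <- (n - 1) * (k - 1)
      F0 <- MSR / MSE
      p <- stats::pf(F0, n - 1, df2, lower.tail = FALSE)
      # Shrout-Fleiss approximate interval for the absolute-agreement form
      a <- k * icc / (n * (1 - icc))
      b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / df2)
      Fs <- stats::qf(1 - alpha / 2, n - 1, v)
      lo <- n * (MSR - Fs * MSE) /
        (Fs * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      Fs2 <- stats::qf(1 - alpha / 2, v, n - 1)
      up <- n * (Fs2 * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * Fs2 * MSR)
      ci <- c(lo, up)
    } else { p <- 0; ci <- c(1, 1) }
  }
  list(icc = icc, ci95 = ci, p_value = p, n_items = n, form = form)
}

#' Pairwise ICC of regional morphometry between two siblings
#'
#' Builds the item vector over a region set — each (ROI, hemisphere) average
#' value is one item; hemispheres are kept separate — and computes the
#' single-measure ICC between the two subjects. The default form is
#' `ICC(2,1)` (two-way random, absolute agreement): the siblings are treated
#' as interchangeable measurements of the same regional anatomy, so constant
#' offsets between siblings count against similarity.
#'
#' @param table A `morphometry_table`.
#' @param pair Character vector of two subject ids.
#' @param phenotype One of `thickness`, `area`, `volume`.
#' @param region_set A [region_set()].
#' @param icc_form ICC form, see [icc_single()].
#' @return An `icc_result`: list with `pair`, `phenotype`, `region_set`,
#'   `icc`, `icc_form`, `n_items`, `ci95`, `p_value`.
#' @export
pairwise_icc <- function(table, pair, phenotype, region_set,
                         icc_form = "ICC(2,1)") {
  stopifnot(inherits(table, "morphometry_table"))
  if (length(pair) != 2L || anyDuplicated(pair)) {
    ts_abort("`pair` must be two distinct subject ids", "argument_error")
  }
  ph <- match.arg(phenotype, c("thickness", "area", "volume"))
  sub <- table[table$phenotype == ph & table$roi %in% region_set$rois &
                 table$subject_id %in% pair, ]
  if (!all(pair %in% sub$subject_id)) {
    ts_abort("both subjects must be present in the table", "argument_error")
  }
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "hemi", "roi", "value")],
                             names_from = "subject_id",
                             values_from = "value")
  m <- as.matrix(wide[, pair])
  if (nrow(m) < 3L) {
    ts_abort("fewer than 3 (roi, hemi) items in the region set",
             "insufficient_data")
  }
  res <- icc_single(m, form = icc_form)
  structure(list(pair = pair, phenotype = ph, region_set = region_set$name,
                 icc = res$icc, icc_form = res$form, n_items = res$n_items,
                 ci95 = res$ci95, p_value = res$p_value),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> %s vs %s | %s | %s set | %s = %.3f (n=%d)\n",
              x$pair[1], x$pair[2], x$phenotype, x$region_set, x$icc_form,
              x$icc, x$n_items))
  invisible(x)
}

#' ICCs for every sibling pair, phenotype and region set
#'
#' @param table A `morphometry_table`.
#' @param cohort A [family_cohort()].
#' @param region_sets List of [region_set()]s.
#' @param icc_form ICC form, see [icc_single()].
#' @return Tibble: one row per pair x phenotype x region set.
#' @export
icc_matrix <- function(table, cohort, region_sets, icc_form = "ICC(2,1)") {
  pairs <- enumerate_subject_pairs(cohort)
  grid <- expand.grid(p = seq_len(nrow(pairs)),
                      ph = c("thickness", "area", "volume"),
                      rs = seq_along(region_sets), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pr <- pairs[grid$p[i], ]
    rs <- region_sets[[grid$rs[i]]]
    r <- pairwise_icc(table, c(pr$id1, pr$id2), grid$ph[i], rs, icc_form)
    tibble::tibble(pair = pr$label, phenotype = r$phenotype,
                   region_set = r$region_set, icc_form = r$icc_form,
                   icc = r$icc, n_items = r$n_items,
                   ci_low = r$ci95[1], ci_high = r$ci95[2],
                   p_value = r$p_value)
  })
  dplyr::bind_rows(rows)
}
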