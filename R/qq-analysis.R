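#' Luminosity distributions for all subjects, ROIs and axes
#'
#' For each (ROI, axis) the alpha reference is the maximum slice count over
#' subjects ([alpha_reference()]), composites are built with that shared
#' constant, and distributions extracted under one background rule. Axes are
#' analyzed separately (never pooled).
#'
#' @param masks Nested list `masks[[roi]][[subject_id]]` of [mask_volume()]s
#'   (as returned by [simulate_masks()]).
#' @param axes Character vector of axes (default all three).
#' @param background_rule See [extract_distribution()].
#' @return Nested list `dists[[roi]][[axis]][[subject_id]]` of
#'   `luminosity_distribution`s.
#' @export
luminosity_distributions <- function(masks,
                                     axes = c("sagittal", "coronal", "axial"),
                                     background_rule = "exclude_zero") {
  dists <- lapply(names(masks), function(roi) {
    per_axis <- lapply(axes, function(ax) {
      stacks <- lapply(masks[[roi]], slice_mask, axis = ax)
      aref <- max(vapply(stacks, attr, integer(1), which = "n_slices"))
      lapply(stacks, function(st) {
        extract_distribution(build_composite(st, aref), background_rule)
      })
    })
    stats::setNames(per_axis, axes)
  })
  stats::setNames(dists, names(masks))
}

#' Inter-subject Q-Q comparisons per ROI and axis
#'
#' Builds the three sibling-pair Q-Q curves for every ROI and axis and picks
#' the most similar pair per (ROI, axis).
#'
#' @param dists Output of [luminosity_distributions()].
#' @param cohort A [family_cohort()].
#' @param n_quantiles See [qq_compare()].
#' @return List with `curves` (tibble: roi, axis, pair, divergence) and
#'   `most_similar` (tibble: roi, axis, label, margin, tie).
#' @export
intersubject_qq <- function(dists, cohort, n_quantiles = 99L) {
  pairs <- enumerate_subject_pairs(cohort)
  rows <- list(); ms_rows <- list()
  for (roi in names(dists)) {
    for (ax in names(dists[[roi]])) {
      d <- dists[[roi]][[ax]]
      curves <- stats::setNames(lapply(seq_len(nrow(pairs)), function(i) {
        qq_compare(d[[pairs$id1[i]]], d[[pairs$id2[i]]], n_quantiles,
                   labels = c(pairs$id1[i], pairs$id2[i]))
      }), pairs$label)
      ms <- most_similar_pair(curves)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        roi = roi, axis = ax, pair = pairs$label,
        divergence = vapply(curves, function(cv) cv$divergence, numeric(1)))
      ms_rows[[length(ms_rows) + 1L]] <- tibble::tibble(
        roi = roi, axis = ax, label = ms$label, margin = ms$margin,
        tie = ms$tie)
    }
  }
  list(curves = dplyr::bind_rows(rows),
       most_similar = dplyr::bind_rows(ms_rows))
}

#' Intra-subject ROI-pair Q-Q comparisons along reading pathways
#'
#' For every pathway, every unordered pair of its member ROIs and every
#' subject, compares the subject's own two ROI distributions on the same
#' axis (axes are never mixed).
#'
#' @param dists Output of [luminosity_distributions()].
#' @param pathways Named list of pathways (see [pathway_definitions()]).
#' @param n_quantiles See [qq_compare()].
#' @return Tibble: pathway, roi1, roi2, axis, subject_id, divergence.
#' @export
intrasubject_qq <- function(dists, pathways = pathway_definitions(),
                            n_quantiles = 99L) {
  rows <- list()
  for (pw in pathways) {
    prs <- enumerate_roi_pairs(pw)
    for (i in seq_len(nrow(prs))) {
      r1 <- prs$roi1[i]; r2 <- prs$roi2[i]
      if (!(r1 %in% names(dists)) || !(r2 %in% names(dists))) next
      for (ax in names(dists[[r1]])) {
        subs <- intersect(names(dists[[r1]][[ax]]), names(dists[[r2]][[ax]]))
        for (s in subs) {
          cv <- qq_compare(dists[[r1]][[ax]][[s]], dists[[r2]][[ax]][[s]],
                           n_quantiles, labels = c(r1, r2))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            pathway = pw$name, roi1 = r1, roi2 = r2, axis = ax,
            subject_id = s, divergence = cv$divergence)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}
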