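#' Validate a morphometry table
#'
#' Long-format regional morphometry: one row per (subject, hemisphere, ROI,
#' phenotype) with a strictly positive value (cortical thickness in mm,
#' surface area in mm^2, grey-matter volume in mm^3). Every ROI must be
#' present for both hemispheres for every subject; duplicate keys are
#' rejected.
#'
#' @param x Data frame with columns `subject_id`, `hemi` (`lh`/`rh`), `roi`,
#'   `phenotype` (`thickness`/`area`/`volume`), `value`.
#' @return A validated `morphometry_table` tibble.
#' @export
morphometry_table <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("subject_id", "hemi", "roi", "phenotype", "value")
  if (!all(req %in% names(x))) {
    ts_abort(paste("morphometry table needs columns",
                   paste(req, collapse = ", ")), "validation_error")
  }
  if (!all(x$hemi %in% c("lh", "rh"))) {
    ts_abort("hemi must be 'lh' or 'rh'", "validation_error")
  }
  if (!all(x$phenotype %in% c("thickness", "area", "volume"))) {
    ts_abort("phenotype must be thickness, area or volume", "validation_error")
  }
  if (any(!is.finite(x$value) | x$value <= 0)) {
    ts_abort("morphometry values must be strictly positive", "validation_error")
  }
  x$roi <- canonical_roi(x$roi)
  key <- paste(x$subject_id, x$hemi, x$roi, x$phenotype)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ts_abort(sprintf("duplicated morphometry row: %s", dup),
             "validation_error")
  }
  # both hemispheres present per (subject, roi, phenotype)
  wide <- stats::aggregate(list(n = x$value),
                           by = list(subject_id = x$subject_id, roi = x$roi,
                                     phenotype = x$phenotype),
                           FUN = length)
  bad <- wide[wide$n != 2L, ]
  if (nrow(bad) > 0L) {
    ts_abort(sprintf("missing hemisphere counterpart for ROI(s): %s",
                     paste(unique(bad$roi), collapse = ", ")),
             "validation_error")
  }
  class(x) <- c("morphometry_table", class(x))
  x
}

#' Read / write morphometry TSV
#'
#' The on-disk dialect is a wide per-phenotype table in the style of
#' FreeSurfer stats exports: columns `subject_id`, `hemi`, `roi`,
#' `thickness_mm`, `area_mm2`, `volume_mm3`.
#'
#' @param path TSV path.
#' @return `read_morphometry()`: a validated `morphometry_table`;
#'   `write_morphometry()`: `path`, invisibly.
#' @export
read_morphometry <- function(path) {
  if (!file.exists(path)) ts_abort(paste("no such file:", path), "io_error")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("subject_id", "hemi", "roi", "thickness_mm", "area_mm2",
           "volume_mm3")
  if (!all(req %in% names(tab))) {
    ts_abort(paste("morphometry file needs columns",
                   paste(req, collapse = ", ")), "validation_error")
  }
  long <- tidyr::pivot_longer(tab,
    cols = c("thickness_mm", "area_mm2", "volume_mm3"),
    names_to = "phenotype", values_to = "value")
  long$phenotype <- c(thickness_mm = "thickness", area_mm2 = "area",
                      volume_mm3 = "volume")[long$phenotype]
  morphometry_table(long)
}

#' @rdname read_morphometry
#' @param table A `morphometry_table`.
#' @export
write_morphometry <- function(table, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(table),
                             names_from = "phenotype", values_from = "value")
  wide <- dplyr::rename(wide, thickness_mm = "thickness", area_mm2 = "area",
                        volume_mm3 = "volume")
  wide <- dplyr::arrange(wide, .data$subject_id, .data$roi, .data$hemi)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hemispheric asymmetry index
#'
#' `(L - R) / ((L + R) / 2)`: positive values indicate leftward asymmetry
#' (larger left-hemisphere value), negative values rightward. Antisymmetric
#' under swapping L and R and invariant to rescaling both by the same
#' positive constant; bounded in (-2, 2) for positive inputs.
#'
#' @param L,R Strictly positive left/right hemisphere values (vectorized).
#' @return Numeric vector of asymmetry indices.
#' @export
asymmetry_index <- function(L, R) {
  if (any(!is.finite(L) | !is.finite(R) | L <= 0 | R <= 0)) {
    ts_abort("L and R must be strictly positive", "domain_error")
  }
  2 * (L - R) / (L + R)
}

#' Classify asymmetry direction
#'
#' `leftward` if the index exceeds `epsilon`, `rightward` if below
#' `-epsilon`, otherwise `symmetric`. The default tolerance 0.01 treats
#' near-zero indices as symmetric.
#'
#' @param index Numeric vector of asymmetry indices.
#' @param epsilon Symmetry tolerance (default 0.01).
#' @return Character vector: `leftward`, `rightward` or `symmetric`.
#' @export
classify_direction <- function(index, epsilon = 0.01) {
  if (any(!is.finite(index))) ts_abort("index must be finite", "domain_error")
  ifelse(index > epsilon, "leftward",
         ifelse(index < -epsilon, "rightward", "symmetric"))
}

#' Per-subject, per-ROI asymmetry records
#'
#' Computes the asymmetry index for every subject and every ROI of a region
#' set for one phenotype. ROIs absent from the table are skipped and reported
#' in the `skipped_rois` attribute rather than failing.
#'
#' @param table A `morphometry_table`.
#' @param region_set A [region_set()].
#' @param phenotype One of `thickness`, `area`, `volume`.
#' @param epsilon Tolerance for [classify_direction()].
#' @return Tibble with `subject_id`, `roi`, `phenotype`, `L`, `R`, `index`,
#'   `direction`.
#' @export
asymmetry_table <- function(table, region_set, phenotype, epsilon = 0.01) {
  stopifnot(inherits(table, "morphometry_table"))
  ph <- match.arg(phenotype, c("thickness", "area", "volume"))
  sub <- table[table$phenotype == ph & table$roi %in% region_set$rois, ]
  present <- unique(sub$roi)
  skipped <- setdiff(region_set$rois, present)
  wide <- tidyr::pivot_wider(sub[, c("subject_id", "hemi", "roi", "value")],
                             names_from = "hemi", values_from = "value")
  out <- tibble::tibble(
    subject_id = wide$subject_id,
    roi = factor(wide$roi, levels = region_set$rois),
    phenotype = ph,
    L = wide$lh, R = wide$rh,
    index = asymmetry_index(wide$lh, wide$rh)
  )
  out$direction <- classify_direction(out$index, epsilon)
  out <- dplyr::arrange(out, .data$subject_id, .data$roi)
  out$roi <- as.character(out$roi)
  attr(out, "skipped_rois") <- skipped
  out
}

#' Asymmetry table in wide (subjects x ROIs) layout
#'
#' @param asym Output of [asymmetry_table()].
#' @return Tibble: one row per subject, one column per ROI.
#' @export
asymmetry_wide <- function(asym) {
  tidyr::pivot_wider(asym[, c("subject_id", "roi", "index")],
                     names_from = "roi", values_from = "index")
}
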