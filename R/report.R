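#' Desikan-style whole-cortex ROI list
#'
#' The 34 standard gyral parcels commonly used for whole-cortex regional
#' summaries, in canonical snake_case keys. The pipeline accepts any
#' parcellation; this is the default "whole cortex" set for simulation and
#' records its region count in reports.
#'
#' @return Character vector of 34 ROI keys.
#' @export
whole_cortex_rois <- function() {
  c("banks_superior_temporal_sulcus", "caudal_anterior_cingulate",
    "caudal_middle_frontal", "cuneus", "entorhinal", "fusiform",
    "inferior_parietal", "inferior_temporal", "isthmus_cingulate",
    "lateral_occipital", "lateral_orbitofrontal", "lingual",
    "medial_orbitofrontal", "middle_temporal", "parahippocampal",
    "paracentral", "pars_opercularis", "pars_orbitalis",
    "pars_triangularis", "pericalcarine", "postcentral",
    "posterior_cingulate", "precentral", "precuneus",
    "rostral_anterior_cingulate", "rostral_middle_frontal",
    "superior_frontal", "superior_parietal", "superior_temporal",
    "supramarginal", "frontal_pole", "temporal_pole",
    "transverse_temporal", "insula")
}

#' Pipeline configuration
#'
#' Drives [run_pipeline()] from one object: either a [sim_config()] (the
#' synthetic family) or paths to real inputs (VCF + pedigree, morphometry
#' TSV, mask directory) — exactly one source per data class — plus analysis
#' options.
#'
#' @param simulation A [sim_config()], or `NULL` when real paths are given.
#' @param vcf,pedigree,morphometry,mask_dir Input paths (ignored when
#'   `simulation` is given).
#' @param panel A [gene_panel()]; default panel if `NULL`.
#' @param icc_form,epsilon,n_quantiles,background_rule Analysis options.
#' @param axes Axes for the luminosity analysis.
#' @param roi_set ROIs to simulate masks for (default: the pathway ROIs).
#' @param morph_rois ROIs for simulated morphometry (default: whole-cortex
#'   list plus the pathway ROIs).
#' @param out_dir Output directory.
#' @param write_artifacts Write VCF/TSV/NIfTI/PNG stage artifacts (default
#'   `TRUE`).
#' @param write_plots Render summary plots (default `FALSE`).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            vcf = NULL, pedigree = NULL, morphometry = NULL,
                            mask_dir = NULL, panel = NULL,
                            icc_form = "ICC(2,1)", epsilon = 0.01,
                            n_quantiles = 99L,
                            background_rule = "exclude_zero",
                            axes = c("sagittal", "coronal", "axial"),
                            roi_set = NULL, morph_rois = NULL,
                            out_dir = tempfile("twinscope_"),
                            write_artifacts = TRUE, write_plots = FALSE) {
  real <- !vapply(list(vcf, pedigree, morphometry, mask_dir), is.null,
                  logical(1))
  if (is.null(simulation) && !all(real)) {
    ts_abort("give either a simulation config or all real input paths",
             "config_error")
  }
  if (!is.null(simulation) && any(real)) {
    ts_abort("give either a simulation config or real inputs, not both",
             "config_error")
  }
  pw <- pathway_definitions()
  pw_rois <- unique(unlist(lapply(pw, `[[`, "rois")))
  structure(list(
    simulation = simulation, vcf = vcf, pedigree = pedigree,
    morphometry = morphometry, mask_dir = mask_dir,
    panel = panel %||% gene_panel(),
    icc_form = icc_form, epsilon = epsilon,
    n_quantiles = as.integer(n_quantiles),
    background_rule = background_rule, axes = axes,
    roi_set = roi_set %||% pw_rois,
    morph_rois = morph_rois %||% unique(c(whole_cortex_rois(), pw_rois)),
    out_dir = out_dir, write_artifacts = write_artifacts,
    write_plots = write_plots
  ), class = "pipeline_config")
}

#' Run the full family case-study pipeline
#'
#' Sequences data acquisition (simulation or reading of real inputs),
#' genotype QC and co-segregation analysis, ICC and asymmetry morphometry,
#' and the luminosity Q-Q analysis, then renders a structured report.
#' Fully deterministic for a fixed simulation seed.
#'
#' @param cfg A [pipeline_config()].
#' @return A `study_report` list with elements `genetics`, `icc`,
#'   `asymmetry`, `image`, `provenance`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest <- list.files(out_dir, recursive = TRUE)
      ts_abort(sprintf("stage '%s' failed: %s (artifacts so far: %s)",
                       name, conditionMessage(e),
                       paste(manifest, collapse = ", ")),
               "stage_error")
    })
  }

  # --- acquire data -------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim <- cfg$simulation
    cohort <- family_cohort()
    gtab <- stage("synthdata", simulate_genotypes(cohort, cfg$panel, sim))
    bg <- stage("synthdata",
                simulate_genotypes(cohort, NULL, sim,
                                   n_snps = sim$n_snps_background,
                                   seed_offset = 7L))
    morph <- stage("synthdata",
                   simulate_morphometry(cohort, cfg$morph_rois, sim))
    masks <- stage("synthdata", simulate_masks(cohort, cfg$roi_set, sim))
    if (cfg$write_artifacts) {
      write_family_vcf(gtab, file.path(out_dir, "family.vcf"))
      write_pedigree(cohort, file.path(out_dir, "family.ped.tsv"))
      write_morphometry(morph, file.path(out_dir, "morphometry.tsv"))
      mdir <- file.path(out_dir, "masks")
      dir.create(mdir, showWarnings = FALSE)
      for (roi in names(masks)) for (s in names(masks[[roi]])) {
        write_mask(masks[[roi]][[s]],
                   file.path(mdir, paste0(s, "__", roi, ".nii.gz")))
      }
      truth <- attr(gtab, "truth")
      jsonlite::write_json(
        list(planted_coseg = truth$planted, invariant = truth$invariant),
        file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
    }
  } else {
    cohort <- stage("input", read_pedigree(cfg$pedigree))
    gtab <- stage("input", read_family_vcf(cfg$vcf))
    bg <- NULL
    morph <- stage("input", read_morphometry(cfg$morphometry))
    files <- list.files(cfg$mask_dir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    masks <- list()
    for (f in files) {
      m <- stage("input", read_mask(f))
      masks[[m$roi]][[m$subject_id]] <- m
    }
  }

  # --- genetics -----------------------------------------------------------
  genetics <- stage("genetics", {
    ann <- annotate_snps(gtab, cfg$panel)
    qc <- apply_gencall_qc(ann)
    filt <- drop_family_invariant_snps(qc)
    res <- find_cosegregating_snps(filt, cohort$affected_sibling_ids,
                                   cohort$discordant_id)
    if (!is.null(bg)) {
      res <- background_comparison(res, apply_gencall_qc(bg), cohort)
    }
    if (cfg$write_artifacts) {
      write_coseg_results(res, filt, file.path(out_dir, "genetics"))
    }
    list(result = res, n_input_snps = nrow(gtab$gt),
         n_variable = res$n_panel_variable)
  })

  # --- morphometry --------------------------------------------------------
  whole <- region_set("whole_cortex", unique(morph$roi))
  reading <- reading_region_set()
  icc_tab <- stage("morphometry",
                   icc_matrix(morph, cohort, list(whole, reading),
                              cfg$icc_form))
  # asymmetry set adds the superior temporal gyrus to the reading regions
  asym_set <- region_set("reading_asymmetry",
                         unique(c(reading$rois, "superior_temporal")))
  asym <- stage("morphometry", dplyr::bind_rows(lapply(
    c("thickness", "volume", "area"), function(ph)
      asymmetry_table(morph, asym_set, ph, cfg$epsilon))))
  if (cfg$write_artifacts) {
    utils::write.table(icc_tab, file.path(out_dir, "icc_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(asym, file.path(out_dir, "asymmetry_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- luminosity ---------------------------------------------------------
  image <- stage("luminosity", {
    dists <- luminosity_distributions(masks, cfg$axes, cfg$background_rule)
    inter <- intersubject_qq(dists, cohort, cfg$n_quantiles)
    intra <- intrasubject_qq(dists, pathway_definitions(), cfg$n_quantiles)
    if (cfg$write_artifacts) {
      idir <- file.path(out_dir, "composites")
      dir.create(idir, showWarnings = FALSE)
      for (roi in names(masks)) for (ax in cfg$axes) {
        aref <- alpha_reference(masks[[roi]], ax)
        for (s in names(masks[[roi]])) {
          cmp <- build_composite(slice_mask(masks[[roi]][[s]], ax), aref)
          write_composite_png(cmp, file.path(
            idir, paste0(s, "__", roi, "__", ax, ".png")))
        }
      }
      jsonlite::write_json(
        list(curves = inter$curves, most_similar = inter$most_similar,
             roi_pairs = intra),
        file.path(out_dir, "qq_summary.json"), auto_unbox = TRUE,
        digits = NA)
    }
    list(inter = inter, intra = intra)
  })

  # --- assemble -----------------------------------------------------------
  cfg_file <- tempfile(); saveRDS(cfg[setdiff(names(cfg), "out_dir")],
                                  cfg_file)
  report <- structure(list(
    genetics = genetics,
    icc = icc_tab,
    asymmetry = asym,
    image = image,
    provenance = list(
      package = as.character(utils::packageVersion("twinscope")),
      seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else NA,
      icc_form = cfg$icc_form,
      n_whole_cortex_rois = length(whole$rois),
      config_hash = unname(tools::md5sum(cfg_file))
    )
  ), class = "study_report")
  unlink(cfg_file)

  verify_report_tallies(report)
  if (cfg$write_artifacts) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(render_summary(report), file.path(out_dir, "report.txt"))
  }
  if (cfg$write_plots) write_report_plots(report, out_dir)
  report
}

# conservation identities re-checked before rendering
verify_report_tallies <- function(report) {
  res <- report$genetics$result
  n <- length(res$matching_snps)
  if (sum(res$per_gene_counts) != n || sum(res$per_class_counts) != n) {
    ts_abort("tally conservation violated in genetics result",
             "report_error")
  }
  invisible(TRUE)
}

report_to_json <- function(report) {
  res <- report$genetics$result
  list(
    genetics = list(
      n_matching = length(res$matching_snps),
      n_variable = res$n_panel_variable,
      panel_proportion = res$panel_proportion,
      background_proportion = res$background_proportion,
      per_gene_counts = as.list(res$per_gene_counts),
      per_class_counts = as.list(res$per_class_counts),
      matching_snps = res$matching_snps
    ),
    icc = report$icc,
    asymmetry = report$asymmetry,
    image = list(most_similar = report$image$inter$most_similar,
                 curves = report$image$inter$curves,
                 roi_pairs = report$image$intra),
    provenance = report$provenance
  )
}

#' Render the human-readable study summary
#'
#' Three sections mirroring the report structure: Genetics Results,
#' Asymmetry Analyses, Image Analyses, each listing stage outputs with the
#' configuration used.
#'
#' @param report A `study_report` from [run_pipeline()].
#' @return Character vector of text lines.
#' @export
render_summary <- function(report) {
  stopifnot(inherits(report, "study_report"))
  res <- report$genetics$result
  gene_lines <- if (length(res$per_gene_counts)) {
    paste0("  ", names(res$per_gene_counts), ": ",
           as.integer(res$per_gene_counts), " SNP(s)")
  } else "  (no matching SNPs)"
  icc <- report$icc
  icc_lines <- sprintf("  %-10s %-13s %-9s %s = %.2f (n=%d)",
                       icc$pair, icc$phenotype, icc$region_set,
                       icc$icc_form, icc$icc, icc$n_items)
  asym <- report$asymmetry
  asym_lines <- sprintf("  %-10s %-30s %-10s index %+.3f (%s)",
                        asym$subject_id, asym$roi, asym$phenotype,
                        asym$index, asym$direction)
  ms <- report$image$inter$most_similar
  ms_lines <- sprintf("  %-30s %-9s most similar: %-10s (margin %.4f%s)",
                      ms$roi, ms$axis, ms$label, ms$margin,
                      ifelse(ms$tie, ", tie", ""))
  c("== Genetics Results ==",
    sprintf("Pattern-matching SNPs: %d of %d variable (%.1f%%)",
            length(res$matching_snps), res$n_panel_variable,
            100 * res$panel_proportion),
    if (!is.na(res$background_proportion))
      sprintf("Genome background: %.1f%%", 100 * res$background_proportion),
    gene_lines,
    "",
    "== Asymmetry Analyses ==",
    sprintf("ICC form: %s | whole-cortex regions: %d",
            report$provenance$icc_form,
            report$provenance$n_whole_cortex_rois),
    icc_lines, "", asym_lines,
    "",
    "== Image Analyses ==",
    ms_lines)
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}
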