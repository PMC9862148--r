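#' Reading-related candidate gene symbols
#'
#' The 28 genes with prior evidence for association with reading and language
#' phenotypes that form the default co-segregation panel: candidate genes from
#' dyslexia risk loci (e.g. DCDC2, KIAA0319, ROBO1), language genes (FOXP2,
#' CNTNAP2), and GWAS/linkage hits (e.g. FGF18, LPHN3, MSI2, RBFOX2).
#'
#' @return Character vector of 28 gene symbols.
#' @export
reading_gene_symbols <- function() {
  c("MRPL19", "ZNF385D", "ROBO1", "VEPH1", "LPHN3", "FGF18", "DCDC2",
    "KIAA0319", "TTRAP", "THEM2", "RIPOR2", "CMAHP", "FOXP2", "CCDC136",
    "CNTNAP2", "SLC2A3", "COL4A2", "NOP9", "TUBGCP5", "CYFIP1", "NIPA2",
    "SEMA6D", "DNAAF4", "CMIP", "ATP2C2", "MSI2", "MYO18B", "RBFOX2")
}

#' Construct a gene panel
#'
#' A panel is a set of gene symbols with genomic intervals (1-based inclusive)
#' used to assign SNPs to genes. The default panel carries the 28
#' reading-related symbols with a deterministic synthetic interval layout
#' (100 kb genes spaced 1 Mb apart across chromosomes); real analyses should
#' supply measured coordinates via [read_gene_panel()].
#'
#' @param genes Data frame with columns `symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive). Default: synthetic layout over [reading_gene_symbols()].
#' @param flank_bp Non-negative flank in bp for gene assignment (default 0).
#' @return A `gene_panel` object (tibble with attribute `flank_bp`).
#' @export
gene_panel <- function(genes = NULL, flank_bp = 0L) {
  flank_bp <- assert_count(flank_bp, "flank_bp")
  if (is.null(genes)) {
    sym <- reading_gene_symbols()
    # synthetic coordinates: 4 chromosomes x 7 genes, 100 kb bodies, 1 Mb apart
    chrom <- paste0("chr", rep(1:4, each = 7L))
    start <- rep(seq(1e6, by = 1e6, length.out = 7L), times = 4L)
    genes <- tibble::tibble(symbol = sym, chrom = chrom,
                            start = start, end = start + 1e5 - 1)
  }
  genes <- tibble::as_tibble(genes)
  req <- c("symbol", "chrom", "start", "end")
  if (!all(req %in% names(genes))) {
    ts_abort("gene panel needs columns symbol, chrom, start, end",
             "config_error")
  }
  if (any(genes$end < genes$start)) {
    ts_abort("gene intervals must have start <= end", "config_error")
  }
  # intervals must not overlap within a gene symbol
  by_sym <- split(genes, genes$symbol)
  for (g in by_sym) {
    g <- g[order(g$chrom, g$start), ]
    same <- g$chrom[-1] == g$chrom[-nrow(g)]
    if (nrow(g) > 1L && any(same & g$start[-1] <= g$end[-nrow(g)])) {
      ts_abort(sprintf("overlapping intervals within gene %s", g$symbol[1]),
               "config_error")
    }
  }
  structure(genes, class = c("gene_panel", class(genes)), flank_bp = flank_bp)
}

#' Read a gene panel from a BED-derived TSV
#'
#' Columns `symbol`, `chrom`, `start`, `end` in BED half-open, 0-based
#' coordinates; converted to 1-based inclusive on read (start + 1) and the
#' conversion is reported via a message.
#'
#' @param path TSV path.
#' @param flank_bp Flank in bp, see [gene_panel()].
#' @return A `gene_panel`.
#' @export
read_gene_panel <- function(path, flank_bp = 0L) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$start <- tab$start + 1L
  message("gene panel: converted BED half-open coordinates to 1-based inclusive")
  gene_panel(tab, flank_bp = flank_bp)
}

#' Region sets for morphometry analyses
#'
#' `reading_region_set()` is the default reading-network subset used for the
#' focused intraclass-correlation comparison: fusiform, inferior parietal,
#' banks of the superior temporal sulcus, pars opercularis, pars triangularis,
#' supramarginal and transverse temporal cortex.
#'
#' @param name Set label.
#' @param rois Character vector of canonical ROI keys.
#' @return A `region_set` (list with `name`, `rois`).
#' @export
region_set <- function(name, rois) {
  rois <- canonical_roi(rois)
  if (length(rois) == 0L) ts_abort("region set needs at least one ROI",
                                   "config_error")
  structure(list(name = name, rois = unique(rois)), class = "region_set")
}

#' @rdname region_set
#' @export
reading_region_set <- function() {
  region_set("reading", c(
    "fusiform", "inferior_parietal", "banks_superior_temporal_sulcus",
    "pars_opercularis", "pars_triangularis", "supramarginal",
    "transverse_temporal"))
}

#' Reading-pathway definitions for the luminosity analysis
#'
#' The three reading-network pathways whose member regions define the
#' intra-subject ROI-pair comparisons: ventral (automatic word recognition:
#' inferior occipital, fusiform), frontal (attention/verbalization: pars
#' orbitalis, pars triangularis, pars opercularis) and dorsal (phonological
#' processing: supramarginal, angular, superior temporal, transverse temporal,
#' planum temporale, planum polare).
#'
#' @return Named list of `pathway` objects (`name`, `rois`).
#' @export
pathway_definitions <- function() {
  mk <- function(name, rois) {
    structure(list(name = name, rois = canonical_roi(rois)),
              class = "pathway")
  }
  list(
    ventral = mk("ventral", c("inferior_occipital", "fusiform")),
    frontal = mk("frontal", c("pars_orbitalis", "pars_triangularis",
                              "pars_opercularis")),
    dorsal  = mk("dorsal", c("supramarginal", "angular", "superior_temporal",
                             "transverse_temporal", "planum_temporale",
                             "planum_polare"))
  )
}

#' All unordered ROI pairs of a pathway
#'
#' @param pathway A `pathway` (see [pathway_definitions()]) or a list with a
#'   `rois` character vector.
#' @return Tibble with columns `roi1`, `roi2`; `n(n-1)/2` rows.
#' @export
enumerate_roi_pairs <- function(pathway) {
  rois <- pathway$rois
  if (is.null(rois) || length(rois) < 2L) {
    ts_abort("pathway must contain at least 2 ROIs", "argument_error")
  }
  cmb <- utils::combn(rois, 2L)
  tibble::tibble(roi1 = cmb[1, ], roi2 = cmb[2, ])
}

# alias map: atlas-style names -> canonical snake_case keys
roi_alias_table <- function() {
  c(
    "bankssts" = "banks_superior_temporal_sulcus",
    "banks sts" = "banks_superior_temporal_sulcus",
    "banks superior temporal sulcus" = "banks_superior_temporal_sulcus",
    "g_temp_sup-g_t_transv" = "transverse_temporal",
    "transversetemporal" = "transverse_temporal",
    "heschl" = "transverse_temporal",
    "heschls gyrus" = "transverse_temporal",
    "superiortemporal" = "superior_temporal",
    "g_temp_sup-lateral" = "superior_temporal",
    "inferiorparietal" = "inferior_parietal",
    "parsopercularis" = "pars_opercularis",
    "parstriangularis" = "pars_triangularis",
    "parsorbitalis" = "pars_orbitalis",
    "g_oc-temp_lat-fusifor" = "fusiform",
    "fusiform gyrus" = "fusiform",
    "supramarginal gyrus" = "supramarginal",
    "angular gyrus" = "angular",
    "g_pariet_inf-angular" = "angular",
    "g_pariet_inf-supramar" = "supramarginal",
    "inferioroccipital" = "inferior_occipital",
    "inferior occipital" = "inferior_occipital",
    "planumtemporale" = "planum_temporale",
    "planum temporale" = "planum_temporale",
    "planumpolare" = "planum_polare",
    "planum polare" = "planum_polare"
  )
}

#' Canonicalize ROI names
#'
#' Lower-cases, trims, converts separators to underscores, and resolves known
#' Desikan- and Destrieux-style aliases (e.g. `"bankssts"`,
#' `"G_temp_sup-G_T_transv"`) to canonical snake_case keys.
#'
#' @param x Character vector of ROI names.
#' @return Character vector of canonical keys.
#' @export
canonical_roi <- function(x) {
  key <- tolower(trimws(x))
  al <- roi_alias_table()
  hit <- key %in% names(al)
  key[hit] <- al[key[hit]]
  gsub("[^a-z0-9]+", "_", key)
}
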